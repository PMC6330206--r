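test_that("great-circle distances match the haversine closed form", {
  co <- data.frame(site = c("o", "e", "n"), lon = c(0, 1, 0),
                   lat = c(0, 0, 1))
  D <- geoDistances(co)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  # one degree along the equator / meridian on R = 6371 km
  expect_equal(D["o", "e"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(D["o", "e"], 111.19, tolerance = 1e-3)
  expect_equal(D["o", "n"], D["o", "e"], tolerance = 1e-9)

  set.seed(3)
  co2 <- data.frame(site = paste0("s", 1:12), lon = runif(12, -30, 30),
                    lat = runif(12, -30, 30))
  D2 <- geoDistances(co2)
  for (i in 1:30) {
    ix <- sample(12, 3)
    expect_lte(D2[ix[1], ix[3]],
               D2[ix[1], ix[2]] + D2[ix[2], ix[3]] + 1e-9)
  }

  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(c(co2$lon[1], co2$lat[1]),
                                  c(co2$lon[2], co2$lat[2]),
                                  r = 6371)
  expect_equal(D2[1, 2], ref, tolerance = 1e-9)
})

test_that("PCNM bases satisfy the principal-coordinate contracts", {
  # equilateral triangle: planar geometry gives exactly 2 positive axes
  side <- 1
  xy <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2))
  D <- as.matrix(dist(xy))
  b <- pcnm(D, truncation = side)
  expect_equal(length(eigenValues(b)), 2L)
  expect_true(all(eigenValues(b) > 0))

  expect_error(pcnm(matrix(0, 3, 3)), "degenerate")

  # equispaced transect: vectors centered, orthogonal, wave-like
  co <- data.frame(site = paste0("s", 1:25), lon = seq(0, 2, length.out = 25),
                   lat = 0)
  D <- geoDistances(co)
  b <- pcnm(D)
  V <- axisScores(b)
  expect_lt(max(abs(colMeans(V))), 1e-10)
  G <- crossprod(V)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # leading vector ~ half-cosine along the transect; broad-scale and
  # positively autocorrelated at short range
  x <- seq_len(25)
  cosine <- cos(pi * (x - 0.5) / 25)
  expect_gt(abs(cor(V[, 1], cosine)), 0.8)
  cg <- moransICorrelogram(V[, 1], D, nClasses = 5, nPerm = 99, seed = 1)
  expect_gt(cg@table$statistic[1], 0)

  skip_if_not_installed("vegan")
  ref <- vegan::pcnm(D)
  expect_equal(length(eigenValues(b)), sum(ref$values > 1e-8 * max(ref$values)))
  expect_equal(eigenValues(b), ref$values[seq_along(eigenValues(b))],
               tolerance = 1e-6)
  expect_gt(abs(cor(V[, 1], ref$vectors[, 1])), 0.999)
})

test_that("Moran correlograms behave at the sign and null extremes", {
  co <- data.frame(site = paste0("s", 1:20),
                   lon = seq(0, 1, length.out = 20), lat = 0)
  D <- geoDistances(co)
  alternating <- rep(c(1, -1), 10)
  cg <- moransICorrelogram(alternating, D, nClasses = 6, nPerm = 99,
                           seed = 2)
  expect_lt(cg@table$statistic[1], -1 / 19)       # below E[I]
  expect_error(moransICorrelogram(rep(1, 20), D), "constant")

  # pair counts over classes total n(n-1)/2
  expect_equal(sum(cg@table$n_pairs), choose(20, 2))

  # null calibration: rejection rate near nominal
  set.seed(4)
  rej <- replicate(40, {
    v <- rnorm(20)
    any(moransICorrelogram(v, D, nClasses = 3, nPerm = 99,
                           seed = sample.int(1e6, 1))@table$p < 0.05)
  })
  expect_lte(mean(rej), 0.35)                     # ~3 classes at 5% each
})

test_that("Mantel correlograms track distance-structured dissimilarity", {
  set.seed(5)
  co <- data.frame(site = paste0("s", 1:24), lon = runif(24), lat = runif(24))
  D <- geoDistances(co)
  beta <- D / max(D) * 0.8                        # beta proportional to distance
  cg <- mantelCorrelogram(beta, D, nClasses = 5, nPerm = 99, seed = 6)
  tab <- cg@table
  expect_gt(tab$statistic[1], 0)   # near pairs less dissimilar than average
  expect_lt(tab$statistic[nrow(tab)], 0)
  expect_equal(sum(tab$n_pairs), choose(24, 2))
  expect_error(mantelCorrelogram(beta, D, nPerm = 0), "nPerm")
  expect_error(mantelCorrelogram(beta[1:10, 1:10], D), "conformable")
})

test_that("residualization removes exactly the modelled structure", {
  set.seed(7)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  y <- 2 * X[, "a"] - X[, "b"] + 5
  expect_equal(unname(residualize(y, X)), rep(0, 30), tolerance = 1e-10)

  orth <- resid(lm(rnorm(30) ~ X))                # orthogonal to X
  r <- residualize(orth, X)
  expect_equal(unname(r), unname(orth - mean(orth)), tolerance = 1e-10)
  expect_error(residualize(y, cbind(X, X[, 1])), "collinearity")

  # beta residualization: environment-driven dissimilarity loses its
  # spatial signal once environmental distance is regressed out
  hits <- vapply(1:10, function(s) {
    l <- simulateLandscape(30, nSoil = 1, nClim = 1, autocorrRange = 300, seed = s)
    D <- geoDistances(l$coords)
    envD <- as.matrix(dist(l$env[, 1]))
    beta <- envD / max(envD) * 0.9
    res <- residualizeBeta(beta, envD)
    any(mantelCorrelogram(res, D, nClasses = 3, nPerm = 99,
                          seed = s)@table$p < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})
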