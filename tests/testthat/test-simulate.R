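test_that("simulated trees are binary, ultrametric and deterministic", {
  expect_error(simulateTree(1), "nTips")

  cherry <- simulateTree(2, seed = 5)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])

  tr <- simulateTree(50, seed = 1)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulateTree(50, seed = 1)))
  expect_true(isUltrametricTree(tr, tol = 1e-8))
  # binary rooted tree: 49 bifurcations for 50 tips
  kids <- tabulate(tr$edge[, 1])
  expect_equal(sum(kids[kids > 0] - 1), 49)
  expect_true(all(kids[kids > 0] == 2))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
})

test_that("trait simulation reproduces its target covariance structure", {
  tr <- simulateTree(8, seed = 2)
  expect_error(simulateTraits(tr, lambda = 1.5, model = "lambda_scaled"),
               "lambda")
  t1 <- simulateTraits(tr, nTraits = 3, seed = 9)
  expect_identical(t1, simulateTraits(tr, nTraits = 3, seed = 9))

  # white noise: off-diagonal sample covariance shrinks to 0, variance to
  # sigma2 (unit-depth tree)
  wn <- simulateTraits(tr, model = "white_noise", sigma2 = 2,
                       nTraits = 1000, seed = 3)
  M <- apply(traitMatrix(wn), c(1, 2), as.numeric)
  S <- cov(t(M))
  expect_equal(mean(diag(S)), 2, tolerance = 0.15)
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 0.35)
  expect_lt(abs(mean(off)), 0.05)

  # Brownian cherry: Var(x1 - x2) = 2 * sigma2 * depth
  ch <- readNewick("(a:1,b:1);", text = TRUE)
  bm <- simulateTraits(ch, model = "brownian", sigma2 = 1.5,
                       nTraits = 4000, seed = 4)
  M <- apply(traitMatrix(bm), c(1, 2), as.numeric)
  expect_equal(var(M["a", ] - M["b", ]), 2 * 1.5, tolerance = 0.15)
})

test_that("landscapes carry the requested spatial autocorrelation", {
  expect_error(simulateLandscape(5), "nSites")
  l1 <- simulateLandscape(20, nSoil = 2, nClim = 2, seed = 11)
  expect_identical(l1, simulateLandscape(20, nSoil = 2, nClim = 2, seed = 11))
  expect_equal(colMeans(l1$env), rep(0, 4), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(apply(l1$env, 2, sd), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(attr(l1$env, "group"), c("soil", "soil", "clim", "clim"))

  # long-range landscapes: positive Moran's I in the first distance class
  # in nearly all seeds; near-zero range: mostly inside the null envelope
  firstClass <- function(range, seed) {
    l <- simulateLandscape(40, nSoil = 1, nClim = 0, autocorrRange = range, nugget = 0,
                           seed = seed)
    D <- geoDistances(l$coords)
    cg <- moransICorrelogram(l$env[, 1], D, nClasses = 5, nPerm = 99,
                             seed = seed)
    cg@table[1, ]
  }
  longR <- vapply(1:10, function(s) {
    r <- firstClass(500, s); r$statistic > 0 && r$p < 0.05
  }, logical(1))
  expect_gte(mean(longR), 0.8)
  shortR <- vapply(1:10, function(s) firstClass(0.01, s)$p < 0.05,
                   logical(1))
  expect_lte(mean(shortR), 0.3)
})

test_that("community assembly honours its invariants and limits", {
  ds <- smallDataset()
  expect_true(all(ds$comm %in% 0:1))
  expect_true(all(rowSums(ds$comm) >= 2))
  expect_true(all(colSums(ds$comm) >= 1))
  expect_identical(ds$comm, smallDataset()$comm)

  # neutral limit: occurrence probability uniform, species frequencies
  # differ only by binomial noise around baseProb * nSites
  tr <- simulateTree(60, seed = 1)
  trt <- simulateTraits(tr, nTraits = 2, seed = 2)
  l <- simulateLandscape(40, nSoil = 2, nClim = 2, seed = 3)
  comm <- simulateCommunities(tr, trt, l$env, l$coords,
                              nicheBreadth = Inf, dispersalRange = Inf,
                              baseProb = 0.4, seed = 4)
  freq <- colSums(comm)
  expect_equal(mean(freq) / 40, 0.4, tolerance = 0.1)
  expect_lt(max(freq), 40 * 0.4 + 5 * sqrt(40 * 0.4 * 0.6) + 1)

  # narrow niche: TD beta correlates positively with environmental distance
  commN <- simulateCommunities(tr, trt, l$env, l$coords,
                               nicheBreadth = 0.5, dispersalRange = Inf,
                               baseProb = 0.4, seed = 5)
  prof <- diversityProfile(commN, taxonomicDistance(colnames(commN)))
  envD <- as.matrix(dist(l$env[, 1]))
  lt <- lower.tri(envD)
  expect_gt(cor(betaDiversity(prof)[lt], envD[lt]), 0.1)

  # unresolvable sites fail loudly
  expect_error(simulateCommunities(tr, trt, l$env, l$coords,
                                   nicheBreadth = 0.01, baseProb = 1e-6,
                                   seed = 6, maxRetries = 3),
               "generation failure")
})
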