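test_that("PCoA reconstructs Euclidean geometry and orders gradients", {
  # points on a line: first axis reproduces the ordering
  x <- c(0, 0.3, 1.1, 2.0, 3.2, 4.0)
  beta <- as.matrix(dist(x)) / 10
  pc <- pcoaAxes(beta, axisRule = "all_positive")
  ord <- order(pc$scores[, 1])
  expect_true(identical(ord, order(x)) || identical(ord, rev(order(x))))

  # zero matrix: no positive axes
  z <- pcoaAxes(matrix(0, 4, 4))
  expect_equal(z$nRetained, 0L)
  expect_equal(ncol(z$scores), 0L)

  # Gower reconstruction: full-axis scores reproduce a Euclidean-embeddable
  # dissimilarity
  set.seed(11)
  pts <- matrix(rnorm(40), 10, 4)
  beta <- as.matrix(dist(pts))
  pc <- pcoaAxes(beta, axisRule = "all_positive")
  rec <- as.matrix(dist(pc$scores))
  expect_equal(rec, beta, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("RDA reduces to known closed forms", {
  set.seed(12)
  n <- 30
  y <- rnorm(n)
  expect_equal(rdaFit(y, cbind(y), nPerm = 19)$r2, 1, tolerance = 1e-12)

  x <- rnorm(n)
  fit <- rdaFit(y, cbind(x = x), nPerm = 99, seed = 1)
  expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(fit$adjR2, 1 - (1 - fit$r2) * (n - 1) / (n - 2),
               tolerance = 1e-12)
  expect_error(rdaFit(y, cbind(x, x), nPerm = 19), "collinearity")
  expect_error(rdaFit(y, cbind(x), nPerm = 0), "nPerm")

  # orthogonal predictors: adjusted R2 hovers around zero
  adj <- vapply(1:30, function(s) {
    set.seed(100 + s)
    rdaFit(rnorm(n), cbind(rnorm(n)), nPerm = 19, seed = s)$adjR2
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.05)

  skip_if_not_installed("vegan")
  Y <- matrix(rnorm(n * 3), n)
  X <- matrix(rnorm(n * 2), n)
  ref <- vegan::rda(Y ~ X)
  fit2 <- rdaFit(Y, scale(X), nPerm = 19, seed = 1)
  expect_equal(fit2$r2, unname(vegan::RsquareAdj(ref)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit2$adjR2, unname(vegan::RsquareAdj(ref)$adj.r.squared),
               tolerance = 1e-10)
})

test_that("forward selection finds planted signal and exhausts when uncapped", {
  set.seed(13)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 * X[, 3] + rnorm(n, sd = 0.5)

  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    Xs <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
    ys <- 2 * Xs[, 3] + rnorm(n, sd = 0.5)
    m <- forwardSelect(ys, Xs, nPerm = 99, seed = s)
    length(selectedTerms(m)) > 0 && selectedTerms(m)[1] == "v3"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # alpha = 1, no cap: every candidate enters and cumulative R2 equals the
  # full-model R2
  m <- forwardSelect(y, X, alpha = 1.0, nPerm = 19, seed = 3,
                     adjR2Cap = FALSE)
  expect_setequal(selectedTerms(m), colnames(X))
  expect_equal(sum(m@addedR2), rdaFit(y, X, nPerm = 19)$r2,
               tolerance = 1e-10)
  expect_true(all(m@addedR2 >= 0))

  # pure noise: selection usually stays empty
  empties <- vapply(1:20, function(s) {
    set.seed(300 + s)
    Xn <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
    length(selectedTerms(forwardSelect(rnorm(n), Xn, nPerm = 99,
                                       seed = s))) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.8)
})

test_that("partial RDA equals the brute-force adjusted-R2 difference", {
  set.seed(14)
  n <- 35
  Y <- matrix(rnorm(n * 2), n)
  X <- matrix(rnorm(n * 3), n)
  Z <- matrix(rnorm(n * 2), n)

  pr <- partialRda(Y, X, Z, nPerm = 49, seed = 1)
  ppY <- scale(Y, scale = FALSE)
  r2 <- function(M) {
    M <- scale(M)
    f <- qr.fitted(qr(M), ppY); sum(f^2) / sum(ppY^2)
  }
  brute <- adjustedR2(r2(cbind(X, Z)), n, 5) - adjustedR2(r2(Z), n, 2)
  expect_equal(pr$fraction, brute, tolerance = 1e-10)

  # empty conditioning reduces to plain RDA
  pr0 <- partialRda(Y, X, NULL, nPerm = 49, seed = 2)
  expect_equal(pr0$fraction, rdaFit(Y, X, nPerm = 9)$adjR2,
               tolerance = 1e-12)

  # X inside span(Z): fraction collapses
  prIn <- partialRda(Y, Z[, 1, drop = FALSE], Z, nPerm = 49, seed = 3)
  expect_lt(abs(prIn$fraction), 1e-10)
})

test_that("two-set variation partitioning closes algebraically", {
  set.seed(15)
  n <- 30
  Y <- rnorm(n)
  E <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("e1", "e2")))
  S <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("s1", "s2")))

  vp <- varpart2(Y, E, S)
  f <- fractions(vp)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # brute-force identity
  Yc <- scale(Y, scale = FALSE)
  r2 <- function(M) { M <- scale(M); sum(qr.fitted(qr(M), Yc)^2) / sum(Yc^2) }
  aE <- adjustedR2(r2(E), n, 2); aS <- adjustedR2(r2(S), n, 2)
  aES <- adjustedR2(r2(cbind(E, S)), n, 4)
  expect_equal(unname(f), c(aES - aS, aE + aS - aES, aES - aE, 1 - aES),
               tolerance = 1e-10)

  # degenerate configurations
  fE <- fractions(varpart2(Y, E, NULL))
  expect_equal(unname(fE[c("b", "c")]), c(0, 0), tolerance = 1e-12)
  expect_equal(fE[["a"]], aE, tolerance = 1e-12)
  fSame <- fractions(varpart2(Y, E, E))
  expect_equal(unname(fSame[c("a", "c")]), c(0, 0), tolerance = 1e-10)
  expect_equal(fSame[["b"]], aE, tolerance = 1e-10)

  skip_if_not_installed("vegan")
  # vegan rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d] = residuals
  ref <- vegan::varpart(Y, scale(E), scale(S))$part$indfract$Adj.R.square
  expect_equal(unname(f[c("a", "c", "b", "d")]), ref, tolerance = 1e-10)
})
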