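## Phylogenetic signal statistics: Blomberg's K with a tip-shuffling
## permutation test, and Pagel's lambda with a likelihood-ratio test.
##
## K compares the observed ratio of non-phylogenetic to phylogenetic mean
## squared error to its Brownian expectation on the same tree:
##   K = [MSE0 / MSE] / E[MSE0 / MSE],
##   MSE0 = (y - a)'(y - a) / (n - 1),  MSE = (y - a)' C^-1 (y - a) / (n - 1),
##   E[MSE0 / MSE] = (tr(C) - n / (1' C^-1 1)) / (n - 1),
## with a the GLS phylogenetic mean under the shared-path covariance C.
## lambda scales the off-diagonal of C; its MLE is found by profiling the
## mean and rate out of the Gaussian likelihood and optimizing over [0, 1].

.phyloC <- function(tree) {
  C <- ape::vcv.phylo(tree)
  ## zero-length branches (random polytomy resolution) can make C singular;
  ## a minimal diagonal jitter is added only in that case
  ok <- inherits(try(chol(C), silent = TRUE), "matrix")
  if (!ok) C <- C + diag(1e-10, nrow(C))
  C
}

.alignTrait <- function(tree, trait) {
  if (is.null(names(trait)))
    stop("trait values must be named by species")
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait values missing for some tips")
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait contains missing values")
  if (sd(y) == 0)
    stop("degenerate trait: constant across tips, K undefined")
  y
}

.kMachine <- function(C) {
  n <- nrow(C)
  invC <- solve(C)
  csum <- colSums(invC)                 # 1' C^-1
  denom <- sum(csum)                    # 1' C^-1 1
  expectedRatio <- (sum(diag(C)) - n / denom) / (n - 1)
  list(invC = invC, csum = csum, denom = denom, expected = expectedRatio)
}

.kStat <- function(y, mach) {
  a <- sum(mach$csum * y) / mach$denom
  q <- y - a
  mse0 <- sum(q * q)
  mse <- drop(q %*% mach$invC %*% q)
  (mse0 / mse) / mach$expected
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K = 1 is the Brownian-motion expectation on the given tree; K > 1 means
#' stronger, K < 1 weaker, resemblance among relatives than Brownian
#' evolution predicts.
#'
#' @param tree \code{ape::phylo} tree with branch lengths (>= 3 tips).
#' @param trait named numeric vector of tip values.
#' @return K (non-negative scalar).
#' @export
blombergK <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3)
    stop("invalid argument: K needs at least 3 tips")
  y <- .alignTrait(tree, trait)
  .kStat(y, .kMachine(.phyloC(tree)))
}

#' Permutation test for Blomberg's K
#'
#' Trait values are shuffled across the tips of the phylogeny; the
#' one-tailed p-value is \code{(1 + #(K_perm >= K_obs)) / (nPerm + 1)}.
#'
#' @param tree \code{ape::phylo} tree.
#' @param trait named numeric vector of tip values.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the shuffles.
#' @return list with \code{K} and \code{p}.
#' @export
blombergKTest <- function(tree, trait, nPerm = 999L, seed = 1L) {
  if (nPerm < 1) stop("invalid argument: nPerm must be >= 1")
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3)
    stop("invalid argument: K needs at least 3 tips")
  y <- .alignTrait(tree, trait)
  mach <- .kMachine(.phyloC(tree))
  kObs <- .kStat(y, mach)
  set.seed(seed)
  n <- length(y)
  kPerm <- vapply(seq_len(nPerm),
                  function(i) .kStat(y[sample.int(n)], mach), numeric(1))
  list(K = kObs, p = (1 + sum(kPerm >= kObs)) / (nPerm + 1))
}

.lambdaLogLik <- function(lambda, y, C) {
  n <- length(y)
  V <- C * lambda
  diag(V) <- diag(C)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  invVy <- backsolve(ch, forwardsolve(t(ch), y))
  invV1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- sum(invVy) / sum(invV1)
  q <- y - a
  invVq <- backsolve(ch, forwardsolve(t(ch), q))
  s2 <- sum(q * invVq) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda with likelihood-ratio test
#'
#' Maximizes the Gaussian log-likelihood of the trait under covariance
#' C(lambda) — shared-path covariance with off-diagonals scaled by lambda —
#' with the phylogenetic mean and rate profiled out, lambda constrained to
#' [0, 1]. Significance is a likelihood-ratio test of lambda-hat against
#' lambda = 0 on a plain chi-squared(1) reference (no boundary halving;
#' this matches common tooling and is mildly conservative when
#' lambda-hat sits at 0).
#'
#' @param tree \code{ape::phylo} tree with branch lengths.
#' @param trait named numeric vector of tip values.
#' @return list with \code{lambda}, \code{logL} (at the optimum),
#'   \code{logL0} (at lambda = 0) and \code{p}.
#' @export
pagelLambda <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3)
    stop("invalid argument: lambda needs at least 3 tips")
  y <- .alignTrait(tree, trait)
  C <- .phyloC(tree)
  f <- function(l) .lambdaLogLik(l, y, C)
  opt <- optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  ## optimize() can miss maxima at the box edges; compare explicitly
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  lambdaHat <- cand[best]
  logL <- ll[best]
  logL0 <- ll[2]
  stat <- max(0, 2 * (logL - logL0))
  list(lambda = lambdaHat, logL = logL, logL0 = logL0,
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Default numeric coding for qualitative traits
#'
#' Assigns codes 1..k to the sorted categories of every qualitative trait;
#' used when no explicit coding map is supplied.
#'
#' @param traits long-format trait table.
#' @return data.frame(trait, category, code).
#' @export
defaultCodingMap <- function(traits) {
  qual <- unique(traits$trait[traits$kind == "qualitative"])
  maps <- lapply(qual, function(tr) {
    cats <- sort(unique(traits$value[traits$trait == tr]))
    data.frame(trait = tr, category = cats, code = seq_along(cats),
               stringsAsFactors = FALSE)
  })
  if (length(maps)) do.call(rbind, maps)
  else data.frame(trait = character(), category = character(),
                  code = numeric(), stringsAsFactors = FALSE)
}

#' Phylogenetic-signal table for all traits
#'
#' Tests each trait with Blomberg's K (tip-shuffling permutation test) and
#' Pagel's lambda (likelihood-ratio test). Qualitative traits are tested
#' on their numeric codings.
#'
#' @param tree \code{ape::phylo} tree.
#' @param traits long-format trait table.
#' @param codingMap coding map for qualitative traits; defaults to
#'   \code{\link{defaultCodingMap}}.
#' @param nPerm permutations for the K test.
#' @param seed integer seed.
#' @return data.frame(trait, K, K_p, lambda, lambda_p).
#' @export
signalTable <- function(tree, traits, codingMap = NULL, nPerm = 999L,
                        seed = 1L) {
  if (is.null(codingMap)) codingMap <- defaultCodingMap(traits)
  M <- encodeTraits(traits, codingMap)
  out <- lapply(seq_len(ncol(M)), function(j) {
    y <- setNames(M[, j], rownames(M))
    kt <- blombergKTest(tree, y, nPerm = nPerm, seed = seed + j)
    pl <- pagelLambda(tree, y)
    data.frame(trait = colnames(M)[j], K = kt$K, K_p = kt$p,
               lambda = pl$lambda, lambda_p = pl$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
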