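## Constrained ordination machinery: principal coordinate analysis of beta
## matrices, redundancy analysis with permutation tests and Ezekiel
## adjusted R2, forward selection with the double stopping rule, partial
## RDA and two-set variation partitioning.

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Double-centers \code{-0.5 * beta^2}, eigen-decomposes, and returns axis
#' scores scaled by the square root of the eigenvalues. Axis retention is
#' either broken-stick exceedance among the positive eigenvalues (leading
#' axes whose variance proportion exceeds the broken-stick expectation; at
#' least one axis is always kept) or all positive axes. Negative
#' eigenvalues are reported, not corrected.
#'
#' @param beta symmetric, zero-diagonal site x site dissimilarity matrix.
#' @param axisRule \code{"broken_stick"} (default) or
#'   \code{"all_positive"}.
#' @return list with \code{scores} (sites x retained axes), \code{eig}
#'   (all eigenvalues), \code{nRetained}, \code{negative} (number of
#'   negative eigenvalues).
#' @export
pcoaAxes <- function(beta, axisRule = c("broken_stick", "all_positive")) {
  axisRule <- match.arg(axisRule)
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == ncol(beta))
  if (max(abs(beta - t(beta))) > 1e-8)
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(beta)
  A <- -0.5 * beta^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * max(abs(eg$values)))
  if (length(pos) == 0L)
    return(list(scores = matrix(0, n, 0, dimnames = list(rownames(beta),
                                                         NULL)),
                eig = eg$values, nRetained = 0L,
                negative = sum(eg$values < 0)))
  lam <- eg$values[pos]
  scores <- sweep(eg$vectors[, pos, drop = FALSE], 2, sqrt(lam), `*`)
  dimnames(scores) <- list(rownames(beta),
                           sprintf("PCo%d", seq_along(pos)))
  k <- length(pos)
  if (axisRule == "broken_stick") {
    prop <- lam / sum(lam)
    bs <- rev(cumsum(1 / rev(seq_len(k)))) / k
    exceed <- prop > bs
    keep <- if (exceed[1]) {
      r <- rle(exceed)
      seq_len(r$lengths[1])
    } else 1L
  } else keep <- seq_len(k)
  list(scores = scores[, keep, drop = FALSE], eig = eg$values,
       nRetained = length(keep), negative = sum(eg$values < 0))
}

## unadjusted RDA R2 of centered Y on centered X via QR projection
.rdaR2 <- function(Yc, Xc) {
  if (ncol(Xc) == 0L) return(0)
  fit <- qr.fitted(qr(Xc), Yc)
  sum(fit^2) / sum(Yc^2)
}

.checkFullRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    stop(sprintf("collinearity error: aliased predictor%s %s",
                 if (length(aliased) > 1) "s" else "",
                 paste(sQuote(aliased), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Ezekiel adjusted R-squared
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param m number of predictors.
#' @return \code{1 - (1 - r2) * (n - 1) / (n - m - 1)}.
#' @export
adjustedR2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

.prepYX <- function(Y, X) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- if (is.null(X) || NCOL(X) == 0L) {
    matrix(0, nrow(Y), 0)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
    standardizeColumns(X)
  }
  list(Yc = Yc, Xc = Xc)
}

#' Redundancy analysis with permutation test
#'
#' Multivariate least squares of the centered response on the standardized
#' predictors; R-squared is the trace of the fitted sum of squares over
#' the total, the adjusted R-squared is Ezekiel's, and significance comes
#' from permuting response rows.
#'
#' @param Y site x response numeric matrix (a single column for alpha
#'   diversity, retained PCoA axes for beta).
#' @param X site x predictor numeric matrix (full rank).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{r2}, \code{adjR2}, \code{F} (pseudo-F) and
#'   \code{p}.
#' @export
rdaFit <- function(Y, X, nPerm = 999L, seed = 1L) {
  if (nPerm < 1) stop("invalid argument: nPerm must be >= 1")
  pp <- .prepYX(Y, X)
  n <- nrow(pp$Yc)
  m <- ncol(pp$Xc)
  if (n <= m + 1) stop("invalid argument: need n > m + 1 observations")
  .checkFullRank(pp$Xc)
  r2 <- .rdaR2(pp$Yc, pp$Xc)
  Fobs <- (r2 / m) / ((1 - r2) / (n - m - 1))
  set.seed(seed)
  r2Perm <- vapply(seq_len(nPerm), function(i)
    .rdaR2(pp$Yc[sample.int(n), , drop = FALSE], pp$Xc), numeric(1))
  list(r2 = r2, adjR2 = adjustedR2(r2, n, m), F = Fobs,
       p = (1 + sum(r2Perm >= r2)) / (nPerm + 1))
}

#' Forward selection of RDA predictors with double stopping
#'
#' The global (all-candidate) model is tested first; if it is not
#' significant at \code{alpha} the selection is empty. Otherwise
#' candidates are added one at a time — always the one with the largest
#' added unadjusted R-squared — as long as its residual-permutation
#' p-value is below \code{alpha}; selection also halts once the
#' cumulative adjusted R-squared reaches the global model's (the variable
#' that crossed the line is kept — a single strong predictor can
#' legitimately beat the noise-penalized global adjusted R-squared). The
#' per-step added R-squared is the "individual contribution" of the
#' variable.
#'
#' @param Y site x response matrix.
#' @param candidates site x candidate-predictor matrix with column names.
#' @param alpha significance threshold for entry (default 0.05).
#' @param nPerm number of permutations per test.
#' @param seed integer seed.
#' @param adjR2Cap apply the global adjusted-R2 cap (double stopping,
#'   default TRUE).
#' @return an \code{\link{OrdinationModel}}.
#' @export
forwardSelect <- function(Y, candidates, alpha = 0.05, nPerm = 999L,
                          seed = 1L, adjR2Cap = TRUE) {
  pp <- .prepYX(Y, candidates)
  Yc <- pp$Yc; Xall <- pp$Xc
  n <- nrow(Yc)
  .checkFullRank(Xall)
  glob <- rdaFit(Y, candidates, nPerm = nPerm, seed = seed)
  sel <- character(); addedR2 <- stepP <- cumAdj <- numeric()
  if (glob$p < alpha) {
    remaining <- colnames(Xall)
    r2Cur <- 0
    set.seed(seed + 1L)
    repeat {
      if (length(remaining) == 0L) break
      if (n <= length(sel) + 2L) break        # no dof left for another term
      r2With <- vapply(remaining, function(v)
        .rdaR2(Yc, Xall[, c(sel, v), drop = FALSE]), numeric(1))
      bestVar <- remaining[which.max(r2With)]
      added <- max(r2With) - r2Cur
      ## residual permutation: shuffle rows of Y residualized on the
      ## current model, test the added R2 of the best candidate
      Xsel <- Xall[, sel, drop = FALSE]
      Yres <- if (length(sel)) Yc - qr.fitted(qr(Xsel), Yc) else Yc
      Xtry <- Xall[, c(sel, bestVar), drop = FALSE]
      addedPerm <- vapply(seq_len(nPerm), function(i) {
        Yp <- Yres[sample.int(n), , drop = FALSE]
        .rdaR2(Yp, Xtry) - .rdaR2(Yp, Xsel)
      }, numeric(1))
      pAdd <- (1 + sum(addedPerm >= added)) / (nPerm + 1)
      if (!(pAdd < alpha || alpha >= 1)) break
      adjNew <- adjustedR2(r2Cur + added, n, length(sel) + 1L)
      sel <- c(sel, bestVar)
      remaining <- setdiff(remaining, bestVar)
      addedR2 <- c(addedR2, added)
      stepP <- c(stepP, pAdd)
      cumAdj <- c(cumAdj, adjNew)
      r2Cur <- r2Cur + added
      ## double stopping: once the cumulative adjusted R2 reaches the
      ## global model's, the model cannot be legitimately enlarged; the
      ## variable that crossed the line is kept, further entries stop
      if (adjR2Cap && adjNew > glob$adjR2 + 1e-12) break
    }
  }
  finalAdj <- if (length(sel)) cumAdj[length(cumAdj)] else 0
  new("OrdinationModel", selected = sel, addedR2 = addedR2, stepP = stepP,
      cumAdjR2 = cumAdj, globalAdjR2 = glob$adjR2, globalP = glob$p,
      finalAdjR2 = finalAdj, nPerm = as.integer(nPerm))
}

#' Partial RDA fraction of X given Z
#'
#' The testable fraction is \code{adjR2(X union Z) - adjR2(Z)};
#' significance comes from permuting the rows of the response residualized
#' on the conditioning set.
#'
#' @param Y site x response matrix.
#' @param X site x predictor matrix of interest.
#' @param Z site x conditioning-predictor matrix (may be NULL/empty).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{fraction} (adjusted-R2 difference) and
#'   \code{p}.
#' @export
partialRda <- function(Y, X, Z = NULL, nPerm = 999L, seed = 1L) {
  ppX <- .prepYX(Y, X); ppZ <- .prepYX(Y, Z)
  Yc <- ppX$Yc
  n <- nrow(Yc)
  XZ <- cbind(ppX$Xc, ppZ$Xc)
  ## X may overlap span(Z); effective predictor counts are matrix ranks
  mZ <- if (ncol(ppZ$Xc)) qr(ppZ$Xc)$rank else 0L
  mXZ <- qr(XZ)$rank
  r2Z <- .rdaR2(Yc, ppZ$Xc)
  r2XZ <- .rdaR2(Yc, XZ)
  frac <- adjustedR2(r2XZ, n, mXZ) -
    (if (mZ) adjustedR2(r2Z, n, mZ) else 0)
  Yres <- if (ncol(ppZ$Xc)) Yc - qr.fitted(qr(ppZ$Xc), Yc) else Yc
  added <- r2XZ - r2Z
  set.seed(seed)
  addedPerm <- vapply(seq_len(nPerm), function(i) {
    Yp <- Yres[sample.int(n), , drop = FALSE]
    .rdaR2(Yp, XZ) - .rdaR2(Yp, ppZ$Xc)
  }, numeric(1))
  list(fraction = frac, p = (1 + sum(addedPerm >= added)) / (nPerm + 1))
}

#' Two-set variation partitioning on adjusted R-squared
#'
#' Decomposes the variance of the response explained by environment (E)
#' and space (S) into pure environment a = adjR2(E+S) - adjR2(S), pure
#' space c = adjR2(E+S) - adjR2(E), joint b = adjR2(E) + adjR2(S) -
#' adjR2(E+S) and unexplained d = 1 - adjR2(E+S). Negative fractions
#' (possible with adjusted R-squared) are reported as-is.
#'
#' @param Y site x response matrix.
#' @param E site x environment-predictor matrix (may be NULL/empty).
#' @param S site x space-predictor matrix (may be NULL/empty).
#' @param label optional text label (facet/scale) stored on the result.
#' @return a \code{\link{VarpartFractions}}.
#' @export
varpart2 <- function(Y, E = NULL, S = NULL, label = character()) {
  ppE <- .prepYX(Y, E); ppS <- .prepYX(Y, S)
  Yc <- ppE$Yc
  n <- nrow(Yc)
  adj <- function(Xc) if (ncol(Xc) == 0L) 0
    else adjustedR2(.rdaR2(Yc, Xc), n, ncol(Xc))
  ES <- cbind(ppE$Xc, ppS$Xc)
  if (ncol(ES)) {
    ## E and S may share structure (or columns); keep a full-rank basis of
    ## the union so adjR2 uses the effective number of predictors
    q <- qr(ES)
    ES <- ES[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  aE <- adj(ppE$Xc); aS <- adj(ppS$Xc); aES <- adj(ES)
  f <- c(a = aES - aS, b = aE + aS - aES, c = aES - aE, d = 1 - aES)
  new("VarpartFractions", fractions = f,
      label = as.character(label))
}
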