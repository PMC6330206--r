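## Spatial predictors and diagnostics: great-circle distances, PCNM
## eigenvectors from a truncated distance matrix, Moran's I and Mantel
## correlograms with permutation tests, and residualization of responses
## on environmental predictors.

#' @importFrom grDevices nclass.Sturges
NULL

#' Great-circle distances between sites
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords data.frame with columns \code{site}, \code{lon},
#'   \code{lat} (decimal degrees).
#' @return symmetric site x site distance matrix (km).
#' @export
geoDistances <- function(coords) {
  stopifnot(all(c("site", "lon", "lat") %in% names(coords)))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
  D <- .haversineKm(coords$lon, coords$lat)
  dimnames(D) <- list(coords$site, coords$site)
  D
}

## longest edge of the minimum spanning tree (Prim's algorithm)
.mstMaxEdge <- function(D) {
  n <- nrow(D)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  maxEdge <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!inTree)
    j <- cand[which.min(best[cand])]
    maxEdge <- max(maxEdge, best[j])
    inTree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  maxEdge
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Builds spatial eigenvector predictors: distances above the truncation
#' threshold are replaced by four times the threshold, the modified
#' distance matrix is double-centered as in principal coordinate analysis,
#' and the eigenvectors with positive eigenvalues are retained (eigenvalue
#' > 1e-8 times the largest). With \code{truncation = "auto"} the
#' threshold is the longest edge of the minimum spanning tree, which keeps
#' the site graph connected.
#'
#' @param D symmetric site x site distance matrix (km).
#' @param truncation positive threshold in km, or \code{"auto"}.
#' @return a \code{\link{PCNMBasis}}; score columns are unit-norm
#'   eigenvectors named PCNM1, PCNM2, ... in descending-eigenvalue order,
#'   each annotated with its Moran's I on the truncation-neighbour graph.
#' @seealso \code{\link{positiveMoranScores}} for the subset modelling
#'   positive spatial autocorrelation.
#' @export
pcnm <- function(D, truncation = "auto") {
  D <- as.matrix(D)
  if (max(D) == 0) stop("degenerate geometry: all sites coincide")
  if (nrow(D) < 3) stop("invalid argument: need at least 3 sites")
  t0 <- if (identical(truncation, "auto")) .mstMaxEdge(D)
        else as.numeric(truncation)
  if (t0 <= 0) stop("invalid argument: truncation must be positive")
  Dstar <- ifelse(D > t0, 4 * t0, D)
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  keep <- which(eg$values > 1e-8 * max(eg$values))
  V <- eg$vectors[, keep, drop = FALSE]
  colnames(V) <- sprintf("PCNM%d", seq_along(keep))
  rownames(V) <- rownames(D)
  ## Moran's I of each vector on the truncation-neighbour graph, to tell
  ## broad-scale (positive-autocorrelation) vectors from fine-scale ones
  W <- (D <= t0) & (D > 0)
  mode(W) <- "numeric"
  sw <- sum(W)
  mor <- apply(V, 2, function(z) {
    z <- z - mean(z)
    (n / sw) * drop(z %*% W %*% z) / sum(z * z)
  })
  new("PCNMBasis", scores = V, eigenvalues = eg$values[keep],
      truncation = t0, moran = mor)
}

#' PCNM vectors with positive spatial autocorrelation
#'
#' Subsets a PCNM basis to the vectors whose Moran's I exceeds its null
#' expectation -1/(n-1); these model broad-scale positive autocorrelation
#' and are the usual spatial predictor set.
#'
#' @param basis a \code{\link{PCNMBasis}}.
#' @return site x vector score matrix (possibly fewer columns than the
#'   full basis).
#' @export
positiveMoranScores <- function(basis) {
  stopifnot(is(basis, "PCNMBasis"))
  n <- nrow(basis@scores)
  basis@scores[, basis@moran > -1 / (n - 1), drop = FALSE]
}

## equal-width distance classes over (0, max(D)]
.distClasses <- function(D, nClasses = "auto") {
  dv <- D[lower.tri(D)]
  k <- if (identical(nClasses, "auto")) nclass.Sturges(dv)
       else as.integer(nClasses)
  if (k < 1) stop("invalid argument: need at least 1 distance class")
  breaks <- seq(0, max(dv), length.out = k + 1)
  mids <- (breaks[-1] + breaks[-(k + 1)]) / 2
  cls <- matrix(NA_integer_, nrow(D), ncol(D))
  idx <- findInterval(D, breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[D == 0] <- NA_integer_                  # diagonal / coincident
  cls[] <- idx
  list(cls = cls, mids = mids, k = k)
}

.twoTailP <- function(obs, perm) {
  n <- length(perm)
  pGe <- (1 + sum(perm >= obs)) / (n + 1)
  pLe <- (1 + sum(perm <= obs)) / (n + 1)
  min(1, 2 * min(pGe, pLe))
}

#' Moran's I correlogram of a per-site variable
#'
#' For each distance class c with binary weights w_ij = 1 iff d_ij falls
#' in the class: \code{I_c = (n / W) * sum(w_ij z_i z_j) / sum(z_i^2)}
#' with z the centered values. Significance per class is a two-tailed
#' permutation test shuffling the values across sites. Classes with no
#' pairs are dropped with a warning.
#'
#' @param values numeric per-site vector (n >= 10).
#' @param D site x site distance matrix (km).
#' @param nClasses number of equal-width distance classes, or
#'   \code{"auto"} (Sturges' rule on the pairwise distances).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return a \code{\link{Correlogram}} with statistic \code{"moran"}.
#' @export
moransICorrelogram <- function(values, D, nClasses = "auto", nPerm = 199L,
                               seed = 1L) {
  n <- length(values)
  if (n < 10) stop("invalid argument: need at least 10 sites")
  if (nPerm < 1) stop("invalid argument: nPerm must be >= 1")
  if (sd(values) == 0) stop("degenerate input: values are constant")
  cc <- .distClasses(D, nClasses)
  moranI <- function(z, W, sw) {
    (n / sw) * drop(z %*% W %*% z) / sum(z * z)
  }
  set.seed(seed)
  perms <- replicate(nPerm, sample.int(n))
  rows <- list()
  for (c in seq_len(cc$k)) {
    W <- (cc$cls == c) & !is.na(cc$cls)
    mode(W) <- "numeric"
    sw <- sum(W)
    if (sw == 0) {
      warning(sprintf("distance class %d (mid %.1f km) has no pairs; dropped",
                      c, cc$mids[c]))
      next
    }
    z <- values - mean(values)
    iObs <- moranI(z, W, sw)
    iPerm <- apply(perms, 2, function(p) moranI(z[p], W, sw))
    rows[[length(rows) + 1]] <-
      data.frame(class_mid_km = cc$mids[c], statistic = iObs,
                 p = .twoTailP(iObs, iPerm), n_pairs = sw / 2)
  }
  new("Correlogram", table = do.call(rbind, rows), statistic = "moran")
}

#' Mantel correlogram of a dissimilarity matrix
#'
#' For each distance class, the Pearson correlation between the
#' dissimilarity entries and the binary class-membership indicator over
#' all site pairs, sign-flipped so positive values mean positive spatial
#' autocorrelation; significance by permutation of site labels (rows and
#' columns of the dissimilarity permuted together), two-tailed.
#'
#' @param beta symmetric site x site dissimilarity matrix.
#' @param D site x site distance matrix (km), conformable with beta.
#' @param nClasses number of distance classes or \code{"auto"}.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @return a \code{\link{Correlogram}} with statistic \code{"mantel"}.
#' @export
mantelCorrelogram <- function(beta, D, nClasses = "auto", nPerm = 199L,
                              seed = 1L) {
  beta <- as.matrix(beta)
  if (!all(dim(beta) == dim(D)))
    stop("beta and distance matrices are not conformable")
  if (nPerm < 1) stop("invalid argument: nPerm must be >= 1")
  cc <- .distClasses(D, nClasses)
  lt <- lower.tri(beta)
  bv <- beta[lt]
  n <- nrow(beta)
  set.seed(seed)
  perms <- replicate(nPerm, sample.int(n))
  rows <- list()
  for (c in seq_len(cc$k)) {
    ind <- (cc$cls == c) & !is.na(cc$cls)
    npairs <- sum(ind[lt])
    if (npairs == 0) {
      warning(sprintf("distance class %d (mid %.1f km) has no pairs; dropped",
                      c, cc$mids[c]))
      next
    }
    iv <- ind[lt]
    ## sign flipped so that positive spatial autocorrelation (nearby sites
    ## less dissimilar than average) reads as positive r, the standard
    ## correlogram convention
    rObs <- -cor(bv, iv)
    rPerm <- apply(perms, 2, function(p) -cor(beta[p, p][lt], iv))
    rows[[length(rows) + 1]] <-
      data.frame(class_mid_km = cc$mids[c], statistic = rObs,
                 p = .twoTailP(rObs, rPerm), n_pairs = npairs)
  }
  new("Correlogram", table = do.call(rbind, rows), statistic = "mantel")
}

#' Residualize per-site values on environmental predictors
#'
#' Least-squares residuals of the values on the predictor columns (with
#' intercept); used for residual correlograms after accounting for
#' environment.
#'
#' @param values numeric per-site vector.
#' @param X site x predictor numeric matrix.
#' @return residual vector.
#' @export
residualize <- function(values, X) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop("collinearity error: predictors are rank-deficient")
  resid(lm(values ~ X))
}

#' Residualize a dissimilarity matrix on environmental distances
#'
#' Distance-based regression: the vectorized dissimilarities are regressed
#' on the vectorized environmental distance matrices (Mantel residuals),
#' and the residuals reassembled into a symmetric zero-diagonal matrix.
#'
#' @param beta symmetric site x site dissimilarity matrix.
#' @param envDistList one distance matrix or a list of them.
#' @return residual dissimilarity matrix (entries may be negative).
#' @export
residualizeBeta <- function(beta, envDistList) {
  beta <- as.matrix(beta)
  if (is.matrix(envDistList)) envDistList <- list(envDistList)
  lt <- lower.tri(beta)
  X <- vapply(envDistList, function(m) as.matrix(m)[lt],
              numeric(sum(lt)))
  X <- matrix(X, ncol = length(envDistList))
  if (qr(X)$rank < ncol(X))
    stop("collinearity error: environmental distance predictors are rank-deficient")
  r <- resid(lm(beta[lt] ~ X))
  out <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  out[lt] <- r
  out <- out + t(out)
  out
}
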