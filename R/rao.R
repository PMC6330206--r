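## Rao quadratic-entropy alpha/beta partitioning for presence/absence
## communities, with the Jost equivalent-number correction.
##
## Alpha for a site with S present species uses uniform weights p_i = 1/S:
##   alpha = sum_ij p_i p_j d_ij.
## Pairwise gamma uses the mean of the two sites' within-site weights,
## and proportional beta = (gamma_eq - mean(alpha_eq)) / gamma_eq with the
## Jost correction x -> 1/(1 - x) applied to gamma and to each alpha
## before averaging. Functional/phylogenetic distances are rescaled to
## max 1 across the species pool so raw Rao values stay inside [0, 1),
## the domain of the correction.

.presentIdx <- function(row) which(row > 0)

#' Raw Rao alpha diversity of one site
#'
#' Expected distance between two individuals drawn (with replacement) from
#' a site, under uniform presence weights 1/S.
#'
#' @param row 0/1 incidence vector for one site, named by species.
#' @param D a \code{\link{FacetDist}} covering all present species.
#' @return raw Rao alpha (same units as the distances).
#' @examples
#' D <- taxonomicDistance(letters[1:4])
#' raoAlpha(setNames(c(1, 1, 1, 1), letters[1:4]), D)  # 1 - 1/4
#' @export
raoAlpha <- function(row, D) {
  stopifnot(is(D, "FacetDist"))
  present <- names(row)[.presentIdx(row)]
  if (length(present) < 2)
    stop("undefined alpha: site has fewer than 2 species present")
  if (!all(present %in% rownames(distMatrix(D))))
    stop("distance matrix does not cover all present species")
  d <- distMatrix(D)[present, present]
  sum(d) / length(present)^2
}

#' Jost equivalent-number correction
#'
#' Converts a concave diversity value in [0, 1) to an effective number of
#' species via 1 / (1 - x). For the taxonomic facet this maps a site's raw
#' Rao alpha (1 - 1/S) to its richness S exactly.
#'
#' @param x raw diversity value(s) in [0, 1).
#' @return equivalent-number value(s), always >= 1.
#' @export
jostCorrect <- function(x) {
  if (any(x >= 1) || any(x < 0))
    stop("domain error: Jost correction requires values in [0, 1)")
  1 / (1 - x)
}

#' Pairwise proportional Rao beta between two sites
#'
#' Gamma of the pair uses species weights equal to the mean of the two
#' sites' uniform within-site weights. Beta is the proportional excess of
#' Jost-corrected gamma over the mean of the Jost-corrected alphas:
#' \code{(gamma_eq - mean_alpha_eq) / gamma_eq}.
#'
#' @param rowK,rowL 0/1 incidence vectors (named by species) of the two
#'   sites.
#' @param D a \code{\link{FacetDist}}; for functional/phylogenetic facets
#'   the distances should already be rescaled to max 1 (see
#'   \code{\link{rescaleDistances}}).
#' @return list with \code{beta}, \code{gammaRaw}, \code{gammaEq},
#'   \code{meanAlphaEq}.
#' @export
raoBetaPairwise <- function(rowK, rowL, D) {
  stopifnot(is(D, "FacetDist"))
  aK <- raoAlpha(rowK, D)
  aL <- raoAlpha(rowL, D)
  d <- distMatrix(D)
  w <- (rowK[rownames(d)] / sum(rowK > 0) +
        rowL[rownames(d)] / sum(rowL > 0)) / 2
  w[is.na(w)] <- 0
  gammaRaw <- drop(w %*% d %*% w)
  gammaEq <- jostCorrect(gammaRaw)
  meanAlphaEq <- mean(jostCorrect(c(aK, aL)))
  beta <- max(0, (gammaEq - meanAlphaEq) / gammaEq)
  list(beta = beta, gammaRaw = gammaRaw, gammaEq = gammaEq,
       meanAlphaEq = meanAlphaEq)
}

#' Rescale a species distance matrix to maximum 1
#'
#' Keeps raw Rao values inside [0, 1) so the Jost correction is defined.
#' Taxonomic distances are already 0/1 and are returned unchanged.
#'
#' @param D a \code{\link{FacetDist}}.
#' @return a \code{\link{FacetDist}} with maximum off-diagonal distance 1.
#' @export
rescaleDistances <- function(D) {
  stopifnot(is(D, "FacetDist"))
  m <- max(distMatrix(D))
  if (m == 0 || facet(D) == "taxonomic") return(D)
  new("FacetDist", distances = distMatrix(D) / m, facet = facet(D))
}

#' Full alpha/beta diversity profile of a community matrix
#'
#' Computes per-site raw and Jost-corrected Rao alpha and the full matrix
#' of pairwise proportional beta values for one facet.
#'
#' @param comm sites x species 0/1 matrix with dimnames; every site must
#'   hold at least 2 species.
#' @param D a \code{\link{FacetDist}} covering all species of \code{comm}.
#' @param rescale rescale functional/phylogenetic distances to max 1
#'   first (default TRUE).
#' @return a \code{\link{DiversityProfile}}.
#' @export
diversityProfile <- function(comm, D, rescale = TRUE) {
  stopifnot(is(D, "FacetDist"), is.matrix(comm))
  if (is.null(colnames(comm)) || is.null(rownames(comm)))
    stop("community matrix needs species (column) and site (row) names")
  if (!all(colnames(comm) %in% rownames(distMatrix(D))))
    stop("distance matrix does not cover all community species")
  if (rescale) D <- rescaleDistances(D)
  d <- distMatrix(D)[colnames(comm), colnames(comm)]
  n <- nrow(comm)
  S <- rowSums(comm > 0)
  if (any(S < 2))
    stop(sprintf("undefined alpha: site%s %s ha%s fewer than 2 species",
                 if (sum(S < 2) > 1) "s" else "",
                 paste(rownames(comm)[S < 2], collapse = ", "),
                 if (sum(S < 2) > 1) "ve" else "s"))
  W <- comm / S                               # within-site uniform weights
  ## alpha_k = w_k' d w_k, all sites at once
  Wd <- W %*% d
  alphaRaw <- rowSums(Wd * W)
  alphaEq <- jostCorrect(alphaRaw)
  ## pairwise gamma with mean weights:
  ## g_kl = mbar' d mbar = (a_k + a_l + 2 w_k' d w_l) / 4
  crossTerm <- Wd %*% t(W)
  gammaRaw <- (outer(alphaRaw, alphaRaw, "+") + 2 * crossTerm) / 4
  gammaEq <- jostCorrect(gammaRaw)
  meanAlphaEq <- outer(alphaEq, alphaEq, "+") / 2
  beta <- (gammaEq - meanAlphaEq) / gammaEq
  beta <- (beta + t(beta)) / 2                # kill FP asymmetry
  ## the Jost correction is convex, so pairs with very uneven alpha can
  ## yield corrected gamma below the mean corrected alpha; such negative
  ## excess carries no turnover signal and is truncated at 0
  beta[beta < 0] <- 0
  diag(beta) <- 0
  dimnames(beta) <- list(rownames(comm), rownames(comm))
  dimnames(gammaRaw) <- dimnames(beta)
  new("DiversityProfile", facet = facet(D), alphaRaw = alphaRaw,
      alphaEq = alphaEq, beta = beta, gammaRaw = gammaRaw)
}
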