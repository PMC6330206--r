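## Trait coding, standardization, correlation-matrix PCA reduction, and the
## taxonomic / functional species distance constructions.

#' Pivot a long trait table to a species x trait character matrix
#'
#' @param traits long-format trait table (columns species, trait, value,
#'   kind), one row per species x trait.
#' @return character matrix, species as rows.
#' @export
traitMatrix <- function(traits) {
  sp <- unique(traits$species)
  tr <- unique(traits$trait)
  m <- matrix(NA_character_, length(sp), length(tr),
              dimnames = list(sp, tr))
  m[cbind(match(traits$species, sp), match(traits$trait, tr))] <- traits$value
  if (anyNA(m)) stop("trait table is incomplete (missing species x trait cells)")
  m
}

#' Re-code qualitative traits as numbers
#'
#' Qualitative trait categories are replaced by user-supplied numeric
#' codes; quantitative traits pass through unchanged. The coding map is a
#' data.frame with columns \code{trait}, \code{category}, \code{code}
#' (see \code{\link{readCodingMap}} for the CSV form).
#'
#' @param traits long-format trait table (species, trait, value, kind).
#' @param codingMap data.frame(trait, category, code); may be empty when
#'   all traits are quantitative.
#' @return fully numeric species x trait matrix.
#' @export
encodeTraits <- function(traits, codingMap = NULL) {
  m <- traitMatrix(traits)
  kind <- vapply(colnames(m), function(tr)
    traits$kind[match(tr, traits$trait)], character(1))
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    if (kind[j] == "quantitative") {
      out[, j] <- as.numeric(m[, j])
    } else {
      cm <- codingMap[codingMap$trait == colnames(m)[j], , drop = FALSE]
      idx <- match(m[, j], cm$category)
      if (anyNA(idx)) {
        bad <- unique(m[, j][is.na(idx)])
        stop(sprintf("coding error: trait '%s' has unmapped categor%s %s",
                     colnames(m)[j], if (length(bad) > 1) "ies" else "y",
                     paste(sQuote(bad), collapse = ", ")))
      }
      out[, j] <- cm$code[idx]
    }
  }
  out
}

#' Read a trait coding map from CSV
#'
#' Expected columns: \code{trait}, \code{category}, \code{code}.
#'
#' @param path CSV file path.
#' @return data.frame(trait, category, code).
#' @export
readCodingMap <- function(path) {
  cm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "category", "code")
  if (!all(need %in% names(cm)))
    stop("coding map must have columns trait, category, code")
  cm$code <- as.numeric(cm$code)
  cm
}

#' Z-score the columns of a numeric matrix
#'
#' @param m numeric entities x variables matrix.
#' @return matrix with each column centered to mean 0 and scaled to sample
#'   standard deviation 1.
#' @export
standardizeColumns <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, sd)
  zero <- which(sds < .Machine$double.eps^0.5 * (1 + abs(colMeans(m))))
  if (length(zero))
    stop(sprintf("degenerate column%s with zero variance: %s",
                 if (length(zero) > 1) "s" else "",
                 paste(sQuote(colnames(m)[zero]), collapse = ", ")))
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Correlation-matrix PCA with cumulative-variance axis retention
#'
#' Eigen-decomposes the correlation matrix of a z-scored table and retains
#' the smallest number of leading axes whose cumulative proportion of
#' variance reaches \code{varianceThreshold}. Scores are the projections
#' of the (centered, unit-variance) data onto the eigenvectors.
#'
#' @param m z-scored entities x variables matrix (see
#'   \code{\link{standardizeColumns}}).
#' @param varianceThreshold cumulative-variance cut-off in (0, 1];
#'   default 0.90.
#' @return a \code{\link{PCAReduction}}.
#' @export
pcaReduce <- function(m, varianceThreshold = 0.90) {
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("invalid argument: varianceThreshold must lie in (0, 1]")
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("invalid argument: need at least 2 entities")
  R <- cor(m)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  prop <- ev / sum(ev)
  k <- which(cumsum(prop) >= varianceThreshold - 1e-12)[1]
  scores <- m %*% eg$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  rownames(scores) <- rownames(m)
  loadings <- eg$vectors[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(m), colnames(scores))
  new("PCAReduction", scores = scores, eigenvalues = ev, varProp = prop,
      loadings = loadings, nRetained = as.integer(k),
      threshold = varianceThreshold)
}

#' Functional species distances from reduced trait axes
#'
#' Euclidean distances between species in the retained PCA axis space of
#' their (coded, standardized) traits.
#'
#' @param reduction a \code{\link{PCAReduction}} whose rows are species.
#' @return a \code{\link{FacetDist}} with facet \code{"functional"}.
#' @export
functionalDistance <- function(reduction) {
  stopifnot(is(reduction, "PCAReduction"))
  d <- as.matrix(dist(axisScores(reduction)))
  new("FacetDist", distances = d, facet = "functional")
}

#' Taxonomic species distances (species identity)
#'
#' Distance 1 between distinct species, 0 on the diagonal.
#'
#' @param species character vector of unique species identifiers.
#' @return a \code{\link{FacetDist}} with facet \code{"taxonomic"}.
#' @export
taxonomicDistance <- function(species) {
  if (anyDuplicated(species))
    stop("invalid argument: species identifiers must be unique")
  n <- length(species)
  d <- matrix(1, n, n, dimnames = list(species, species))
  diag(d) <- 0
  new("FacetDist", distances = d, facet = "taxonomic")
}
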