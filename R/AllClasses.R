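#' @import methods
#' @importFrom stats sd var cor dist optimize rnorm runif rbinom quantile
#'   lm resid pchisq setNames
#' @importFrom utils head
NULL

.FACETS <- c("taxonomic", "functional", "phylogenetic")

#' Species distance matrix tagged with a diversity facet
#'
#' A symmetric, zero-diagonal, non-negative species-by-species distance
#' matrix together with the diversity facet it represents. Taxonomic
#' distances are 0/1 (species identity), functional distances are Euclidean
#' distances in a reduced trait space, and phylogenetic distances are
#' cophenetic (patristic) distances on an ultrametric tree.
#'
#' @slot distances numeric matrix, species x species, symmetric with zero
#'   diagonal and non-negative entries; dimnames are species identifiers.
#' @slot facet one of \code{"taxonomic"}, \code{"functional"},
#'   \code{"phylogenetic"}.
#'
#' @seealso \code{\link{taxonomicDistance}}, \code{\link{functionalDistance}},
#'   \code{\link{copheneticDistances}}
#' @export
setClass("FacetDist",
  representation(distances = "matrix", facet = "character"))

setValidity("FacetDist", function(object) {
  d <- object@distances
  msg <- character()
  if (!is.numeric(d) || nrow(d) != ncol(d))
    msg <- c(msg, "'distances' must be a square numeric matrix")
  if (length(object@facet) != 1L || !object@facet %in% .FACETS)
    msg <- c(msg, sprintf("'facet' must be one of: %s",
                          paste(.FACETS, collapse = ", ")))
  if (is.numeric(d) && nrow(d) == ncol(d)) {
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
      msg <- c(msg, "species identifiers (dimnames) must be unique and present")
    if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
    if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (identical(object@facet, "taxonomic") && !all(d %in% c(0, 1)))
      msg <- c(msg, "taxonomic distances must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Rao diversity profile for one facet
#'
#' Per-site Rao quadratic-entropy alpha diversity (raw and as Jost
#' equivalent numbers) together with the site-by-site pairwise proportional
#' beta matrix, for a single diversity facet.
#'
#' @slot facet diversity facet the profile was computed under.
#' @slot alphaRaw named numeric, per-site raw Rao alpha (units of the
#'   species distances; in [0, 1) after distance rescaling).
#' @slot alphaEq named numeric, Jost-corrected alpha (equivalent numbers,
#'   always >= 1; equals site richness exactly for the taxonomic facet).
#' @slot beta symmetric site x site matrix of pairwise proportional beta
#'   in [0, 1).
#' @slot gammaRaw symmetric site x site matrix of raw pairwise gamma.
#'
#' @seealso \code{\link{diversityProfile}}
#' @export
setClass("DiversityProfile",
  representation(facet = "character", alphaRaw = "numeric",
                 alphaEq = "numeric", beta = "matrix", gammaRaw = "matrix"))

setValidity("DiversityProfile", function(object) {
  msg <- character()
  n <- length(object@alphaRaw)
  if (!object@facet %in% .FACETS) msg <- c(msg, "invalid facet tag")
  if (length(object@alphaEq) != n) msg <- c(msg, "alpha vectors differ in length")
  if (!all(dim(object@beta) == n)) msg <- c(msg, "beta must be n x n")
  else {
    if (max(abs(object@beta - t(object@beta))) > 1e-10)
      msg <- c(msg, "beta must be symmetric")
    if (any(abs(diag(object@beta)) > 1e-12))
      msg <- c(msg, "beta diagonal must be zero")
    if (any(object@beta < -1e-12) || any(object@beta >= 1))
      msg <- c(msg, "beta must lie in [0, 1)")
  }
  if (any(object@alphaEq < 1 - 1e-10))
    msg <- c(msg, "Jost-corrected alpha must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Principal component reduction of a variable table
#'
#' Correlation-matrix PCA of a standardized entities-by-variables table,
#' keeping the smallest number of leading axes whose cumulative variance
#' reaches a configured threshold.
#'
#' @slot scores entities x retained-axes score matrix (column means zero).
#' @slot eigenvalues all eigenvalues of the correlation matrix,
#'   non-increasing; they sum to the number of variables.
#' @slot varProp proportion of total variance per axis (all axes).
#' @slot loadings variable loadings (eigenvectors) for the retained axes.
#' @slot nRetained number of retained axes.
#' @slot threshold the cumulative-variance threshold used.
#'
#' @seealso \code{\link{pcaReduce}}
#' @export
setClass("PCAReduction",
  representation(scores = "matrix", eigenvalues = "numeric",
                 varProp = "numeric", loadings = "matrix",
                 nRetained = "integer", threshold = "numeric"))

setValidity("PCAReduction", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues), strict = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (object@nRetained < 1L || object@nRetained > length(object@eigenvalues))
    msg <- c(msg, "nRetained out of range")
  if (ncol(object@scores) != object@nRetained)
    msg <- c(msg, "scores must have nRetained columns")
  if (ncol(object@scores) &&
      max(abs(colMeans(object@scores))) > 1e-8)
    msg <- c(msg, "axis scores must be centered")
  if (length(msg)) msg else TRUE
})

#' PCNM spatial eigenvector basis
#'
#' Principal coordinates of neighbour matrices: spatial eigenvectors with
#' positive eigenvalues obtained from a truncated geographic distance
#' matrix, used as multi-scale spatial predictors.
#'
#' @slot scores site x vector matrix, columns named PCNM1, PCNM2, ... in
#'   descending-eigenvalue order; columns centered and mutually orthogonal.
#' @slot eigenvalues positive eigenvalues, non-increasing.
#' @slot truncation truncation distance used (km).
#' @slot moran Moran's I of each vector on the truncation-neighbour graph;
#'   vectors with I above the expectation -1/(n-1) model positive spatial
#'   autocorrelation (broad-scale structure).
#'
#' @seealso \code{\link{pcnm}}
#' @export
setClass("PCNMBasis",
  representation(scores = "matrix", eigenvalues = "numeric",
                 truncation = "numeric", moran = "numeric"))

setValidity("PCNMBasis", function(object) {
  msg <- character()
  if (any(object@eigenvalues <= 0))
    msg <- c(msg, "all retained eigenvalues must be positive")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (ncol(object@scores) != length(object@eigenvalues))
    msg <- c(msg, "one score column per eigenvalue required")
  if (length(msg)) msg else TRUE
})

#' Spatial correlogram
#'
#' Distance-class-wise spatial statistics (Moran's I for per-site values,
#' Mantel r for dissimilarity matrices) with permutation p-values.
#'
#' @slot table data.frame with columns \code{class_mid_km},
#'   \code{statistic}, \code{p}, \code{n_pairs}.
#' @slot statistic \code{"moran"} or \code{"mantel"}.
#'
#' @seealso \code{\link{moransICorrelogram}}, \code{\link{mantelCorrelogram}}
#' @export
setClass("Correlogram",
  representation(table = "data.frame", statistic = "character"))

setValidity("Correlogram", function(object) {
  msg <- character()
  need <- c("class_mid_km", "statistic", "p", "n_pairs")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, sprintf("table must have columns %s",
                          paste(need, collapse = ", ")))
  else if (any(object@table$p <= 0 | object@table$p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Forward-selected RDA model
#'
#' Result of redundancy analysis with forward selection under the double
#' stopping rule (permutation p below alpha and cumulative adjusted
#' R-squared not exceeding the global model's).
#'
#' @slot selected character, predictors in selection order (may be empty).
#' @slot addedR2 per-step added unadjusted R-squared (the "individual
#'   contribution" as a fraction; multiply by 100 for percent).
#' @slot stepP per-step permutation p-value.
#' @slot cumAdjR2 cumulative adjusted R-squared after each step.
#' @slot globalAdjR2 adjusted R-squared of the global (all-candidate) model.
#' @slot globalP permutation p-value of the global model.
#' @slot finalAdjR2 adjusted R-squared of the selected model (0 if empty).
#' @slot nPerm number of permutations used.
#'
#' @seealso \code{\link{forwardSelect}}, \code{\link{rdaFit}}
#' @export
setClass("OrdinationModel",
  representation(selected = "character", addedR2 = "numeric",
                 stepP = "numeric", cumAdjR2 = "numeric",
                 globalAdjR2 = "numeric", globalP = "numeric",
                 finalAdjR2 = "numeric", nPerm = "integer"))

#' Two-set variation partitioning fractions
#'
#' Adjusted-R-squared decomposition of a response into pure environment
#' [a], jointly structured [b], pure space [c] and unexplained [d]
#' fractions; a + b + c + d = 1 by construction.
#'
#' @slot fractions named numeric of length 4: \code{a}, \code{b}, \code{c},
#'   \code{d}. Negative a, b or c can occur (adjusted R-squared is not
#'   bounded below) and are reported as-is.
#' @slot label free-text description (e.g. facet and scale).
#'
#' @seealso \code{\link{varpart2}}
#' @export
setClass("VarpartFractions",
  representation(fractions = "numeric", label = "character"))

setValidity("VarpartFractions", function(object) {
  msg <- character()
  if (!identical(names(object@fractions), c("a", "b", "c", "d")))
    msg <- c(msg, "fractions must be named a, b, c, d")
  else if (abs(sum(object@fractions) - 1) > 1e-10)
    msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})
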