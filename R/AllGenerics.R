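#' Diversity facet of an object
#'
#' @param x a \code{FacetDist} or \code{DiversityProfile}.
#' @return character scalar: \code{"taxonomic"}, \code{"functional"} or
#'   \code{"phylogenetic"}.
#' @export
setGeneric("facet", function(x) standardGeneric("facet"))

#' Species distance matrix stored in a FacetDist
#'
#' @param x a \code{FacetDist}.
#' @return the symmetric species x species distance matrix.
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' Per-site Rao alpha diversity
#'
#' @param x a \code{DiversityProfile}.
#' @param corrected logical; return Jost equivalent numbers (default) or
#'   raw Rao quadratic entropy.
#' @return named numeric vector of per-site alpha values.
#' @export
setGeneric("alphaDiversity",
           function(x, corrected = TRUE) standardGeneric("alphaDiversity"))

#' Pairwise proportional beta matrix
#'
#' @param x a \code{DiversityProfile}.
#' @return symmetric site x site matrix of Rao pairwise beta in [0, 1).
#' @export
setGeneric("betaDiversity", function(x) standardGeneric("betaDiversity"))

#' Axis scores of an ordination-like object
#'
#' @param x a \code{PCAReduction} or \code{PCNMBasis}.
#' @return entities x axes numeric score matrix.
#' @export
setGeneric("axisScores", function(x) standardGeneric("axisScores"))

#' Eigenvalues of an ordination-like object
#'
#' @param x a \code{PCAReduction} or \code{PCNMBasis}.
#' @return numeric vector of eigenvalues in non-increasing order.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' Variation-partitioning fractions
#'
#' @param x a \code{VarpartFractions}.
#' @return named numeric of length 4 (\code{a}, \code{b}, \code{c},
#'   \code{d}).
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' Predictors retained by forward selection
#'
#' @param x an \code{OrdinationModel}.
#' @return character vector of predictor names in selection order.
#' @export
setGeneric("selectedTerms", function(x) standardGeneric("selectedTerms"))
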