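#' @describeIn facet facet tag of a species distance matrix
#' @export
setMethod("facet", "FacetDist", function(x) x@facet)

#' @describeIn facet facet tag of a diversity profile
#' @export
setMethod("facet", "DiversityProfile", function(x) x@facet)

#' @describeIn distMatrix extract the distance matrix
#' @export
setMethod("distMatrix", "FacetDist", function(x) x@distances)

#' @describeIn alphaDiversity per-site alpha from a diversity profile
#' @export
setMethod("alphaDiversity", "DiversityProfile",
  function(x, corrected = TRUE) if (corrected) x@alphaEq else x@alphaRaw)

#' @describeIn betaDiversity pairwise beta from a diversity profile
#' @export
setMethod("betaDiversity", "DiversityProfile", function(x) x@beta)

#' @describeIn axisScores retained PCA axis scores
#' @export
setMethod("axisScores", "PCAReduction", function(x) x@scores)

#' @describeIn axisScores PCNM eigenvector scores
#' @export
setMethod("axisScores", "PCNMBasis", function(x) x@scores)

#' @describeIn eigenValues all correlation-matrix eigenvalues
#' @export
setMethod("eigenValues", "PCAReduction", function(x) x@eigenvalues)

#' @describeIn eigenValues positive PCNM eigenvalues
#' @export
setMethod("eigenValues", "PCNMBasis", function(x) x@eigenvalues)

#' @describeIn fractions the [a, b, c, d] adjusted-R2 fractions
#' @export
setMethod("fractions", "VarpartFractions", function(x) x@fractions)

#' @describeIn selectedTerms selection-order predictor names
#' @export
setMethod("selectedTerms", "OrdinationModel", function(x) x@selected)

setMethod("show", "FacetDist", function(object) {
  cat(sprintf("FacetDist: %s facet, %d species\n",
              object@facet, nrow(object@distances)))
  cat(sprintf("  distance range: [%.4g, %.4g]\n",
              min(object@distances), max(object@distances)))
})

setMethod("show", "DiversityProfile", function(object) {
  cat(sprintf("DiversityProfile: %s facet, %d sites\n",
              object@facet, length(object@alphaRaw)))
  cat(sprintf("  alpha (equivalent numbers): mean %.3f, range [%.3f, %.3f]\n",
              mean(object@alphaEq), min(object@alphaEq), max(object@alphaEq)))
  off <- object@beta[lower.tri(object@beta)]
  cat(sprintf("  pairwise beta: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
})

setMethod("show", "PCAReduction", function(object) {
  cat(sprintf("PCAReduction: %d of %d axes retained (threshold %.2f)\n",
              object@nRetained, length(object@eigenvalues),
              object@threshold))
  cat(sprintf("  cumulative variance of retained axes: %.1f%%\n",
              100 * sum(object@varProp[seq_len(object@nRetained)])))
})

setMethod("show", "PCNMBasis", function(object) {
  n <- nrow(object@scores)
  cat(sprintf(paste0("PCNMBasis: %d vectors with positive eigenvalues ",
                     "(%d with positive Moran's I), truncation %.3g km\n"),
              ncol(object@scores), sum(object@moran > -1 / (n - 1)),
              object@truncation))
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("Correlogram (%s), %d distance classes:\n",
              object@statistic, nrow(object@table)))
  print(object@table, row.names = FALSE)
})

setMethod("show", "OrdinationModel", function(object) {
  cat(sprintf("OrdinationModel: global adj.R2 = %.3f (p = %.4g), %d permutations\n",
              object@globalAdjR2, object@globalP, object@nPerm))
  if (length(object@selected) == 0L) {
    cat("  no predictors selected\n")
  } else {
    df <- data.frame(variable = object@selected,
                     contribution_pct = round(100 * object@addedR2, 2),
                     p = object@stepP,
                     cum_adjR2 = round(object@cumAdjR2, 3))
    print(df, row.names = FALSE)
  }
})

setMethod("show", "VarpartFractions", function(object) {
  cat(sprintf("VarpartFractions%s\n",
              if (length(object@label)) paste0(" [", object@label, "]") else ""))
  f <- object@fractions
  cat(sprintf("  pure environment [a] = %.3f\n  joint            [b] = %.3f\n  pure space       [c] = %.3f\n  unexplained      [d] = %.3f\n",
              f["a"], f["b"], f["c"], f["d"]))
})
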