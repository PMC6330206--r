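## End-to-end orchestration: CSV/newick I/O, cross-validation of the five
## input tables, and the full facet x scale analysis driven by one master
## seed.

#' Read a site x species community matrix from CSV
#'
#' Sites as rows (first column holds site identifiers), species as
#' columns.
#'
#' @param path CSV file path.
#' @return 0/1 integer matrix with dimnames.
#' @export
readCommunityCSV <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  mode(m) <- "integer"
  m
}

#' Read a long-format trait table from CSV
#'
#' Expected columns: \code{species}, \code{trait}, \code{value},
#' \code{kind}.
#'
#' @param path CSV file path.
#' @return data.frame in the package's long trait format.
#' @export
readTraitsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "trait", "value", "kind")
  if (!all(need %in% names(df)))
    stop("trait CSV must have columns species, trait, value, kind")
  df
}

#' Read a site x variable environment table from CSV
#'
#' @param path CSV file path; first column site identifiers. An optional
#'   \code{group} attribute (soil/clim) is reconstructed from column-name
#'   prefixes \code{soil}/\code{clim} when present.
#' @return numeric matrix with dimnames.
#' @export
readEnvCSV <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  grp <- ifelse(grepl("^soil", colnames(m)), "soil",
                ifelse(grepl("^clim", colnames(m)), "clim", NA))
  if (!anyNA(grp)) attr(m, "group") <- grp
  m
}

#' Read site coordinates from CSV
#'
#' Expected columns: \code{site}, \code{lon}, \code{lat}.
#'
#' @param path CSV file path.
#' @return data.frame(site, lon, lat).
#' @export
readCoordsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "lon", "lat") %in% names(df)))
    stop("coordinate CSV must have columns site, lon, lat")
  df
}

#' Write a synthetic dataset to disk
#'
#' Emits \code{tree.nwk}, \code{traits.csv}, \code{env.csv},
#' \code{coords.csv}, \code{community.csv} under \code{dir}.
#'
#' @param dataset list as produced by \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNewick(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$env), file.path(dir, "env.csv"))
  utils::write.csv(dataset$coords, file.path(dir, "coords.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$comm),
                   file.path(dir, "community.csv"))
  invisible(dir)
}

.issue <- function(severity, message)
  data.frame(severity = severity, message = message,
             stringsAsFactors = FALSE)

#' Cross-validate the five analysis inputs
#'
#' Checks species-set consistency (community vs. traits vs. tree tips),
#' site-set consistency (community vs. environment vs. coordinates) and
#' value domains. Nothing is thrown: the full issue list is returned with
#' severities so a caller sees every problem at once.
#'
#' @param comm sites x species 0/1 matrix.
#' @param traits long-format trait table.
#' @param tree \code{ape::phylo} tree.
#' @param env sites x variables numeric matrix.
#' @param coords data.frame(site, lon, lat).
#' @return data.frame(severity, message); zero rows when fully consistent.
#' @export
validateInputs <- function(comm, traits, tree, env, coords) {
  iss <- list()
  add <- function(sev, msg) iss[[length(iss) + 1]] <<- .issue(sev, msg)
  spComm <- colnames(comm)
  spTree <- tree$tip.label
  spTrait <- unique(traits$species)
  orphanTree <- setdiff(spComm, spTree)
  if (length(orphanTree))
    add("error", sprintf("species in community but not in tree: %s",
                         paste(orphanTree, collapse = ", ")))
  orphanTrait <- setdiff(spComm, spTrait)
  if (length(orphanTrait))
    add("error", sprintf("species in community but without traits: %s",
                         paste(orphanTrait, collapse = ", ")))
  siteComm <- rownames(comm)
  if (!setequal(siteComm, rownames(env)))
    add("error", "site sets of community and environment tables differ")
  if (!setequal(siteComm, coords$site))
    add("error", "site sets of community and coordinate tables differ")
  if (!all(comm %in% c(0L, 1L)))
    add("error", "community matrix must be 0/1 incidence")
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    add("error", "coordinates outside valid lon/lat domain")
  if (anyNA(env))
    add("error", "environment table has missing cells")
  thin <- siteComm[rowSums(comm > 0) < 2]
  if (length(thin))
    add("warning",
        sprintf("site%s %s ha%s fewer than 2 species; Rao alpha is undefined there",
                if (length(thin) > 1) "s" else "",
                paste(thin, collapse = ", "),
                if (length(thin) > 1) "ve" else "s"))
  lost <- spComm[colSums(comm > 0) == 0]
  if (length(lost))
    add("warning", sprintf("species never present: %s",
                           paste(lost, collapse = ", ")))
  if (length(iss)) do.call(rbind, iss)
  else data.frame(severity = character(), message = character(),
                  stringsAsFactors = FALSE)
}

.envBlocks <- function(env, varianceThreshold) {
  grp <- attr(env, "group")
  if (is.null(grp)) grp <- rep("env", ncol(env))
  blocks <- list()
  for (g in unique(grp)) {
    sub <- env[, grp == g, drop = FALSE]
    if (ncol(sub) > 1) {
      red <- pcaReduce(standardizeColumns(sub), varianceThreshold)
      sc <- axisScores(red)
      colnames(sc) <- sprintf("PC%d_%s", seq_len(ncol(sc)), g)
      blocks[[g]] <- sc
    } else {
      blocks[[g]] <- standardizeColumns(sub)
    }
  }
  do.call(cbind, blocks)
}

#' Mean pairwise Euclidean distance of an environmental variable group
#'
#' Heterogeneity summary: mean over site pairs of the Euclidean distance
#' computed on the z-scored variables of one group (e.g. soil vs.
#' climate).
#'
#' @param env sites x variables matrix carrying a \code{"group"}
#'   attribute (as from \code{\link{simulateLandscape}}), or any numeric
#'   matrix when \code{group} is NULL.
#' @param group group tag to subset on (e.g. \code{"soil"}).
#' @return list with \code{mean} and \code{se} (standard error over
#'   pairs).
#' @export
meanEnvDistance <- function(env, group = NULL) {
  if (!is.null(group)) {
    grp <- attr(env, "group")
    if (is.null(grp)) stop("environment matrix carries no group attribute")
    env <- env[, grp == group, drop = FALSE]
  }
  d <- dist(standardizeColumns(env))
  list(mean = mean(d), se = sd(d) / sqrt(length(d)))
}

#' Run the full multi-facet diversity analysis
#'
#' From a dataset (observed tables or \code{\link{simulateDataset}}
#' output) computes, for each facet (taxonomic, functional,
#' phylogenetic) and scale (alpha, beta): Rao diversity profiles, the
#' phylogenetic-signal table, PCNM spatial predictors, raw and
#' environment-residual correlograms, pooled forward-selection models and
#' two-set variation partitioning. Deterministic given \code{seed}.
#'
#' @param data list with elements \code{tree}, \code{traits}, \code{env},
#'   \code{coords}, \code{comm}.
#' @param varianceThreshold cumulative-variance rule for trait and
#'   environment PCA reductions (default 0.90).
#' @param codingMap coding map for qualitative traits (defaults to
#'   \code{\link{defaultCodingMap}}).
#' @param nPerm permutations for every permutation test.
#' @param alpha forward-selection entry threshold.
#' @param nClasses correlogram distance classes (\code{"auto"} =
#'   Sturges).
#' @param grafenPower power for Grafen ultrametrization applied when the
#'   input tree is not ultrametric.
#' @param seed master seed; per-stage seeds derived from it are recorded
#'   in the manifest.
#' @return list with components \code{distances}, \code{profiles},
#'   \code{signal}, \code{pcnm}, \code{correlograms}, \code{selection},
#'   \code{varpart}, \code{envHeterogeneity}, \code{manifest}.
#' @export
runAnalysis <- function(data, varianceThreshold = 0.90, codingMap = NULL,
                        nPerm = 199L, alpha = 0.05, nClasses = "auto",
                        grafenPower = 1, seed = 1L) {
  issues <- validateInputs(data$comm, data$traits, data$tree, data$env,
                           data$coords)
  if (any(issues$severity == "error"))
    stop(paste(c("invalid inputs:", issues$message[issues$severity == "error"]),
               collapse = "\n  "))
  seeds <- seed + c(resolve = 11L, signal = 23L, correlog = 37L,
                    selection = 53L)
  tree <- data$tree
  if (hasPolytomy(tree)) tree <- resolvePolytomies(tree, seeds[["resolve"]])
  if (is.null(tree$edge.length) || !isUltrametricTree(tree))
    tree <- grafenBranchLengths(tree, power = grafenPower)
  tree <- ape::keep.tip(tree, colnames(data$comm))

  if (is.null(codingMap)) codingMap <- defaultCodingMap(data$traits)
  traitsNum <- encodeTraits(data$traits, codingMap)
  traitsNum <- traitsNum[colnames(data$comm), , drop = FALSE]
  traitRed <- pcaReduce(standardizeColumns(traitsNum), varianceThreshold)

  distances <- list(
    taxonomic = taxonomicDistance(colnames(data$comm)),
    functional = functionalDistance(traitRed),
    phylogenetic = copheneticDistances(tree))
  profiles <- lapply(distances, function(D)
    diversityProfile(data$comm, D))

  signal <- signalTable(tree, data$traits, codingMap = codingMap,
                        nPerm = nPerm, seed = seeds[["signal"]])

  geoD <- geoDistances(data$coords)
  geoD <- geoD[rownames(data$comm), rownames(data$comm)]
  basis <- pcnm(geoD)
  envSub <- data$env[rownames(data$comm), , drop = FALSE]
  attr(envSub, "group") <- attr(data$env, "group")   # lost on subsetting
  envPred <- .envBlocks(envSub, varianceThreshold)
  envDist <- as.matrix(dist(standardizeColumns(envSub)))

  correlograms <- list(); selection <- list(); varpart <- list()
  s <- seeds[["correlog"]]
  for (f in names(profiles)) {
    prof <- profiles[[f]]
    aEq <- alphaDiversity(prof)
    beta <- betaDiversity(prof)
    correlograms[[f]] <- list(
      alpha = moransICorrelogram(aEq, geoD, nClasses, nPerm, seed = s + 1L),
      alphaResidual = moransICorrelogram(residualize(aEq, envPred), geoD,
                                         nClasses, nPerm, seed = s + 2L),
      beta = mantelCorrelogram(beta, geoD, nClasses, nPerm, seed = s + 3L),
      betaResidual = mantelCorrelogram(residualizeBeta(beta, envDist),
                                       geoD, nClasses, nPerm,
                                       seed = s + 4L))
    s <- s + 10L
    axes <- pcoaAxes(beta)$scores
    responses <- list(alpha = matrix(aEq, ncol = 1,
                                     dimnames = list(names(aEq), "alpha")),
                      beta = axes)
    for (sc in names(responses)) {
      Y <- responses[[sc]]
      key <- paste(f, sc, sep = ".")
      ## spatial candidates: the positive-autocorrelation subset of the
      ## PCNM basis (broad-scale vectors); trimmed further from the fine
      ## end if the pooled candidate set would approach n
      spaceCand <- positiveMoranScores(basis)
      maxCand <- nrow(Y) - 3L
      if (ncol(envPred) + ncol(spaceCand) > maxCand)
        spaceCand <- spaceCand[, seq_len(max(1L, maxCand - ncol(envPred))),
                               drop = FALSE]
      pooled <- cbind(envPred, spaceCand)
      selection[[key]] <- forwardSelect(Y, pooled, alpha = alpha,
                                        nPerm = nPerm,
                                        seed = seeds[["selection"]])
      selE <- intersect(selectedTerms(selection[[key]]), colnames(envPred))
      selS <- intersect(selectedTerms(selection[[key]]),
                        colnames(axisScores(basis)))
      varpart[[key]] <- varpart2(Y,
                                 E = if (length(selE))
                                   envPred[, selE, drop = FALSE],
                                 S = if (length(selS))
                                   axisScores(basis)[, selS, drop = FALSE],
                                 label = key)
    }
  }

  envHet <- if (!is.null(attr(data$env, "group")))
    list(soil = meanEnvDistance(data$env, "soil"),
         clim = meanEnvDistance(data$env, "clim"))
  else list(all = meanEnvDistance(data$env))

  list(distances = distances, profiles = profiles, signal = signal,
       pcnm = basis, correlograms = correlograms, selection = selection,
       varpart = varpart, envHeterogeneity = envHet,
       manifest = list(seed = seed, stageSeeds = seeds, nPerm = nPerm,
                       alpha = alpha,
                       varianceThreshold = varianceThreshold,
                       nSites = nrow(data$comm),
                       nSpecies = ncol(data$comm),
                       issues = issues,
                       packageVersion =
                         as.character(utils::packageVersion("RaoFacets"))))
}
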