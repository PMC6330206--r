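## Synthetic community generator: Yule phylogenies, lambda-scaled Brownian
## traits, Gaussian-process landscapes, niche + dispersal assembly.
## Defaults emulate a dryland vegetation survey: a ~230-species pool on an
## ultrametric tree, 9 traits, 68 sites spanning a few hundred km with 14
## spatially autocorrelated soil/climate variables, presence/absence plots.

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Yule (pure-birth) topology with branch lengths rescaled to unit
#' root-to-tip depth. Tip labels are \code{sp001}, \code{sp002}, ...
#'
#' @param nTips number of tips (>= 2).
#' @param seed integer seed.
#' @return a binary ultrametric \code{ape::phylo} tree of depth 1.
#' @examples
#' tr <- simulateTree(10, seed = 1)
#' @export
simulateTree <- function(nTips, seed = 1L) {
  if (nTips < 2) stop("invalid argument: nTips must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(nTips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(nTips))
  tr
}

.lambdaCov <- function(tree, lambda) {
  C <- ape::vcv.phylo(tree)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Simulate traits with known phylogenetic signal
#'
#' Quantitative traits are drawn from a multivariate normal with covariance
#' \code{sigma2 * C(lambda)}, where C is the shared-path-length matrix of
#' the tree and its off-diagonal entries are scaled by \code{lambda}.
#' \code{model = "brownian"} fixes lambda at 1, \code{"white_noise"} at 0.
#' Optionally the last \code{nQualitative} traits are re-expressed as
#' qualitative categories by quantile-binning the underlying continuous
#' value into \code{nCategories} classes (labels \code{"c1"}, ...),
#' mirroring in reverse the field practice of numerically re-coding
#' categorical traits.
#'
#' @param tree binary \code{ape::phylo} tree with positive branch lengths.
#' @param model \code{"brownian"}, \code{"lambda_scaled"} or
#'   \code{"white_noise"}.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param lambda signal parameter in [0, 1]; used when
#'   \code{model = "lambda_scaled"}.
#' @param nTraits number of traits.
#' @param nQualitative how many of the traits to emit as categorical.
#' @param nCategories number of bins for qualitative traits.
#' @param seed integer seed.
#' @return long-format data.frame with columns \code{species},
#'   \code{trait}, \code{value} (character), \code{kind}
#'   (\code{"quantitative"} or \code{"qualitative"}).
#' @seealso \code{\link{traitMatrix}} to pivot to a numeric species x trait
#'   matrix.
#' @export
simulateTraits <- function(tree, model = c("brownian", "lambda_scaled",
                                           "white_noise"),
                           sigma2 = 1, lambda = 1, nTraits = 9L,
                           nQualitative = 0L, nCategories = 3L, seed = 1L) {
  model <- match.arg(model)
  if (lambda < 0 || lambda > 1)
    stop("invalid argument: lambda must lie in [0, 1]")
  if (sigma2 <= 0) stop("invalid argument: sigma2 must be positive")
  if (nQualitative > nTraits)
    stop("invalid argument: nQualitative exceeds nTraits")
  lam <- switch(model, brownian = 1, white_noise = 0, lambda_scaled = lambda)
  set.seed(seed)
  Cl <- .lambdaCov(tree, lam)
  X <- MASS::mvrnorm(n = nTraits, mu = rep(0, nrow(Cl)),
                     Sigma = sigma2 * Cl)
  X <- matrix(X, nrow = nTraits)            # nTraits = 1 drops dims otherwise
  colnames(X) <- tree$tip.label
  traitNames <- sprintf("trait%d", seq_len(nTraits))
  qualIdx <- if (nQualitative > 0)
    seq(nTraits - nQualitative + 1L, nTraits) else integer()
  rows <- lapply(seq_len(nTraits), function(i) {
    v <- X[i, ]
    if (i %in% qualIdx) {
      br <- quantile(v, probs = seq(0, 1, length.out = nCategories + 1))
      br[1] <- -Inf; br[length(br)] <- Inf
      lab <- paste0("c", as.integer(cut(v, breaks = br, labels = FALSE)))
      data.frame(species = colnames(X), trait = traitNames[i],
                 value = lab, kind = "qualitative",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = colnames(X), trait = traitNames[i],
                 value = as.character(v), kind = "quantitative",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

.haversineKm <- function(lon, lat) {
  ## great-circle distances, R = 6371 km
  n <- length(lon)
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dphi <- phi - phi[i]
    dlam <- lam - lam[i]
    a <- sin(dphi / 2)^2 + cos(phi[i]) * cos(phi) * sin(dlam / 2)^2
    D[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  }
  D
}

#' Simulate a spatially autocorrelated environmental landscape
#'
#' Sites are scattered uniformly over a longitude/latitude rectangle. Each
#' variable group (soil, climate) is built from a small number of latent
#' Gaussian-process fields with covariance
#' \code{(1 - nugget) * exp(-d / autocorrRange) + nugget * I} over
#' great-circle distances; observed variables are random linear
#' combinations of their group's latents plus measurement noise, then
#' z-scored across sites. The latent ranks reproduce the redundancy of
#' field soil/climate tables (a handful of PCA axes carries >= 90\% of the
#' variance), and the nugget is site-level (microhabitat) variance that no
#' spatial predictor can capture.
#'
#' @param nSites number of sites (>= 10).
#' @param nSoil,nClim number of soil and climate variables.
#' @param soilRank,climRank number of latent fields behind each group
#'   (capped at the group's variable count).
#' @param autocorrRange range parameter of the exponential covariance (km);
#'   values near 0 give spatially unstructured variables.
#' @param nugget fraction of non-spatial (site-level) variance of the
#'   latent fields, in [0, 1).
#' @param noise variance of the independent measurement noise added to
#'   each observed variable (latents have unit variance).
#' @param seed integer seed.
#' @param lonRange,latRange rectangle of the site coordinates (decimal
#'   degrees); the default spans roughly 330 x 330 km.
#' @return list with \code{env} (sites x variables z-scored matrix whose
#'   columns carry a \code{"group"} attribute, \code{"soil"} or
#'   \code{"clim"}) and \code{coords} (data.frame: site, lon, lat).
#' @export
simulateLandscape <- function(nSites = 68L, nSoil = 8L, nClim = 6L,
                              soilRank = 4L, climRank = 2L,
                              autocorrRange = 100, nugget = 0.3,
                              noise = 0.1, seed = 1L, lonRange = c(80, 84),
                              latRange = c(43, 46)) {
  if (nSites < 10) stop("invalid argument: nSites must be >= 10")
  if (nSoil < 1 || nClim < 0)
    stop("invalid argument: need nSoil >= 1 and nClim >= 0")
  if (autocorrRange <= 0) stop("invalid argument: autocorrRange must be > 0")
  if (nugget < 0 || nugget >= 1)
    stop("invalid argument: nugget must lie in [0, 1)")
  set.seed(seed)
  lon <- runif(nSites, lonRange[1], lonRange[2])
  lat <- runif(nSites, latRange[1], latRange[2])
  sites <- sprintf("site%02d", seq_len(nSites))
  D <- .haversineKm(lon, lat)
  K <- (1 - nugget) * exp(-D / autocorrRange) + diag(nugget, nSites)
  L <- chol(K + diag(1e-8, nSites))
  groupVars <- function(nVar, rank) {
    if (nVar == 0L) return(NULL)
    rank <- min(rank, nVar)
    F <- crossprod(L, matrix(rnorm(nSites * rank), nSites, rank))
    W <- matrix(rnorm(rank * nVar), rank, nVar)
    ## unit-norm loadings: every variable carries unit latent variance,
    ## so the measurement noise fraction is noise / (1 + noise) for all
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    F %*% W + sqrt(noise) * matrix(rnorm(nSites * nVar), nSites, nVar)
  }
  E <- cbind(groupVars(nSoil, soilRank), groupVars(nClim, climRank))
  E <- scale(E)
  attr(E, "scaled:center") <- NULL
  attr(E, "scaled:scale") <- NULL
  grp <- c(rep("soil", nSoil), rep("clim", nClim))
  colnames(E) <- c(sprintf("soil%d", seq_len(nSoil)),
                   if (nClim) sprintf("clim%d", seq_len(nClim)))
  rownames(E) <- sites
  attr(E, "group") <- grp
  list(env = E, coords = data.frame(site = sites, lon = lon, lat = lat,
                                    stringsAsFactors = FALSE))
}

#' Assemble presence/absence communities by niche matching and dispersal
#'
#' Occurrence probability of species i at site s is
#' \code{baseProb * exp(-(t_i - e_s)^2 / (2 * nicheBreadth^2)) * exp(-d(s,
#' o_i) / dispersalRange)}, where t is the (z-scored) niche trait of the
#' species, e the first environmental variable, and o_i a random origin
#' site per species (the dispersal factor is 1 when \code{dispersalRange}
#' is infinite). Presences are independent Bernoulli draws. Sites ending
#' with fewer than 2 species are redrawn (up to \code{maxRetries});
#' species absent everywhere are placed at their highest-probability site
#' so the species pool stays complete.
#'
#' @param tree \code{ape::phylo}; tips define the species pool.
#' @param traits trait table from \code{\link{simulateTraits}}; its first
#'   quantitative trait is the niche trait.
#' @param env environment matrix from \code{\link{simulateLandscape}}; its
#'   first column is the filtering gradient.
#' @param coords site coordinates (data.frame: site, lon, lat).
#' @param nicheBreadth Gaussian niche width in z-score units; \code{Inf}
#'   switches environmental filtering off.
#' @param dispersalRange e-folding distance of the dispersal kernel (km);
#'   \code{Inf} switches dispersal limitation off.
#' @param baseProb plateau occurrence probability.
#' @param suitFloor background-colonization floor on the niche-by-
#'   dispersal suitability; keeps extreme-environment and remote sites
#'   occupiable under strong filtering.
#' @param seed integer seed.
#' @param maxRetries redraw budget for under-filled sites.
#' @return sites x species 0/1 matrix with dimnames.
#' @export
simulateCommunities <- function(tree, traits, env, coords, nicheBreadth = 1,
                                dispersalRange = Inf, baseProb = 0.12,
                                suitFloor = 0.05, seed = 1L,
                                maxRetries = 100L) {
  stopifnot(inherits(tree, "phylo"))
  if (nicheBreadth <= 0) stop("invalid argument: nicheBreadth must be > 0")
  if (dispersalRange <= 0) stop("invalid argument: dispersalRange must be > 0")
  sp <- tree$tip.label
  quant <- traits[traits$kind == "quantitative", , drop = FALSE]
  if (nrow(quant) == 0L) stop("traits must include a quantitative niche trait")
  nicheName <- quant$trait[1]
  tv <- quant[quant$trait == nicheName, ]
  if (!setequal(tv$species, sp))
    stop("species sets of tree and traits are inconsistent")
  t_i <- as.numeric(tv$value)[match(sp, tv$species)]
  t_i <- as.numeric(scale(t_i))
  e_s <- env[, 1]
  nSites <- nrow(env)
  set.seed(seed)
  niche <- if (is.finite(nicheBreadth))
    exp(-outer(e_s, t_i, "-")^2 / (2 * nicheBreadth^2))
  else matrix(1, nSites, length(sp))
  disp <- matrix(1, nSites, length(sp))
  if (is.finite(dispersalRange)) {
    D <- .haversineKm(coords$lon, coords$lat)
    origin <- sample.int(nSites, length(sp), replace = TRUE)
    disp <- exp(-D[, origin, drop = FALSE] / dispersalRange)
  }
  ## suitability is floored by a weak background-colonization rate: no
  ## site is entirely closed to any species, so extreme-environment or
  ## remote sites stay occupiable (and the >= 2 species invariant
  ## attainable) while the niche/dispersal structure dominates
  P <- baseProb * pmax(niche * disp, suitFloor)
  comm <- matrix(rbinom(length(P), 1L, P), nSites, length(sp))
  for (s in seq_len(nSites)) {
    tries <- 0L
    while (sum(comm[s, ]) < 2L) {
      tries <- tries + 1L
      if (tries > maxRetries)
        stop(sprintf(paste0("generation failure: site %d still has < 2 ",
                            "species after %d redraws (mean occurrence ",
                            "probability %.4f); widen nicheBreadth or ",
                            "raise baseProb"), s, maxRetries, mean(P[s, ])))
      comm[s, ] <- rbinom(length(sp), 1L, P[s, ])
    }
  }
  missing <- which(colSums(comm) == 0L)
  for (j in missing) comm[which.max(P[, j]), j] <- 1L
  dimnames(comm) <- list(rownames(env), sp)
  comm
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper tying the four generators together under one master
#' seed (each stage receives a distinct seed derived from it). Defaults are
#' the package's reference study conditions: a 230-species pool on a Yule
#' tree, 9 Brownian traits (4 of them categorical), 68 sites over a few
#' hundred km with 8 soil and 6 climate variables (100 km autocorrelation
#' range plus a microhabitat nugget), and environment-structured assembly
#' (niche breadth 0.5 z-score units, no dispersal limitation).
#'
#' @param nSpecies,nSites,nTraits,nQualitative,nSoil,nClim,autocorrRange,
#'   nugget,nicheBreadth,dispersalRange,baseProb,suitFloor see the
#'   individual generators.
#' @param traitModel trait evolution model passed to
#'   \code{\link{simulateTraits}}.
#' @param traitLambda lambda for \code{traitModel = "lambda_scaled"}.
#' @param seed master seed.
#' @return list with elements \code{tree}, \code{traits}, \code{env},
#'   \code{coords}, \code{comm}, \code{seeds}.
#' @export
simulateDataset <- function(nSpecies = 230L, nSites = 68L, nTraits = 9L,
                            nQualitative = 4L, nSoil = 8L, nClim = 6L,
                            autocorrRange = 100, nugget = 0.3,
                            nicheBreadth = 0.5,
                            dispersalRange = Inf, baseProb = 0.25,
                            suitFloor = 0.05, traitModel = "brownian",
                            traitLambda = 1, seed = 1L) {
  seeds <- seed + c(tree = 101L, traits = 202L, landscape = 303L,
                    comm = 404L)
  tree <- simulateTree(nSpecies, seed = seeds[["tree"]])
  traits <- simulateTraits(tree, model = traitModel, lambda = traitLambda,
                           nTraits = nTraits, nQualitative = nQualitative,
                           seed = seeds[["traits"]])
  land <- simulateLandscape(nSites, nSoil = nSoil, nClim = nClim,
                            autocorrRange = autocorrRange, nugget = nugget,
                            seed = seeds[["landscape"]])
  comm <- simulateCommunities(tree, traits, land$env, land$coords,
                              nicheBreadth = nicheBreadth,
                              dispersalRange = dispersalRange,
                              baseProb = baseProb, suitFloor = suitFloor,
                              seed = seeds[["comm"]])
  list(tree = tree, traits = traits, env = land$env, coords = land$coords,
       comm = comm, seeds = seeds)
}
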