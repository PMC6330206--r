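# Shared fixtures built in code.

# balanced ultrametric 4-tip tree, depth 1
balancedTree4 <- function()
  readNewick("((a:0.5,b:0.5):0.5,(c:0.5,d:0.5):0.5);", text = TRUE)

# star tree with n tips, equal branch lengths
starTree <- function(n, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

# named incidence row over a species universe
siteRow <- function(present, universe)
  stats::setNames(as.integer(universe %in% present), universe)

# small consistent dataset for pipeline tests
smallDataset <- function(seed = 42)
  simulateDataset(nSpecies = 40, nSites = 20, nTraits = 4,
                  nQualitative = 1, nSoil = 3, nClim = 3, baseProb = 0.25,
                  seed = seed)
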