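## Tree handling: newick I/O, polytomy resolution, Grafen ultrametrization,
## cophenetic distances. Trees are ape "phylo" objects throughout.

#' Read a phylogenetic tree from a newick file or string
#'
#' Accepts rooted trees with polytomies, quoted labels and missing branch
#' lengths. A light structural pre-check reports the character position of
#' the first unbalanced parenthesis or a missing terminal semicolon before
#' handing the string to the newick parser.
#'
#' @param path path to a newick file, or a literal newick string ending in
#'   \code{";"} when \code{text = TRUE}.
#' @param text logical; treat \code{path} as the newick string itself.
#' @return an \code{ape::phylo} tree.
#' @examples
#' tr <- readNewick("((a:1,b:1):1,c:2);", text = TRUE)
#' @export
readNewick <- function(path, text = FALSE) {
  s <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  s <- trimws(s)
  depth <- 0L
  inq <- FALSE
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "'") inq <- !inq
    if (inq) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of string (length %d)",
                 depth, nchar(s)))
  if (!grepl(";\\s*$", s))
    stop(sprintf("newick parse error: missing ';' at position %d", nchar(s)))
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop(sprintf("newick parse error: %s",
                                                  conditionMessage(e))))
  if (is.null(tr)) stop("newick parse error: string could not be parsed")
  if (anyDuplicated(tr$tip.label))
    stop("invalid tree: duplicated tip labels")
  tr
}

#' Write a tree to newick
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Does a tree contain polytomies?
#'
#' @param tree an \code{ape::phylo} tree.
#' @return TRUE if any internal node has more than two children.
#' @export
hasPolytomy <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  any(tabulate(tree$edge[, 1]) > 2L)
}

#' Randomly resolve polytomies into a binary tree
#'
#' Multichotomies are broken into successive dichotomies in random order;
#' every inserted branch has length zero, so tip-to-tip path lengths (and
#' hence cophenetic distances) are unchanged.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param seed integer seed controlling the random resolution.
#' @return a binary \code{ape::phylo} tree.
#' @export
resolvePolytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!hasPolytomy(tree)) return(tree)
  set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

#' Grafen branch lengths (ultrametrization)
#'
#' Assigns node heights proportional to (number of descendant tips - 1),
#' normalized so the root has height 1, and raised to \code{power}. The
#' result is ultrametric with unit root-to-tip depth.
#'
#' @param tree rooted binary \code{ape::phylo} tree.
#' @param power exponent applied to the normalized heights (default 1).
#' @return an ultrametric \code{ape::phylo} tree of depth 1.
#' @export
grafenBranchLengths <- function(tree, power = 1) {
  stopifnot(inherits(tree, "phylo"), power > 0)
  ape::compute.brlen(tree, method = "Grafen", power = power)
}

#' Cophenetic (patristic) species distances from a tree
#'
#' The distance between two tips is the sum of branch lengths along the
#' path connecting them.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @return a \code{\link{FacetDist}} with facet \code{"phylogenetic"},
#'   species ordered as \code{tree$tip.label}.
#' @export
copheneticDistances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("invalid tree: branch lengths missing")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  new("FacetDist", distances = d, facet = "phylogenetic")
}

#' Is a tree ultrametric to a given tolerance?
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return logical.
#' @export
isUltrametricTree <- function(tree, tol = 1e-8) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol * max(depths)
}
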