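#' Read a rooted Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the checks the pipeline relies on: unique
#' tip labels, branch lengths present (missing lengths are set to zero with a
#' warning), and a warning when the tree is unrooted, since Faith PD and the
#' phylogenetic correlation matrix are measured from the root.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting every edge to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  if (!ape::is.rooted(tree))
    warning("tree is unrooted; root-dependent metrics will treat the basal ",
            "trichotomy as the root")
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Rooted binary tree with exponential waiting times between speciation
#' events (birth rate 1, no extinction), via [ape::rphylo()]. Tips are
#' labelled `asv0001`, `asv0002`, ... so simulated trees and community tables
#' share an identifier scheme. The same seed always yields the same Newick
#' string.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @param model currently only `"yule"`.
#' @return an [ape::phylo] object with `n_tips` tips.
#' @export
simulate_tree <- function(n_tips, seed = NULL, model = c("yule")) {
  model <- match.arg(model)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  tree <- with_seed_or_stream(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("asv%04d", seq_len(n_tips))
  tree
}
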