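#' Read a rooted Newick tree with branch lengths
#'
#' Thin validating wrapper over [ape::read.tree()]. The tree must have unique
#' tip labels and a finite non-negative length on every branch; unlabeled
#' internal nodes are fine. Tips are ASV identifiers and may be a superset of
#' any count table they are used with.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("failed to parse Newick in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(tree)) stop("failed to parse Newick in ", path, call. = FALSE)
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  .check_unique(tree$tip.label, "tip")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad)) {
    nodes <- tree$edge[bad, 2]
    lab <- ifelse(nodes <= length(tree$tip.label),
                  tree$tip.label[nodes], paste0("node ", nodes))
    stop("missing or invalid branch length above: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Simulate a random rooted phylogeny for synthetic studies
#'
#' A random rooted bifurcating topology ([ape::rtree()]) with branch lengths
#' drawn i.i.d. exponential(1), tips labeled `ASV0001`, `ASV0002`, ... It
#' stands in for a reference phylogeny when generating synthetic data; it does
#' not model any particular evolutionary process.
#'
#' @param n_tips number of tips, >= 2.
#' @param rng_seed integer seed; the same seed reproduces the same tree.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_tips, rng_seed = 1L) {
  if (!is.numeric(n_tips) || length(n_tips) != 1 || n_tips < 2 ||
      n_tips != round(n_tips)) {
    stop("`n_tips` must be an integer >= 2", call. = FALSE)
  }
  tree <- withr::with_seed(rng_seed, {
    ape::rtree(n_tips, rooted = TRUE, br = stats::rexp)
  })
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_tips))
  tree
}
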