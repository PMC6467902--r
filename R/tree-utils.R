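#' @keywords internal
"_PACKAGE"

#' @useDynLib plumrates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimise quantile rnorm runif rexp rpois sd var cov
#'   pt dpois ppois pchisq prcomp aggregate setNames complete.cases
#' @importFrom utils write.csv read.csv head
NULL

# Internal helpers shared by the simulators and the rate machinery.
# Edges are indexed by row of tree$edge; that indexing is treated as stable
# throughout the package (regimes, phenograms and posterior samples all refer
# to it).

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an object of class 'phylo'")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tree has duplicate tip labels")
  invisible(tree)
}

postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

# For every edge e, the edge indices strictly below e's child node.  A clade
# event with focal edge e covers exactly these edges (the focal edge itself is
# not rescaled), so an n-tip clade covers its 2n - 2 edges.
branch_descendants <- function(tree) {
  nedge <- nrow(tree$edge)
  nnode <- ape::Ntip(tree) + tree$Nnode
  below <- vector("list", nnode)
  desc <- vector("list", nedge)
  for (e in postorder_edges(tree)) {
    par <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    desc[[e]] <- if (is.null(below[[ch]])) integer(0) else below[[ch]]
    below[[par]] <- c(below[[par]], desc[[e]], e)
  }
  desc
}

# Number of tips subtended by each edge (the clade size of its child node).
clade_tip_counts <- function(tree) {
  ntip <- ape::Ntip(tree)
  cnt <- integer(nrow(tree$edge))
  ntips_below <- integer(ntip + tree$Nnode)
  ntips_below[seq_len(ntip)] <- 1L
  for (e in postorder_edges(tree)) {
    cnt[e] <- ntips_below[tree$edge[e, 2L]]
    ntips_below[tree$edge[e, 1L]] <- ntips_below[tree$edge[e, 1L]] + cnt[e]
  }
  cnt
}

# Path of edge indices from each tip back to the root, terminal edge first.
tip_root_paths <- function(tree) {
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  parent_edge <- integer(ntip + tree$Nnode)  # edge above each node; 0 at root
  parent_edge[tree$edge[, 2L]] <- seq_len(nedge)
  lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (parent_edge[node] > 0L) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
}
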