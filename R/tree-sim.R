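#' Simulate a birth-death time tree conditioned on the number of extant tips
#'
#' Forward-time constant-rate birth-death simulation started from two lineages.
#' The process runs until `n_tips` lineages are alive, then extends the tree by
#' one further waiting time drawn from the distribution of the time to the next
#' event (so terminal branches have positive length), and stops.  Realisations
#' in which the process goes extinct before reaching `n_tips` are discarded and
#' redrawn; if `max_retries` consecutive realisations go extinct the function
#' fails rather than silently returning a smaller tree.  Extinct lineages are
#' pruned from the returned tree, so it always carries exactly `n_tips` extant
#' tips.
#'
#' Under pure birth (`death_rate = 0`) the root-to-tip depth is a sum of
#' independent exponentials, with expectation `sum(1/(k * birth_rate))` for
#' `k = 2, ..., n_tips` — the closed form used in the package tests.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> death_rate).
#' @param death_rate per-lineage extinction rate (>= 0).
#' @param seed optional integer seed; when supplied the result is reproducible.
#' @param max_retries maximum number of extinct realisations tolerated.
#' @return an ultrametric rooted bifurcating `phylo` tree with `n_tips` tips
#'   labelled `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = NULL,
                          max_retries = 1000L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    tree <- .simulate_tree_once(n_tips, birth_rate, death_rate)
    if (!is.null(tree)) {
      tree$tip.label <- paste0("t", seq_len(ape::Ntip(tree)))
      return(check_tree(tree))
    }
  }
  stop("birth-death simulation went extinct in ", max_retries,
       " consecutive attempts; increase max_retries or lower death_rate")
}

# One forward realisation; NULL on extinction before reaching n_tips.
.simulate_tree_once <- function(n_tips, birth, death) {
  # per-lineage bookkeeping; lineage 1 and 2 are the root's children
  parent <- c(0L, 0L)
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  fate <- c(NA_character_, NA_character_)  # "speciated" / "extinct" / NA alive
  alive <- c(1L, 2L)
  t_now <- 0
  total_rate <- birth + death
  while (length(alive) < n_tips) {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    t_now <- t_now + rexp(1, n_alive * total_rate)
    idx <- alive[sample.int(n_alive, 1L)]
    t_end[idx] <- t_now
    if (runif(1) < birth / total_rate) {
      fate[idx] <- "speciated"
      k <- length(parent)
      parent <- c(parent, idx, idx)
      t_birth <- c(t_birth, t_now, t_now)
      t_end <- c(t_end, NA_real_, NA_real_)
      fate <- c(fate, NA_character_, NA_character_)
      alive <- c(setdiff(alive, idx), k + 1L, k + 2L)
    } else {
      fate[idx] <- "extinct"
      alive <- setdiff(alive, idx)
    }
  }
  # final interval: stop just before the next event would occur
  t_now <- t_now + rexp(1, length(alive) * total_rate)
  t_end[alive] <- t_now
  .lineages_to_phylo(parent, t_birth, t_end, fate)
}

# Build a phylo object from the lineage table, pruning extinct tips.
.lineages_to_phylo <- function(parent, t_birth, t_end, fate) {
  n_lin <- length(parent)
  is_tip <- is.na(fate) | fate == "extinct"
  tips <- which(is_tip)
  internals <- which(!is_tip)           # speciated lineages
  ntip <- length(tips)
  node_id <- integer(n_lin)
  node_id[tips] <- seq_len(ntip)
  node_id[internals] <- ntip + 1L + seq_along(internals)  # ntip+1 is the root
  edge <- matrix(0L, n_lin, 2)
  for (i in seq_len(n_lin)) {
    edge[i, 1L] <- if (parent[i] == 0L) ntip + 1L else node_id[parent[i]]
    edge[i, 2L] <- node_id[i]
  }
  tree <- structure(list(
    edge = edge,
    edge.length = t_end - t_birth,
    tip.label = paste0("lin", tips),
    Nnode = length(internals) + 1L
  ), class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree)
  ext_idx <- which(fate %in% "extinct")
  if (length(ext_idx)) {
    if (ape::Ntip(tree) - length(ext_idx) < 2L) return(NULL)
    tree <- ape::drop.tip(tree, paste0("lin", ext_idx))
  }
  tree
}
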