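# TRES (Trait Rate equal splits): a species-level rate metric.
#
# For tip i with root path edges j = 1..N_i (j = 1 the terminal edge, j = N_i
# the edge nearest the root) and per-edge values l_j,
#     m_i = sum_j w_j l_j / sum_j w_j,   w_j = 1 / 2^(j - 1),
# i.e. a weighted average of the path's branch values whose weights halve at
# each step rootward.  Applied to a mean rate phenogram (l_j = posterior mean
# scalar x time) it estimates the species-level rate of trait evolution while
# still reflecting the longer-term rate history leading to the tip.

.tres_core <- function(tree, values) {
  paths <- tip_root_paths(tree)
  m <- vapply(paths, function(path) {
    w <- 0.5^(seq_along(path) - 1)
    sum(w * values[path]) / sum(w)
  }, numeric(1))
  out <- data.frame(tip = tree$tip.label, tres = m,
                    log10_tres = log10(m),
                    n_edges = lengths(paths),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tip), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TRES tip rates from a rate phenogram
#'
#' Computes the equal-splits weighted average of rate-scaled branch lengths
#' along each tip's root path (terminal edge weighted 1, halving rootward).
#'
#' @param phenogram a `rate_phenogram`, or a `phylo` tree whose branch
#'   lengths are already rate-scaled.
#' @return data.frame (`tip`, `tres`, `log10_tres`, `n_edges`) ordered by tip
#'   label.
#' @export
tres <- function(phenogram) {
  if (inherits(phenogram, "rate_phenogram")) {
    tree <- phenogram$tree
    values <- phenogram$l
  } else {
    check_tree(phenogram)
    tree <- phenogram
    values <- tree$edge.length
  }
  .tres_core(tree, values)
}

#' TRES computed on per-branch mean scalars instead of scaled lengths
#'
#' Sensitivity variant: the same equal-splits weighting applied to the
#' posterior mean scalar of each branch (so branch durations do not enter).
#' Equal to [tres()] when every branch has unit length.
#'
#' @param phenogram a `rate_phenogram`.
#' @return data.frame as for [tres()].
#' @export
tres_per_branch_rate <- function(phenogram) {
  stopifnot(inherits(phenogram, "rate_phenogram"))
  .tres_core(phenogram$tree, phenogram$mean_scalar)
}
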