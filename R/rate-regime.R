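#' Assign a branch/clade rate-shift regime to a tree
#'
#' Draws a ground-truth rate regime for simulation: a set of non-overlapping
#' shift events, each multiplying the base Brownian rate on the branches it
#' covers.  A clade shift with focal edge `e` covers every edge strictly below
#' `e`'s child node (an n-tip clade covers its 2n - 2 edges); a branch shift
#' covers its single branch.  Shift scalars are drawn log-normally with median
#' 1 and spread `log_scalar_sd` on the log scale, so accelerations and
#' decelerations are a priori symmetric, matching the multiplicative scalar
#' model used in inference.
#'
#' @param tree a `phylo` tree.
#' @param n_clade_shifts,n_branch_shifts number of clade and single-branch
#'   shifts to place.  Placements are disjoint: no branch is covered by two
#'   events.
#' @param log_scalar_sd standard deviation of log shift scalars (>= 0).
#' @param min_clade_size minimum number of tips a shifted clade must subtend.
#' @param sigma2 base Brownian rate per trait dimension (recycled to length 2
#'   by the colour-dataset generator).
#' @param corr trait correlation matrix (must be positive definite).
#' @param seed optional integer seed.
#' @return an object of class `rate_regime`: list with `events`
#'   (data.frame: type, branch, scalar), `sigma2`, `corr`, `n_edge`.
#' @export
assign_rate_regime <- function(tree, n_clade_shifts = 0, n_branch_shifts = 0,
                               log_scalar_sd = 1, min_clade_size = 3,
                               sigma2 = 1, corr = NULL, seed = NULL) {
  check_tree(tree)
  if (log_scalar_sd < 0) stop("log_scalar_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nedge <- nrow(tree$edge)
  desc <- branch_descendants(tree)
  csize <- clade_tip_counts(tree)

  chosen_clades <- integer(0)
  covered <- logical(nedge)  # edges covered by an already placed event
  eligible <- which(csize >= min_clade_size & lengths(desc) > 0L)
  for (i in seq_len(n_clade_shifts)) {
    ok <- eligible[!eligible %in% chosen_clades &
                     vapply(eligible, function(e)
                       !covered[e] && !any(covered[desc[[e]]]) &&
                         !any(chosen_clades %in% desc[[e]]), logical(1))]
    if (!length(ok))
      stop("cannot place clade shift ", i,
           ": no eligible clade of >= ", min_clade_size,
           " tips remains disjoint from existing shifts")
    e <- ok[sample.int(length(ok), 1L)]
    chosen_clades <- c(chosen_clades, e)
    covered[desc[[e]]] <- TRUE
  }
  chosen_branches <- integer(0)
  for (i in seq_len(n_branch_shifts)) {
    ok <- which(!covered & !seq_len(nedge) %in% chosen_branches)
    if (!length(ok))
      stop("cannot place branch shift ", i, ": all branches already covered")
    e <- ok[sample.int(length(ok), 1L)]
    chosen_branches <- c(chosen_branches, e)
    covered[e] <- TRUE
  }

  n_ev <- n_clade_shifts + n_branch_shifts
  events <- data.frame(
    type = rep(c("clade", "branch"), c(n_clade_shifts, n_branch_shifts)),
    branch = c(chosen_clades, chosen_branches),
    scalar = exp(rnorm(n_ev, 0, log_scalar_sd)),
    stringsAsFactors = FALSE
  )
  if (is.null(corr)) corr <- diag(max(length(sigma2), 2L))
  chk <- try(chol(corr), silent = TRUE)
  if (inherits(chk, "try-error"))
    stop("trait correlation matrix is not positive definite")
  structure(list(events = events, sigma2 = sigma2, corr = corr,
                 n_edge = nedge),
            class = "rate_regime")
}

#' Per-branch effective rate scalars implied by a regime
#'
#' Branches not covered by any event have scalar 1; covered branches carry the
#' product of the scalars of all covering events (disjoint by construction in
#' [assign_rate_regime()], but products are supported for hand-built regimes).
#'
#' @param regime a `rate_regime`.
#' @param tree the tree the regime was built on.
#' @return numeric vector of length `nrow(tree$edge)`, all > 0.
#' @export
regime_scalars <- function(regime, tree) {
  stopifnot(inherits(regime, "rate_regime"))
  check_tree(tree)
  nedge <- nrow(tree$edge)
  if (nedge != regime$n_edge)
    stop("regime was built for a tree with ", regime$n_edge, " edges, not ",
         nedge)
  desc <- branch_descendants(tree)
  r <- rep(1, nedge)
  ev <- regime$events
  for (i in seq_len(nrow(ev))) {
    cov <- if (ev$type[i] == "clade") desc[[ev$branch[i]]] else ev$branch[i]
    r[cov] <- r[cov] * ev$scalar[i]
  }
  r
}

#' @export
print.rate_regime <- function(x, ...) {
  cat("Rate regime:", nrow(x$events), "shift event(s) on a tree with",
      x$n_edge, "edges\n")
  if (nrow(x$events)) print(x$events)
  cat("base sigma^2:", paste(signif(x$sigma2, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a rate regime as a structured key-value sidecar file
#'
#' Regimes are serialised as YAML; `read_regime(write_regime(r, f))` returns a
#' regime identical to `r`.
#'
#' @param regime a `rate_regime`.
#' @param path file path.
#' @return `write_regime` returns `path` invisibly; `read_regime` returns a
#'   `rate_regime`.
#' @export
write_regime <- function(regime, path) {
  stopifnot(inherits(regime, "rate_regime"))
  obj <- list(
    n_edge = regime$n_edge,
    sigma2 = as.numeric(regime$sigma2),
    corr = apply(regime$corr, 1, as.numeric, simplify = FALSE),
    events = if (nrow(regime$events) == 0) list() else
      lapply(seq_len(nrow(regime$events)), function(i)
        list(type = regime$events$type[i],
             branch = regime$events$branch[i],
             scalar = regime$events$scalar[i]))
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_regime
#' @export
read_regime <- function(path) {
  obj <- yaml::read_yaml(path)
  ev <- if (length(obj$events) == 0) {
    data.frame(type = character(0), branch = integer(0), scalar = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      type = vapply(obj$events, `[[`, character(1), "type"),
      branch = vapply(obj$events, `[[`, integer(1), "branch"),
      scalar = vapply(obj$events, `[[`, numeric(1), "scalar"),
      stringsAsFactors = FALSE
    )
  }
  structure(list(events = ev, sigma2 = as.numeric(obj$sigma2),
                 corr = do.call(rbind, lapply(obj$corr, as.numeric)),
                 n_edge = obj$n_edge),
            class = "rate_regime")
}
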