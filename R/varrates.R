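# Variable-rates multivariate Brownian model: likelihood and RJMCMC.
#
# A scalar configuration is a set of shift events, each either a branch event
# (rescaling its single branch) or a clade event (rescaling every branch
# strictly below the focal branch's child node).  The effective scalar of a
# branch is the product of all events covering it.  Inside the sampler the
# log effective scalars are centred, fixing their geometric mean to 1: only
# relative rates are identified (the trait covariance R absorbs the global
# scale), so posterior scalars are reported on that relative scale.

.vr_prep <- function(tree, traits) {
  check_tree(tree)
  if (!ape::is.binary.phylo(tree))
    stop("variable-rates machinery requires a bifurcating tree")
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1,
                                             dimnames = list(names(traits)))
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("trait matrix must have tip labels as row names")
  if (!all(tree$tip.label %in% rownames(traits)))
    stop("traits missing for tip(s): ",
         paste(setdiff(tree$tip.label, rownames(traits)), collapse = ", "))
  traits <- traits[tree$tip.label, , drop = FALSE]
  if (anyNA(traits)) stop("trait matrix contains missing values")
  list(edge0 = tree$edge - 1L,
       tlen = tree$edge.length,
       post0 = postorder_edges(tree) - 1L,
       ntip = ape::Ntip(tree),
       X = traits)
}

.config_log_scalars <- function(tree, config) {
  nedge <- nrow(tree$edge)
  g <- numeric(nedge)
  if (is.null(config) || nrow(config) == 0) return(g)
  if (!all(c("type", "branch", "scalar") %in% names(config)))
    stop("config must have columns type, branch, scalar")
  if (any(config$scalar <= 0)) stop("shift scalars must be > 0")
  desc <- branch_descendants(tree)
  for (i in seq_len(nrow(config))) {
    cov <- if (config$type[i] == "clade") desc[[config$branch[i]]] else
      config$branch[i]
    g[cov] <- g[cov] + log(config$scalar[i])
  }
  g
}

#' Log-likelihood of the multivariate variable-rates Brownian model
#'
#' Computes the log density of tip traits under Brownian motion in which the
#' variance accumulated along branch `j` is `r_j * t_j` (times the among-trait
#' covariance `R`), with `r_j` the effective scalar implied by the shift
#' configuration.  Evaluated by Felsenstein's pruning algorithm — one
#' Gaussian contrast per internal node plus a root term — in O(tips) per
#' trait block, never by dense inversion of the among-tip covariance.
#'
#' @param tree a bifurcating `phylo` tree.
#' @param traits tip matrix (rows named by tip) or named vector.
#' @param config shift configuration: data.frame with columns `type`
#'   (`"branch"`/`"clade"`), `branch` (edge index), `scalar` (> 0); `NULL` or
#'   zero rows means homogeneous Brownian motion.
#' @param R among-trait covariance matrix (positive definite).
#' @param root root state vector (defaults to zero).
#' @param center if `TRUE`, centre log effective scalars (geometric mean 1)
#'   before evaluating, as the sampler does; the default `FALSE` uses the
#'   configuration's scalars as given.
#' @return the log-likelihood (a single number).
#' @export
mv_bm_loglik <- function(tree, traits, config = NULL, R = NULL, root = NULL,
                         center = FALSE) {
  pr <- .vr_prep(tree, traits)
  p <- ncol(pr$X)
  if (is.null(R)) R <- diag(p)
  R <- as.matrix(R)
  if (!all(dim(R) == p)) stop("R must be ", p, " x ", p)
  if (is.null(root)) root <- numeric(p)
  g <- .config_log_scalars(tree, config)
  .cpp_pruning_loglik(pr$edge0, pr$tlen, pr$post0, pr$ntip, pr$X, g, R,
                      as.numeric(root), center)
}

#' Reversible-jump MCMC over branch/clade rate-shift configurations
#'
#' Samples the joint posterior of (i) the set of shift events (number,
#' locations, branch vs clade type, scalar values), (ii) the among-trait
#' covariance `R` (random-walk Metropolis on its Cholesky factor), and
#' (iii) the root state, for the multivariate variable-rates Brownian model.
#' Priors: the number of events is Poisson (`shift_prior_mean`, truncated by
#' the number of available slots), event locations are uniform over distinct
#' (branch, type) slots with clade events restricted to internal branches,
#' and log scalars are Normal(0, `scalar_prior_sd`).  With the new-event
#' scalar proposed from its prior, the reversible-jump acceptance ratios
#' reduce to the likelihood ratio times `mean/(K+1)` (birth) or `K/mean`
#' (death), so a prior-only run samples the (truncated) Poisson exactly —
#' the correctness smoke test used in the package tests.
#'
#' @param tree a bifurcating `phylo` tree (>= 4 tips).
#' @param traits tip trait matrix (rows named by tip labels).
#' @param iterations total number of elementary moves.
#' @param burnin fraction of iterations discarded by the summaries.
#' @param thin record one sample every `thin` moves.
#' @param seed optional integer seed.
#' @param shift_prior_mean Poisson mean of the shift-count prior.
#' @param scalar_prior_sd sd of the log-scalar prior.
#' @param move_probs probabilities of the six move types (birth, death,
#'   resize, relocate, update-R, update-root); renormalised internally.
#' @param step_scalar,step_R,step_root random-walk proposal scales.
#' @param prior_only if `TRUE` the likelihood is held at zero and only the
#'   configuration moves are used (prior sampling).
#' @return object of class `vr_posterior`: the tree, a `samples` list
#'   (`iter`, `K`, `loglik`, `log_scalars` matrix, coverage indicators,
#'   `R`, `root`), the per-sample `events` data.frame, move `acceptance`
#'   diagnostics, and the settings.
#' @export
rjmcmc_variable_rates <- function(tree, traits, iterations = 1e5,
                                  burnin = 0.25, thin = 100, seed = NULL,
                                  shift_prior_mean = 2, scalar_prior_sd = 1,
                                  move_probs = c(birth = 0.15, death = 0.15,
                                                 resize = 0.25,
                                                 relocate = 0.10,
                                                 R = 0.25, root = 0.10),
                                  step_scalar = 0.5, step_R = 0.15,
                                  step_root = 0.2, prior_only = FALSE) {
  pr <- .vr_prep(tree, traits)
  if (pr$ntip < 4) stop("need at least 4 tips")
  if (iterations < thin) stop("iterations must be >= thin")
  if (burnin < 0 || burnin >= 1) stop("burnin must be a fraction in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  nedge <- nrow(tree$edge)
  desc <- branch_descendants(tree)
  clade_ok <- tree$edge[, 2L] > pr$ntip      # internal branches only
  cover0 <- lapply(desc, function(d) as.integer(d - 1L))
  p <- ncol(pr$X)
  if (prior_only) move_probs[c("R", "root")] <- 0
  # initial R from the tip covariance (ridge keeps it positive definite)
  S <- cov(pr$X) + diag(1e-4 + 0.05 * mean(diag(cov(pr$X))), p)
  L <- t(chol(S))
  init_theta <- c(log(diag(L)), L[lower.tri(L)])
  init_root <- colMeans(pr$X)
  res <- .cpp_rjmcmc(pr$edge0, pr$tlen, pr$post0, pr$ntip, pr$X, cover0,
                     clade_ok, as.integer(iterations), as.integer(thin),
                     shift_prior_mean, scalar_prior_sd,
                     as.numeric(move_probs), step_scalar, step_R, step_root,
                     5, 10, init_theta, init_root, prior_only)
  if (sum(res$accepted) == 0)
    stop("no proposal was accepted in ", iterations, " iterations; ",
         "proposed per move type: ",
         paste(res$proposed, collapse = ", "))
  events <- data.frame(sample = res$event_sample,
                       type = c("branch", "clade")[res$event_type + 1L],
                       branch = res$event_edge,
                       scalar = exp(res$event_logr),
                       stringsAsFactors = FALSE)
  acc <- data.frame(move = c("birth", "death", "resize", "relocate", "R",
                             "root"),
                    proposed = res$proposed, accepted = res$accepted)
  structure(list(
    tree = tree,
    samples = list(iter = res$iter, K = res$K, loglik = res$loglik,
                   log_scalars = res$log_scalars, cover_any = res$cover_any,
                   cover_branch = res$cover_branch,
                   clade_focal = res$clade_focal, R = res$R,
                   root = res$root),
    events = events,
    acceptance = acc,
    settings = list(iterations = iterations, burnin = burnin, thin = thin,
                    shift_prior_mean = shift_prior_mean,
                    scalar_prior_sd = scalar_prior_sd,
                    prior_only = prior_only, p = p)
  ), class = "vr_posterior")
}

#' @export
print.vr_posterior <- function(x, ...) {
  n <- length(x$samples$iter)
  cat("Variable-rates posterior:", n, "samples (thin",
      x$settings$thin, ") from", x$settings$iterations, "iterations\n")
  cat("mean shift count:", round(mean(x$samples$K), 2), "\n")
  print(x$acceptance)
  invisible(x)
}

.post_burnin_idx <- function(posterior) {
  cut <- posterior$settings$burnin * posterior$settings$iterations
  which(posterior$samples$iter > cut)
}

#' Summarise a variable-rates posterior as a mean rate phenogram
#'
#' Per-branch posterior mean effective scalar (relative scale, geometric mean
#' 1 within each sample), rate-scaled branch lengths `l_j = mean(r_j) * t_j`,
#' and per-branch shift posterior probabilities: `pp_cover` (fraction of
#' samples in which any event covers the branch), `pp_branch` (a branch event
#' sits on it) and `pp_clade` (a clade event has it as focal branch).
#'
#' @param posterior a `vr_posterior`.
#' @param tree optionally, the tree (defaults to the one in the posterior).
#' @return object of class `rate_phenogram`: the input tree, `mean_scalar`,
#'   `l` (= mean_scalar * edge length), the shift probabilities, and
#'   `scaled_tree` (the topology with branch lengths `l`).
#' @export
summarise_rate_phenogram <- function(posterior, tree = posterior$tree) {
  stopifnot(inherits(posterior, "vr_posterior"))
  keep <- .post_burnin_idx(posterior)
  if (!length(keep)) stop("no post-burn-in samples to summarise")
  g <- posterior$samples$log_scalars[keep, , drop = FALSE]
  mean_scalar <- colMeans(exp(g))
  mean_log_scalar <- colMeans(g)
  l <- mean_scalar * tree$edge.length
  scaled <- tree
  scaled$edge.length <- l
  structure(list(
    tree = tree, mean_scalar = mean_scalar,
    mean_log_scalar = mean_log_scalar, l = l,
    pp_cover = colMeans(posterior$samples$cover_any[keep, , drop = FALSE]),
    pp_branch = colMeans(posterior$samples$cover_branch[keep, ,
                                                        drop = FALSE]),
    pp_clade = colMeans(posterior$samples$clade_focal[keep, , drop = FALSE]),
    n_samples = length(keep), scaled_tree = scaled
  ), class = "rate_phenogram")
}

#' Build a rate phenogram directly from a tree and per-branch scalars
#'
#' Convenience constructor used when branch scalars are known (e.g. the
#' ground-truth regime of a simulation) rather than sampled.
#'
#' @param tree a `phylo` tree.
#' @param scalars per-branch rate scalars (> 0); default all 1.
#' @return a `rate_phenogram` with degenerate shift probabilities (all 0).
#' @export
rate_phenogram <- function(tree, scalars = rep(1, nrow(tree$edge))) {
  check_tree(tree)
  if (length(scalars) != nrow(tree$edge) || any(scalars <= 0))
    stop("scalars must be positive, one per edge")
  scaled <- tree
  scaled$edge.length <- scalars * tree$edge.length
  structure(list(tree = tree, mean_scalar = scalars,
                 mean_log_scalar = log(scalars),
                 l = scaled$edge.length,
                 pp_cover = rep(0, nrow(tree$edge)),
                 pp_branch = rep(0, nrow(tree$edge)),
                 pp_clade = rep(0, nrow(tree$edge)),
                 n_samples = 0L, scaled_tree = scaled),
            class = "rate_phenogram")
}

#' @export
print.rate_phenogram <- function(x, ...) {
  cat("Rate phenogram on", ape::Ntip(x$tree), "tips;",
      "mean scalar range [", signif(min(x$mean_scalar), 3), ",",
      signif(max(x$mean_scalar), 3), "]\n")
  if (x$n_samples > 0)
    cat("from", x$n_samples, "posterior samples\n")
  invisible(x)
}

#' Posterior probability that a given clade underwent a rate shift
#'
#' Two summaries of the evidence that the clade subtended by `branch`'s child
#' node shifted rate.  `"faster"` (default) is the posterior probability that
#' the clade's mean log relative scalar exceeds the background's (the
#' branches outside the clade): it is invariant to how the sampler represents
#' the shift as events, which matters because one true clade shift can be
#' expressed as a clade event at the stem, or as a clade event at a daughter
#' branch plus branch events, with posterior mass legitimately split across
#' these.  `"events"` is the probability that at least one clade-type event
#' has its focal branch on the stem or inside the clade — closer to a
#' "shift location" reading, but diluted by representation splitting.
#'
#' @param posterior a `vr_posterior`.
#' @param branch the clade's stem edge index (its child node subtends the
#'   clade).
#' @param type `"faster"` or `"events"`.
#' @return a posterior probability.
#' @export
clade_shift_pp <- function(posterior, branch, type = c("faster", "events")) {
  stopifnot(inherits(posterior, "vr_posterior"))
  type <- match.arg(type)
  tree <- posterior$tree
  clade <- branch_descendants(tree)[[branch]]
  if (!length(clade)) stop("branch ", branch, " subtends no clade (tip edge)")
  idx <- .post_burnin_idx(posterior)
  if (type == "faster") {
    g <- posterior$samples$log_scalars[idx, , drop = FALSE]
    mean(rowMeans(g[, clade, drop = FALSE]) >
           rowMeans(g[, -clade, drop = FALSE]))
  } else {
    ev <- posterior$events
    region <- c(branch, clade)
    hit <- unique(ev$sample[ev$type == "clade" & ev$branch %in% region])
    mean(idx %in% hit)
  }
}

#' Detect significant rate shifts in a phenogram
#'
#' Branches whose branch-event posterior probability, or clade-focal
#' posterior probability, strictly exceeds `threshold` (the conventional
#' cut-off is 0.99).
#'
#' @param phenogram a `rate_phenogram` carrying shift probabilities.
#' @param threshold posterior probability cut-off.
#' @return data.frame (`type`, `branch`, `posterior_prob`, `mean_scalar`),
#'   zero rows if nothing exceeds the threshold.
#' @export
detect_shifts <- function(phenogram, threshold = 0.99) {
  stopifnot(inherits(phenogram, "rate_phenogram"))
  br <- which(phenogram$pp_branch > threshold)
  cl <- which(phenogram$pp_clade > threshold)
  out <- data.frame(
    type = rep(c("branch", "clade"), c(length(br), length(cl))),
    branch = c(br, cl),
    posterior_prob = c(phenogram$pp_branch[br], phenogram$pp_clade[cl]),
    mean_scalar = phenogram$mean_scalar[c(br, cl)],
    stringsAsFactors = FALSE)
  out[order(out$branch), , drop = FALSE]
}
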