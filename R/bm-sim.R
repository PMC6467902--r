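#' Simulate multivariate Brownian trait evolution under a rate regime
#'
#' Draws tip values from the multivariate normal implied by Brownian motion on
#' the tree, where the trait increment along edge `j` has covariance
#' `r_j * t_j * Sigma`, `r_j` the regime's effective scalar, `t_j` the edge
#' length in time units and `Sigma = diag(sigma) %*% corr %*% diag(sigma)`
#' built from the regime's per-trait `sigma2` and correlation matrix.
#'
#' @param tree a `phylo` tree.
#' @param regime a `rate_regime` (or `NULL` for homogeneous rates with unit
#'   variance per trait).
#' @param root_state numeric vector of trait values at the root; its length
#'   sets the number of traits.
#' @param seed optional integer seed.
#' @return matrix of tip values (tips x traits) with tip labels as row names.
#' @export
simulate_multivariate_bm <- function(tree, regime = NULL,
                                     root_state = c(0, 0), seed = NULL) {
  sim <- .simulate_bm_nodes(tree, regime, root_state, seed)
  out <- sim$values[seq_len(ape::Ntip(tree)), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# Same draw, but retaining every node's value (tips 1..ntip, then internals);
# used by the colour-dataset generator to bias terminal displacements.
.simulate_bm_nodes <- function(tree, regime = NULL, root_state = c(0, 0),
                               seed = NULL) {
  check_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  p <- length(root_state)
  if (is.null(regime)) {
    r <- rep(1, nrow(tree$edge))
    Sigma <- diag(p)
  } else {
    r <- regime_scalars(regime, tree)
    sigma2 <- rep_len(regime$sigma2, p)
    corr <- regime$corr
    if (!all(dim(corr) == p))
      stop("regime correlation matrix is ", nrow(corr), "x", ncol(corr),
           " but ", p, " traits were requested")
    Sigma <- diag(sqrt(sigma2), p) %*% corr %*% diag(sqrt(sigma2), p)
  }
  Lt <- try(chol(Sigma), silent = TRUE)   # upper triangular, Sigma = Lt'Lt
  if (inherits(Lt, "try-error"))
    stop("trait covariance is not positive definite")
  ntip <- ape::Ntip(tree)
  vals <- matrix(NA_real_, ntip + tree$Nnode, p)
  vals[ntip + 1L, ] <- root_state
  edges <- rev(postorder_edges(tree))   # parents before children
  z <- matrix(rnorm(length(edges) * p), length(edges), p)
  for (k in seq_along(edges)) {
    e <- edges[k]
    vals[tree$edge[e, 2L], ] <- vals[tree$edge[e, 1L], ] +
      sqrt(r[e] * tree$edge.length[e]) * drop(z[k, ] %*% Lt)
  }
  list(values = vals, scalars = r)
}
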