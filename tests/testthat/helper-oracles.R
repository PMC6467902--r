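# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately uses a different algorithm from the implementation
# it checks (dense linear algebra instead of pruning, explicit path
# enumeration instead of the vectorised metric, etc.).

# Dense multivariate-normal log-likelihood of the variable-rates BM model:
# among-tip covariance from rate-scaled shared path lengths, trait covariance
# R, evaluated by brute-force inversion.
dense_bm_loglik <- function(tree, X, g, R, root) {
  n <- ape::Ntip(tree)
  p <- ncol(X)
  tr2 <- tree
  tr2$edge.length <- tree$edge.length * exp(g)
  C <- ape::vcv(tr2)[tree$tip.label, tree$tip.label]
  E <- sweep(X[tree$tip.label, , drop = FALSE], 2, root)
  iC <- solve(C)
  iR <- solve(R)
  as.numeric(-0.5 * (n * p * log(2 * pi) +
                       p * determinant(C)$modulus +
                       n * determinant(R)$modulus +
                       sum(diag(iR %*% t(E) %*% iC %*% E))))
}

# Brute-force TRES: explicit enumeration of each tip's root path through
# repeated parent lookups on the edge matrix, no shared code with tres().
brute_tres <- function(tree, edge_values) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- numeric(ntip)
  for (tip in seq_len(ntip)) {
    node <- tip
    ls <- numeric(0)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      ls <- c(ls, edge_values[e])
      node <- tree$edge[e, 1]
    }
    w <- 1 / 2^(seq_along(ls) - 1)
    out[tip] <- sum(w * ls) / sum(w)
  }
  names(out) <- tree$tip.label
  out
}

# Dense GLS ancestral states under BM (conditional means given tips, with the
# GLS root), via the full node-node covariance matrix.
dense_anc <- function(tree, x) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  x <- x[tree$tip.label]
  dmat <- ape::dist.nodes(tree)
  depth <- dmat[n + 1L, ]
  Call <- (outer(depth, depth, `+`) - dmat) / 2
  Ct <- Call[1:n, 1:n]
  iC <- solve(Ct)
  mu <- sum(iC %*% x) / sum(iC)
  drop(mu + Call[(n + 1):N, 1:n] %*% iC %*% (x - mu))
}

# Ordinary (non-phylogenetic) reduced major axis fit.
ordinary_rma <- function(x, y) {
  b <- sign(cov(x, y)) * sd(y) / sd(x)
  list(slope = b, intercept = mean(y) - b * mean(x), r2 = cor(x, y)^2)
}

# A homogeneous rate_regime with a given 2x2 trait covariance.
regime_from_cov <- function(S, tree) {
  structure(list(events = data.frame(type = character(0),
                                     branch = integer(0),
                                     scalar = numeric(0)),
                 sigma2 = diag(S), corr = stats::cov2cor(S),
                 n_edge = nrow(tree$edge)),
            class = "rate_regime")
}

# Circular mean direction (degrees) and mean resultant length.
circ_stats <- function(deg) {
  th <- deg * pi / 180
  c1 <- mean(cos(th)); s1 <- mean(sin(th))
  list(mean = (atan2(s1, c1) * 180 / pi) %% 360,
       R = sqrt(c1^2 + s1^2))
}

# Smallest absolute angular difference in degrees.
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
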