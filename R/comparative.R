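# Phylogenetic reduced major axis regression under an ML estimate of
# Pagel's lambda, and the Clarke (1980) slope test with non-integer degrees
# of freedom.

.lambda_vcv <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# Profile log-likelihood of lambda for a (possibly multivariate) BM model:
# the GLS mean and the among-trait covariance are profiled out at their ML
# values (divisor n).
.lambda_profile_ll <- function(lambda, C, X) {
  n <- nrow(X); p <- ncol(X)
  Cl <- .lambda_vcv(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetC <- 2 * sum(log(diag(ch)))
  iC1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- colSums(iC1 * X) / sum(iC1)
  E <- sweep(X, 2, a)
  W <- backsolve(ch, forwardsolve(t(ch), E))
  Rhat <- crossprod(E, W) / n
  detR <- determinant(Rhat, logarithm = TRUE)
  if (detR$sign <= 0) return(-Inf)
  -0.5 * (n * p * log(2 * pi) + p * logdetC +
            n * as.numeric(detR$modulus) + n * p)
}

#' Maximum likelihood estimate of Pagel's lambda
#'
#' Bounded optimisation of the Brownian-motion profile likelihood on
#' `[0, 1]`, where lambda multiplies the off-diagonal (shared-path) entries
#' of the among-tip covariance.  For a trait matrix a single joint lambda is
#' estimated with the among-trait covariance profiled out.  On a star tree
#' the likelihood is flat in lambda; the fit is then flagged unidentifiable.
#'
#' @param tree a `phylo` tree.
#' @param traits named tip vector, or matrix with tips as row names.
#' @return list: `lambda`, `logLik`, `identifiable` (FALSE when the profile
#'   is flat to within numerical tolerance).
#' @export
ml_lambda <- function(tree, traits) {
  check_tree(tree)
  if (is.null(dim(traits)))
    traits <- matrix(traits, ncol = 1, dimnames = list(names(traits)))
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("traits must be named by tip label")
  if (!all(tree$tip.label %in% rownames(traits)))
    stop("traits missing for some tips")
  X <- traits[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("traits contain missing values")
  C <- ape::vcv(tree)
  probe <- vapply(c(0, 0.5, 1), function(l) .lambda_profile_ll(l, C, X),
                  numeric(1))
  if (any(!is.finite(probe)))
    stop("lambda profile likelihood not finite; check the tree and traits")
  if (diff(range(probe)) < 1e-9 * max(1, abs(probe[1]))) {
    return(list(lambda = 1, logLik = probe[3], identifiable = FALSE))
  }
  opt <- optimise(function(l) .lambda_profile_ll(l, C, X), c(0, 1),
                  maximum = TRUE, tol = 1e-8)
  # compare against the boundaries, which optimise() can miss
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, probe[1], probe[3])
  best <- which.max(ll)
  list(lambda = cand[best], logLik = ll[best], identifiable = TRUE)
}

#' Phylogenetic reduced major axis regression
#'
#' Fits the RMA (standardised major axis) line relating two tip traits using
#' evolutionary variances and covariance estimated by GLS on a
#' lambda-transformed tree, with one lambda estimated jointly for the
#' bivariate pair by maximum likelihood.  The slope is
#' `sign(cov) * sqrt(var_y / var_x)` and the line passes through the GLS
#' means.  The hypothesis `slope = h0_slope` is tested with Clarke's (1980)
#' rotation test: `T = |log|b| - log|h0|| / sqrt((1 - r2)/(n - 2))` referred
#' to a t distribution with the non-integer degrees of freedom
#' `2 + (n - 2)/(1 + r2/2)`.
#'
#' @param tree a `phylo` tree.
#' @param x,y named tip vectors.
#' @param h0_slope hypothesised slope (default 1, the one-to-one line).
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return object of class `phylo_rma`: slope, intercept, `r2`, `lambda`,
#'   `T`, `df`, `p_value`, `n`, the evolutionary covariance matrix and GLS
#'   means.
#' @export
phylo_rma <- function(tree, x, y, h0_slope = 1, lambda = "ML") {
  check_tree(tree)
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by tip label")
  if (!all(tree$tip.label %in% names(x)) ||
      !all(tree$tip.label %in% names(y)))
    stop("x and y must cover every tip")
  X <- cbind(x = x[tree$tip.label], y = y[tree$tip.label])
  if (anyNA(X)) stop("x and y must be complete")
  n <- nrow(X)
  C <- ape::vcv(tree)
  if (identical(lambda, "ML")) {
    # perfectly collinear or constant traits make the bivariate profile
    # degenerate; fall back to the univariate lambda of x
    lam <- tryCatch(ml_lambda(tree, X), error = function(e)
      ml_lambda(tree, X[, 1, drop = FALSE]))
    lambda_hat <- lam$lambda
    identifiable <- lam$identifiable
  } else {
    lambda_hat <- as.numeric(lambda)
    if (lambda_hat < 0 || lambda_hat > 1) stop("lambda must be in [0, 1]")
    identifiable <- TRUE
  }
  Cl <- .lambda_vcv(C, lambda_hat)
  ch <- chol(Cl)
  iC1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- colSums(iC1 * X) / sum(iC1)
  E <- sweep(X, 2, a)
  W <- backsolve(ch, forwardsolve(t(ch), E))
  V <- crossprod(E, W) / (n - 1)      # evolutionary variances / covariance
  if (V[1, 1] <= 0 || V[2, 2] <= 0 ||
      V[1, 1] < .Machine$double.eps * 100 * abs(V[2, 2]) ||
      V[2, 2] < .Machine$double.eps * 100 * abs(V[1, 1]))
    stop("zero evolutionary variance in x or y; RMA slope undefined")
  slope <- sign(V[1, 2]) * sqrt(V[2, 2] / V[1, 1])
  if (slope == 0) slope <- sqrt(V[2, 2] / V[1, 1])  # cov exactly 0: take +
  intercept <- a[2] - slope * a[1]
  r2 <- V[1, 2]^2 / (V[1, 1] * V[2, 2])
  if (sign(slope) != sign(h0_slope)) {
    warning("slope and h0_slope have opposite signs; test statistic set to 0")
    Tstat <- 0
  } else if (r2 >= 1 - 1e-12) {
    # perfect correlation: the slope is known without error
    Tstat <- if (abs(log(abs(slope)) - log(abs(h0_slope))) < 1e-12) 0 else
      Inf
  } else {
    Tstat <- abs(log(abs(slope)) - log(abs(h0_slope))) /
      sqrt((1 - r2) / (n - 2))
  }
  df <- 2 + (n - 2) / (1 + r2 / 2)
  p <- 2 * pt(Tstat, df = df, lower.tail = FALSE)
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 r2 = unname(r2), lambda = lambda_hat,
                 lambda_identifiable = identifiable,
                 T = unname(Tstat), df = unname(df), p_value = unname(p),
                 n = n, h0_slope = h0_slope, evolutionary_vcv = V,
                 means = a),
            class = "phylo_rma")
}

#' @export
print.phylo_rma <- function(x, digits = 4, ...) {
  cat("Phylogenetic reduced major axis regression (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  y = %.*g + %.*g x   (R2 = %.*g, lambda = %.*g%s)\n",
              digits, x$intercept, digits, x$slope, digits, x$r2,
              digits, x$lambda,
              if (x$lambda_identifiable) "" else ", unidentifiable"))
  cat(sprintf("  H0 slope = %g: T = %.*g, d.f. = %.*g, P = %.3g\n",
              x$h0_slope, digits, x$T, digits, x$df, x$p_value))
  invisible(x)
}
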