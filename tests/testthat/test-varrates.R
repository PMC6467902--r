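test_that("pruning likelihood equals the dense oracle on small trees", {
  set.seed(1)
  for (i in 1:8) {
    tr <- simulate_tree(sample(4:6, 1), 1, 0)
    ne <- nrow(tr$edge)
    g <- rnorm(ne)
    A <- matrix(rnorm(4), 2)
    R <- crossprod(A) + diag(0.3, 2)
    X <- simulate_multivariate_bm(tr, NULL, c(0, 0))
    root <- rnorm(2)
    cfg <- data.frame(type = "branch", branch = seq_len(ne),
                      scalar = exp(g))
    expect_equal(mv_bm_loglik(tr, X, cfg, R, root),
                 dense_bm_loglik(tr, X, g, R, root), tolerance = 1e-10)
  }
})

test_that("doubling all scalars equals doubling all branch lengths", {
  tr <- simulate_tree(10, 1, 0, seed = 2)
  X <- simulate_multivariate_bm(tr, NULL, c(0, 0), seed = 3)
  R <- diag(2)
  cfg2 <- data.frame(type = "branch", branch = seq_len(nrow(tr$edge)),
                     scalar = 2)
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  expect_equal(mv_bm_loglik(tr, X, cfg2, R),
               mv_bm_loglik(tr2, X, NULL, R), tolerance = 1e-10)
  # and the centred likelihood is invariant to the global rescaling
  expect_equal(mv_bm_loglik(tr, X, cfg2, R, center = TRUE),
               mv_bm_loglik(tr, X, NULL, R, center = TRUE),
               tolerance = 1e-10)
})

test_that("two-tip star likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  X <- matrix(c(0.3, -1.1), 2, dimnames = list(c("a", "b")))
  # tips iid Normal(root, 1): density = prod dnorm(x, 0, 1)
  expect_equal(mv_bm_loglik(tr, X, NULL, R = matrix(1), root = 0),
               sum(dnorm(c(0.3, -1.1), 0, 1, log = TRUE)),
               tolerance = 1e-12)
})

test_that("phenogram summaries are correct arithmetic on samples", {
  tr <- simulate_tree(6, 1, 0, seed = 4)
  ne <- nrow(tr$edge)
  # hand-built posterior: scalar alternating 1 and 3 on edge 2
  g <- matrix(0, 10, ne)
  g[seq(2, 10, 2), 2] <- log(3)
  fake <- structure(list(
    tree = tr,
    samples = list(iter = 1:10, K = rep(0:1, 5), loglik = rep(0, 10),
                   log_scalars = g,
                   cover_any = matrix(0L, 10, ne),
                   cover_branch = matrix(0L, 10, ne),
                   clade_focal = matrix(0L, 10, ne)),
    settings = list(iterations = 10, burnin = 0, thin = 1)),
    class = "vr_posterior")
  ph <- summarise_rate_phenogram(fake)
  expect_equal(ph$mean_scalar[2], 2)
  expect_equal(ph$mean_scalar[-2], rep(1, ne - 1))
  expect_equal(ph$l, ph$mean_scalar * tr$edge.length)
  # an all-null posterior reproduces the time tree
  fake$samples$log_scalars <- matrix(0, 10, ne)
  ph0 <- summarise_rate_phenogram(fake)
  expect_equal(ph0$scaled_tree$edge.length, tr$edge.length)
})

test_that("detect_shifts respects thresholds and monotonicity", {
  tr <- simulate_tree(8, 1, 0, seed = 5)
  ph <- rate_phenogram(tr)
  expect_equal(nrow(detect_shifts(ph)), 0)
  ph$pp_clade[3] <- 1.0
  ph$pp_branch[7] <- 0.6
  hi <- detect_shifts(ph, 0.99)
  lo <- detect_shifts(ph, 0.5)
  expect_equal(hi$type, "clade")
  expect_equal(hi$branch, 3)
  expect_true(all(paste(hi$type, hi$branch) %in% paste(lo$type, lo$branch)))
  expect_equal(nrow(lo), 2)
})

test_that("short chains run, mix and are seed-reproducible", {
  tr <- simulate_tree(16, 1, 0, seed = 6)
  X <- simulate_multivariate_bm(tr, NULL, c(0, 0), seed = 7)
  p1 <- rjmcmc_variable_rates(tr, X, iterations = 5000, thin = 10,
                              seed = 8)
  p2 <- rjmcmc_variable_rates(tr, X, iterations = 5000, thin = 10,
                              seed = 8)
  expect_identical(p1$samples$log_scalars, p2$samples$log_scalars)
  expect_gt(sum(p1$acceptance$accepted), 0)
  expect_true(all(is.finite(p1$samples$loglik)))
})

test_that("independent chains agree on per-branch mean scalars", {
  tr <- simulate_tree(48, 1, 0, seed = 9)
  reg <- assign_rate_regime(tr, 1, 0, log_scalar_sd = 0,
                            min_clade_size = 10, seed = 10)
  reg$events$scalar <- 8
  X <- simulate_multivariate_bm(tr, reg, c(0, 0), seed = 11)
  ph1 <- summarise_rate_phenogram(
    rjmcmc_variable_rates(tr, X, iterations = 4e4, thin = 40, seed = 12))
  ph2 <- summarise_rate_phenogram(
    rjmcmc_variable_rates(tr, X, iterations = 4e4, thin = 40, seed = 13))
  expect_gt(cor(ph1$mean_log_scalar, ph2$mean_log_scalar), 0.9)
})
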