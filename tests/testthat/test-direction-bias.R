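test_that("ancestral states honour symmetry and invariance", {
  # symmetric cherry: the root estimate is the tip midpoint
  tr <- ape::read.tree(text = "(a:1,b:1);")
  a <- ancestral_states_ml(tr, c(a = 0, b = 4))
  expect_equal(unname(a[1, 1]), 2)
  # constant tips give constant nodes
  tr2 <- simulate_tree(20, 1, 0, seed = 1)
  cst <- setNames(rep(3.3, 20), tr2$tip.label)
  expect_equal(unname(ancestral_states_ml(tr2, cst)[, 1]),
               rep(3.3, tr2$Nnode))
})

test_that("ancestral states equal the dense GLS oracle", {
  set.seed(2)
  for (i in 1:6) {
    tr <- simulate_tree(sample(5:12, 1), 1, 0)
    x <- setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    got <- ancestral_states_ml(tr, x)[, 1]
    expect_equal(unname(got), unname(dense_anc(tr, x)), tolerance = 1e-10)
  }
})

test_that("trajectory angles follow the axis conventions", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  # place tips so each displacement from the reconstructed parent is known
  vals <- rbind(a = c(5, 0), b = c(-5, 0), c = c(0, 5), d = c(0, -5))
  rates <- setNames(rep(1, 4), rownames(vals))
  traj <- tip_trajectories(tr, vals, rates)
  ang <- setNames(traj$angle, traj$species)
  # a and b sit opposite along PC1; their parent is reconstructed between
  expect_equal(unname(ang["a"]), 0, tolerance = 1e-8)
  expect_equal(unname(ang["b"]), 180, tolerance = 1e-8)
  expect_equal(unname(ang["c"]), 90, tolerance = 1e-8)
  expect_equal(unname(ang["d"]), 270, tolerance = 1e-8)
})

test_that("zero-magnitude trajectories are dropped with a warning", {
  tr <- simulate_tree(10, 1, 0, seed = 3)
  cst <- matrix(1, 10, 2, dimnames = list(tr$tip.label))
  rates <- setNames(rep(1, 10), tr$tip.label)
  expect_warning(traj <- tip_trajectories(tr, cst, rates),
                 "zero-magnitude")
  expect_equal(nrow(traj), 0)
})

test_that("generator bias is recovered through reconstruction round-trip", {
  tr <- simulate_tree(300, 1, 0, seed = 4)
  reg <- assign_rate_regime(tr, 0, 150, log_scalar_sd = 1.5, seed = 5)
  ds <- simulate_colour_dataset(tr, reg, reg, n_patches = 1,
                                n_specimens = 1, intraspecific_sd = 0,
                                bias_angle = 0, bias_concentration = 12,
                                seed = 6)
  tv <- ds$true_tips[ds$true_tips$sex == "male", ]
  M <- as.matrix(tv[, c("pc1", "pc2")]); rownames(M) <- tv$species
  term <- which(tr$edge[, 2] <= 300)
  rates <- setNames(ds$true_rates$male[term][order(tr$edge[term, 2])],
                    tr$tip.label)
  traj <- tip_trajectories(tr, M, rates)
  fast_tips <- tr$tip.label[tr$edge[ds$fast_edges$male, 2]]
  sub <- traj[traj$species %in% fast_tips, ]
  expect_gt(nrow(sub), 15)
  expect_lt(ang_diff(circ_stats(sub$angle)$mean, 0), 15)
})

test_that("degenerate equal-rate data never flags", {
  set.seed(7)
  traj <- data.frame(angle = runif(500, 0, 360), rate = 2)
  st <- segment_rate_test(traj, 20, 500, seed = 8)
  expect_true(all(st$flag == "null"))
  expect_true(all(abs(st$observed_mean - 2) < 1e-12))
})

test_that("segment bookkeeping: partition, counts, conservation, seed", {
  set.seed(9)
  traj <- data.frame(angle = c(runif(400, 0, 360), 0, 360, 359.999),
                     rate = rlnorm(403))
  st <- segment_rate_test(traj, 20, 300, seed = 10)
  expect_equal(nrow(st), 18)
  expect_equal(sum(st$count), 403)
  # angle 360 wraps into the first segment
  expect_gte(st$count[1], 2)
  # total rate mass is conserved
  expect_equal(sum(st$count * st$observed_mean), sum(traj$rate),
               tolerance = 1e-9)
  # fixed seed fixes the bands; ordering of rows is irrelevant
  st2 <- segment_rate_test(traj[sample(nrow(traj)), ], 20, 300, seed = 10)
  expect_equal(st$observed_mean, st2$observed_mean)
  expect_equal(st$null_lo, st2$null_lo)
  expect_equal(st$null_hi, st2$null_hi)
  expect_error(segment_rate_test(traj, 20, 50), "n_perm")
  expect_error(segment_rate_test(traj, 23), "divide")
})

test_that("rotating all trajectories rotates the flags", {
  set.seed(11)
  ang <- runif(3000, 0, 360)
  rate <- rlnorm(3000)
  rate[abs(ang - 90) <= 10] <- rate[abs(ang - 90) <= 10] * 5
  st0 <- segment_rate_test(data.frame(angle = ang, rate = rate), 20, 500,
                           seed = 12)
  for (shift in c(40, 180, 300)) {
    st1 <- segment_rate_test(data.frame(angle = (ang + shift) %% 360,
                                        rate = rate), 20, 500, seed = 12)
    k <- shift / 20
    expect_equal(st1$flag, st0$flag[((seq_len(18) - 1 - k) %% 18) + 1])
  }
})

test_that("stratified runs match direct calls and handle identical sexes", {
  set.seed(13)
  df <- data.frame(angle = runif(800, 0, 360), rate = rlnorm(800),
                   sex = rep(c("male", "female"), 400),
                   patch = "crown")
  df$rate[df$sex == "female"] <- df$rate[df$sex == "male"]
  df$angle[df$sex == "female"] <- df$angle[df$sex == "male"]
  one <- pooled_and_stratified(df, "all", n_perm = 300, seed = 14)
  direct <- segment_rate_test(df, n_perm = 300, seed = 14)
  expect_equal(one$all$observed_mean, direct$observed_mean)
  per_sex <- pooled_and_stratified(df, "sex", n_perm = 300, seed = 15)
  expect_equal(per_sex$male$observed_mean, per_sex$female$observed_mean)
  expect_equal(per_sex$male$flag, per_sex$female$flag)
})
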