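test_that("isotropic displacements have vanishing circular resultant", {
  tr <- simulate_tree(500, 1, 0, seed = 1)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 1,
                                n_specimens = 1, intraspecific_sd = 0,
                                bias_angle = 0, bias_concentration = 0,
                                seed = 2)
  ang <- ds$displacements$angle[ds$displacements$sex == "male"]
  expect_equal(length(ang), 500)
  expect_lt(circ_stats(ang)$R, 0.1)
})

test_that("biased fast displacements concentrate on the target angle", {
  tr <- simulate_tree(500, 1, 0, seed = 3)
  reg <- assign_rate_regime(tr, 0, 120, log_scalar_sd = 1, seed = 4)
  ds <- simulate_colour_dataset(tr, reg, reg, n_patches = 1,
                                n_specimens = 1, intraspecific_sd = 0,
                                bias_angle = 0, bias_concentration = 8,
                                seed = 5)
  d <- ds$displacements
  fast <- d$fast & d$sex == "male"
  expect_gt(sum(fast), 20)
  expect_lt(ang_diff(circ_stats(d$angle[fast])$mean, 0), 10)
})

test_that("zero intraspecific noise collapses specimens to the tip value", {
  tr <- simulate_tree(10, 1, 0, seed = 6)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 2,
                                n_specimens = 3, intraspecific_sd = 0,
                                seed = 7)
  sp <- ds$specimens
  key <- paste(sp$species, sp$sex, sp$patch)
  for (ch in c("channel_v", "channel_s", "channel_m", "channel_l")) {
    spread <- tapply(sp[[ch]], key, function(v) diff(range(v)))
    expect_true(all(spread < 1e-12))
  }
})

test_that("receptor encodings round-trip through the colourspace maps", {
  tr <- simulate_tree(15, 1, 0, seed = 8)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 1,
                                n_specimens = 1, intraspecific_sd = 0,
                                seed = 9)
  xyz <- to_tetrahedral(to_relative_stimuli(ds$specimens))
  recovered <- cbind(xyz[, "x"], xyz[, "y"]) / ds$pc_scale
  truth <- ds$true_tips[match(paste(ds$specimens$species,
                                    ds$specimens$sex,
                                    ds$specimens$patch),
                              paste(ds$true_tips$species,
                                    ds$true_tips$sex,
                                    ds$true_tips$patch)), ]
  expect_equal(recovered[, 1], truth$pc1, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(recovered[, 2], truth$pc2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(xyz[, "z"]), rep(0, nrow(xyz)), tolerance = 1e-12)
})

test_that("bias with no fast branches warns and stays valid", {
  tr <- simulate_tree(12, 1, 0, seed = 10)
  w <- testthat::capture_warnings(
    ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 1,
                                  n_specimens = 1, bias_angle = 0,
                                  bias_concentration = 5, seed = 11))
  expect_length(w, 2)  # one per sex
  expect_match(w, "vacuous", all = TRUE)
  expect_s3_class(ds, "colour_dataset")
  expect_equal(nrow(ds$specimens), 12 * 2)
})

test_that("every species has specimens of both sexes and receptor values are valid", {
  tr <- simulate_tree(20, 1, 0, seed = 12)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 3,
                                n_specimens = 2, seed = 13)
  sp <- ds$specimens
  tab <- table(sp$species, sp$sex)
  expect_true(all(tab == 3 * 2))
  ch <- as.matrix(sp[, c("channel_v", "channel_s", "channel_m",
                         "channel_l")])
  expect_true(all(ch >= 0))
  expect_equal(rowSums(ch), rep(1, nrow(ch)), tolerance = 1e-9)
})
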