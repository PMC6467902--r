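test_that("relative stimuli normalise correctly and reject bad input", {
  expect_equal(drop(to_relative_stimuli(c(1, 1, 1, 1))),
               c(v = .25, s = .25, m = .25, l = .25))
  expect_equal(drop(to_relative_stimuli(c(2, 0, 0, 0))),
               c(v = 1, s = 0, m = 0, l = 0))
  expect_equal(drop(to_relative_stimuli(c(1, 2, 3, 4))),
               c(v = .1, s = .2, m = .3, l = .4))
  expect_error(to_relative_stimuli(c(0, 0, 0, 0)), "all-zero")
  expect_error(to_relative_stimuli(c(-1, 1, 1, 1)), "non-negative")
})

test_that("the tetrahedral projection has the standard geometry", {
  # achromatic centre at the origin
  expect_equal(drop(to_tetrahedral(c(.25, .25, .25, .25))),
               c(x = 0, y = 0, z = 0))
  # four pure-receptor vertices at distance 0.75 from the origin
  V <- to_tetrahedral(diag(4))
  expect_equal(unname(sqrt(rowSums(V^2))), rep(0.75, 4))
  # regular tetrahedron: all six vertex-vertex distances equal
  dd <- dist(V)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-12)
  # v vertex on the vertical axis
  expect_equal(drop(to_tetrahedral(c(1, 0, 0, 0))), c(x = 0, y = 0, z = .75))
  expect_error(to_tetrahedral(c(.5, .5, .5, .5)), "sum to 1")
})

test_that("simplex -> tetrahedron -> simplex is the identity", {
  set.seed(1)
  q <- matrix(rexp(400), ncol = 4)
  usml <- to_relative_stimuli(q)
  back <- tetrahedral_to_stimuli(to_tetrahedral(usml))
  expect_equal(back, usml, tolerance = 1e-12)
})

test_that("device mapping recovers an exact linear map and flags bad designs", {
  set.seed(2)
  D <- matrix(runif(300), ncol = 3)
  A <- matrix(runif(12, -1, 1), 3, 4)
  b <- runif(4)
  cone <- sweep(D %*% A, 2, b, `+`)
  fit <- fit_device_mapping(D, cone, degree = 1)
  expect_equal(unname(fit$coefficients[1, ]), b, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[-1, ]), unname(A), tolerance = 1e-10)
  expect_equal(unname(fit$r), rep(1, 4), tolerance = 1e-10)
  # noisy calibration still validates strongly
  noisy <- cone + matrix(rnorm(length(cone), 0, 0.01), nrow(cone))
  fit2 <- fit_device_mapping(D, noisy, degree = 1)
  expect_true(all(fit2$r > 0.99))
  pred <- predict_cone_catch(fit, D)
  expect_equal(unname(pred), unname(cone), tolerance = 1e-10)
  # underdetermined and rank-deficient designs fail
  expect_error(fit_device_mapping(D[1:3, ], cone[1:3, ]), "underdetermined")
  expect_error(fit_device_mapping(cbind(D[, 1], D[, 1]), cone),
               "rank-deficient")
})

test_that("colourspace PCA behaves on degenerate and isotropic clouds", {
  # collinear points: PC1 explains everything
  t_ <- seq(0, 1, length.out = 50)
  line <- cbind(t_, 2 * t_, -t_)
  p1 <- pca_colourspace(line)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)
  # isotropic cloud: roughly a third each
  set.seed(3)
  cloud <- matrix(rnorm(30000), ncol = 3)
  p2 <- pca_colourspace(cloud)
  expect_true(all(abs(p2$var_explained - 1 / 3) < 0.02))
  # orthogonal reconstruction is exact
  rec <- sweep(p2$scores %*% t(p2$loadings), 2, -p2$center)
  expect_equal(rec, cloud, tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention and order invariance
  p3 <- pca_colourspace(cloud[sample(nrow(cloud)), ])
  expect_equal(abs(p3$loadings), abs(p2$loadings), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_error(pca_colourspace(matrix(1, 10, 3)), "identical")
})

test_that("species means, counts and dispersion are correct", {
  rec <- data.frame(
    species = rep("sp1", 4), sex = rep(c("male", "female"), each = 2),
    specimen = paste0("s", 1:4), patch = "crown",
    channel_v = c(.25, .25, .25, .25), channel_s = c(.25, .25, .25, .25),
    channel_m = c(.25, .25, .35, .15), channel_l = c(.25, .25, .15, .35))
  prof <- species_means(rec)
  m <- prof[prof$sex == "male", ]
  expect_equal(c(m$x, m$y, m$z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(prof$n_specimens, c(2L, 2L))
  expect_equal(m$dispersion, 0, tolerance = 1e-12)
  f <- prof[prof$sex == "female", ]
  expect_gt(f$dispersion, 0)
  # missing cells are listed: sp2 lacks its female/crown cell
  rec2 <- rec
  rec2$species[rec2$sex == "male"] <- "sp2"
  rec2 <- rec2[!(rec2$species == "sp2" & rec2$sex == "female"), ]
  expect_error(species_means(rec2), "sp2/female/crown")
})

test_that("dichromatism handles hand-computable and degenerate cases", {
  base <- expand.grid(species = c("sp1", "sp2"), sex = c("male", "female"),
                      patch = plumage_patches, stringsAsFactors = FALSE)
  base$specimen <- paste0(base$species, base$sex, "1")
  base$channel_v <- .25; base$channel_s <- .25
  base$channel_m <- .25; base$channel_l <- .25
  # sp2 males differ on the crown only, by a known tetra distance
  i <- base$species == "sp2" & base$sex == "male" & base$patch == "crown"
  base$channel_v[i] <- .45; base$channel_m[i] <- .05
  d_one <- sqrt(sum((to_tetrahedral(c(.45, .25, .05, .25)) -
                       to_tetrahedral(c(.25, .25, .25, .25)))^2))
  prof <- species_means(base)
  dm <- compute_dichromatism(prof, "mean")
  dx <- compute_dichromatism(prof, "max")
  expect_equal(dm$dichromatism[dm$species == "sp1"], 0, tolerance = 1e-12)
  expect_equal(dx$dichromatism[dx$species == "sp1"], 0, tolerance = 1e-12)
  expect_equal(dm$dichromatism[dm$species == "sp2"], d_one / 10,
               tolerance = 1e-10)
  expect_equal(dx$dichromatism[dx$species == "sp2"], d_one,
               tolerance = 1e-10)
  expect_true(all(dx$dichromatism >= dm$dichromatism))
  # a species missing one sex is excluded with a warning
  prof2 <- prof[!(prof$species == "sp1" & prof$sex == "female"), ]
  expect_warning(d2 <- compute_dichromatism(prof2, "mean"), "sp1")
  expect_false("sp1" %in% d2$species)
})

test_that("dichromatism is invariant under rigid rotation of all points", {
  set.seed(4)
  tr <- simulate_tree(12, 1, 0)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 2,
                                n_specimens = 2,
                                male_offset = c(0.4, -0.2), seed = 5)
  prof <- species_means(ds)
  d0 <- compute_dichromatism(prof, "mean")$dichromatism
  th <- 0.71
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  prof2 <- prof
  prof2[, c("x", "y", "z")] <- as.matrix(prof[, c("x", "y", "z")]) %*%
    t(Rot)
  expect_equal(compute_dichromatism(prof2, "mean")$dichromatism, d0,
               tolerance = 1e-10)
})

test_that("dichromatism recovers the programmed male-female offset", {
  tr <- simulate_tree(25, 1, 0, seed = 6)
  off <- c(0.5, -0.3)
  ds <- simulate_colour_dataset(tr, NULL, NULL, n_patches = 4,
                                n_specimens = 3, intraspecific_sd = 0.02,
                                male_offset = off,
                                shared_sex_draw = TRUE, seed = 7)
  prof <- species_means(ds)
  d <- compute_dichromatism(prof, "mean")
  programmed <- sqrt(sum(off^2)) * ds$pc_scale
  # sampling error scale: noise sd (tetra units) / sqrt(specimens), per patch
  expect_equal(mean(d$dichromatism), programmed,
               tolerance = 0.15)
  expect_equal(unname(quantile(d$dichromatism, .5)), programmed,
               tolerance = 0.15)
})

test_that("mechanism classification is total, exclusive and sensible", {
  expect_equal(as.character(classify_mechanism(rbind(c(0, 0, 0, 1)))),
               "carotenoid")
  expect_equal(as.character(classify_mechanism(rbind(c(1, 0, 0, 0)))),
               "structural")
  expect_equal(as.character(classify_mechanism(rbind(c(0, 1, 0, 0)))),
               "structural")
  expect_equal(as.character(classify_mechanism(rbind(rep(.25, 4)))),
               "intermediate")
  # exhaustive on a random sweep of the simplex
  set.seed(8)
  q <- to_relative_stimuli(matrix(rexp(4000), ncol = 4))
  lab <- classify_mechanism(q)
  expect_false(anyNA(lab))
  expect_setequal(levels(lab), c("carotenoid", "intermediate", "structural"))
})
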