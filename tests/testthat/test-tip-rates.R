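test_that("hand-worked equal-splits cases evaluate exactly", {
  # chain trees: one tip whose path lengths are known terminal -> root
  chain1 <- ape::read.tree(text = "(a:5,b:5);")
  expect_equal(tres(chain1)$tres, c(5, 5))
  # path (2, 3): m = (1*2 + 0.5*3) / 1.5
  t2 <- ape::read.tree(text = "((a:2,b:2):3,c:5);")
  out <- tres(t2)
  expect_equal(out$tres[out$tip == "a"], (2 + 0.5 * 3) / 1.5)
  expect_equal(out$tres[out$tip == "a"], 2.333333, tolerance = 1e-6)
  expect_equal(out$tres[out$tip == "c"], 5)
  # path (2, 3, 4): m = (2 + 1.5 + 1) / 1.75
  t3 <- ape::read.tree(text = "(((a:2,b:2):3,c:5):4,d:9);")
  out3 <- tres(t3)
  expect_equal(out3$tres[out3$tip == "a"], (2 + 0.5 * 3 + 0.25 * 4) / 1.75)
  expect_equal(out3$tres[out3$tip == "a"], 2.571429, tolerance = 1e-6)
  expect_equal(out3$n_edges[out3$tip == "a"], 3)
})

test_that("tres equals brute-force path enumeration on random trees", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    tr <- ape::rtree(n)   # random branch lengths from a different generator
    got <- tres(tr)
    want <- brute_tres(tr, tr$edge.length)
    expect_identical(got$tip, sort(tr$tip.label))
    expect_equal(got$tres, unname(want[got$tip]), tolerance = 1e-12)
  }
})

test_that("tres is a convex combination of the path's branch values", {
  set.seed(2)
  for (i in 1:20) {
    tr <- ape::rtree(sample(5:80, 1))
    out <- tres(tr)
    paths <- plumrates:::tip_root_paths(tr)
    names(paths) <- tr$tip.label
    for (tip in out$tip) {
      vals <- tr$edge.length[paths[[tip]]]
      m <- out$tres[out$tip == tip]
      expect_gte(m, min(vals) - 1e-12)
      expect_lte(m, max(vals) + 1e-12)
    }
  }
})

test_that("edges beyond depth 20 are numerically irrelevant", {
  # a caterpillar tree: one tip with a very deep path
  n <- 30
  txt <- paste0(paste(rep("(", n - 1), collapse = ""), "t1:1",
                paste(sprintf(",t%d:1):1", 2:(n - 1)), collapse = ""),
                ",t", n, ":1);")
  tr <- ape::read.tree(text = txt)
  deep <- tres(tr)
  # truncating the path at 20 edges changes nothing beyond 1e-5 of the max
  paths <- plumrates:::tip_root_paths(tr)
  names(paths) <- tr$tip.label
  for (tip in c("t1", "t2")) {
    vals <- tr$edge.length[paths[[tip]]]
    w <- 0.5^(seq_along(vals) - 1)
    m_trunc <- sum((w * vals)[1:min(20, length(vals))]) /
      sum(w[1:min(20, length(vals))])
    expect_lt(abs(deep$tres[deep$tip == tip] - m_trunc),
              1e-5 * max(vals))
  }
})

test_that("the scalar variant matches tres on unit-length trees", {
  tr <- simulate_tree(20, 1, 0, seed = 3)
  scalars <- rlnorm(nrow(tr$edge), 0, 0.5)
  ph <- rate_phenogram(tr, scalars)
  # homogeneous scalars: every tip rate is 1
  ph1 <- rate_phenogram(tr, rep(1, nrow(tr$edge)))
  expect_equal(tres_per_branch_rate(ph1)$tres, rep(1, 20))
  # with unit branch lengths the two variants coincide
  tru <- tr; tru$edge.length <- rep(1, nrow(tr$edge))
  phu <- rate_phenogram(tru, scalars)
  expect_equal(tres_per_branch_rate(phu)$tres, tres(phu)$tres)
})

test_that("a terminal-branch scalar inflates only that tip and relatives", {
  tr <- simulate_tree(15, 1, 0, seed = 4)
  ne <- nrow(tr$edge)
  term <- which(tr$edge[, 2] <= 15)
  e <- term[1]
  tip <- tr$tip.label[tr$edge[e, 2]]
  scal <- rep(1, ne); scal[e] <- 10
  ph <- rate_phenogram(tr, scal)
  out <- tres_per_branch_rate(ph)
  base <- tres_per_branch_rate(rate_phenogram(tr, rep(1, ne)))
  expect_gt(out$tres[out$tip == tip], 4)   # weighted toward 10
  unchanged <- setdiff(out$tip, tip)
  expect_equal(out$tres[out$tip %in% unchanged],
               base$tres[base$tip %in% unchanged])
})
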