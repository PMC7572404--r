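test_that("normalization produces the expected dimensionless images", {
  expect_equal(normalize_series(c(2, 4, 6), "mean"), c(0.5, 1, 1.5))
  expect_equal(normalize_series(c(2, 4, 6), "initial"), c(1, 2, 3))
  expect_equal(normalize_series(c(7, 7, 7), "mean"), c(1, 1, 1))
  expect_equal(normalize_series(c(7, 7, 7), "initial"), c(1, 1, 1))
  expect_error(normalize_series(c(0, 1), "initial"), "zero")
  expect_error(normalize_series(c(-1, 1), "mean"), "zero")
})

test_that("the grey relational degree matches the hand-computed example", {
  x0 <- normalize_series(c(1, 2, 3), "mean")
  x1 <- normalize_series(c(3, 2, 1), "mean")
  g <- grey_relational_degree(x0, list(x1), rho = 0.5)
  expect_equal(unname(g), 5 / 9, tolerance = 1e-12)
  # identity comparator scores exactly 1
  gi <- grey_relational_degree(x0, list(a = x0, b = x1))
  expect_equal(unname(gi["a"]), 1)
  # all comparators identical to the reference: every degree is 1
  g1 <- grey_relational_degree(x0, list(x0, x0))
  expect_equal(unname(g1), c(1, 1))
})

test_that("vectorized degrees equal the loop oracle on random panels", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x0 <- normalize_series(runif(n, 1, 10), "mean")
    comp <- lapply(seq_len(sample(1:5, 1)), function(j) {
      normalize_series(runif(n, 1, 10), "mean")
    })
    rho <- runif(1, 0.05, 1)
    got <- grey_relational_degree(x0, comp, rho)
    want <- grd_loop_oracle(x0, comp, rho)
    expect_equal(unname(got), want, tolerance = 1e-12)
    expect_true(all(got > 0 & got <= 1))
  }
})

test_that("degrees are scale invariant and symmetric under time reversal", {
  set.seed(62)
  ref_raw <- runif(8, 5, 50)
  comp_raw <- runif(8, 5, 50)
  base <- grey_relational_degree(normalize_series(ref_raw),
                                 list(normalize_series(comp_raw)))
  for (c_mult in c(0.01, 3, 1e4)) {
    scaled <- grey_relational_degree(
      normalize_series(ref_raw),
      list(normalize_series(c_mult * comp_raw)))
    expect_equal(unname(scaled), unname(base), tolerance = 1e-12)
  }
  rev_g <- grey_relational_degree(normalize_series(rev(ref_raw)),
                                  list(normalize_series(rev(comp_raw))))
  expect_equal(unname(rev_g), unname(base), tolerance = 1e-12)
})

test_that("raising rho moves every degree toward 1 monotonically", {
  set.seed(63)
  x0 <- normalize_series(runif(10, 1, 10))
  comp <- lapply(1:3, function(i) normalize_series(runif(10, 1, 10)))
  rhos <- c(0.1, 0.3, 0.5, 0.8, 1)
  gs <- vapply(rhos, function(r) {
    grey_relational_degree(x0, comp, r)
  }, numeric(3))
  for (i in 1:3) {
    expect_true(all(diff(gs[i, ]) > 0))
    expect_true(all(gs[i, ] <= 1))
  }
})

test_that("panel degrees separate a tracking factor from a random walk", {
  set.seed(64)
  wins <- 0
  for (s in 1:20) {
    years <- 1986:2015
    ref <- 100 * cumprod(c(1, rep(1.012, 29))) * (1 + rnorm(30, 0, 0.005))
    tracker <- ref * (1 + rnorm(30, 0, 0.01))
    walk <- 100 * exp(cumsum(rnorm(30, 0, 0.08)))
    panel <- data.frame(
      region = "R1", year = rep(years, 3),
      variable = rep(c("oasis_area", "A", "B"), each = 30),
      value = c(ref, tracker, walk))
    m <- panel_grd(panel, rho = 0.5)
    if (m["R1", "A"] > m["R1", "B"]) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("panel matrix layout is stable under factor permutation", {
  panel <- data.frame(
    region = rep(c("R1", "R2"), each = 9),
    year = rep(rep(2000:2002, 3), 2),
    variable = rep(rep(c("oasis_area", "f1", "f2"), each = 3), 2),
    value = c(1, 2, 3, 1, 2, 3, 3, 1, 2,
              2, 3, 4, 2, 3, 4, 5, 1, 1))
  m1 <- panel_grd(panel, factors = c("f1", "f2"))
  m2 <- panel_grd(panel, factors = c("f2", "f1"))
  expect_equal(m1["R1", "f1"], m2["R1", "f1"])
  expect_equal(m1["R2", "f2"], m2["R2", "f2"])
  expect_equal(unname(m1["R1", "f1"]), 1)  # identical to reference
  # single region, single identity factor: one cell equal to 1
  single <- panel[panel$region == "R1" &
                    panel$variable %in% c("oasis_area", "f1"), ]
  ms <- panel_grd(single, factors = "f1")
  expect_equal(dim(ms), c(1L, 1L))
  expect_equal(unname(ms[1, 1]), 1)
  # missing factor series yields a flagged NA cell, not a drop
  holey <- panel[!(panel$region == "R2" & panel$variable == "f2"), ]
  expect_warning(mh <- panel_grd(holey, factors = c("f1", "f2")),
                 "missing")
  expect_true(is.na(mh["R2", "f2"]))
  expect_false(is.na(mh["R1", "f2"]))
})

test_that("factor ranking orders by aggregate degree and reports ties", {
  m <- structure(
    matrix(c(0.95, 0.95, 0.9, 0.9, 0.65, 0.65), 2, 3,
           dimnames = list(c("R1", "R2"), c("pop", "awd", "gdp"))),
    class = c("grd_matrix", "matrix"), rho = 0.5,
    normalization = "mean", variant = "deng")
  rk <- rank_factors(m)
  expect_equal(rk$factor, c("pop", "awd", "gdp"))
  expect_equal(rk$gamma, c(0.95, 0.9, 0.65))
  expect_false(any(rk$tied))
  tied <- m; tied[, "awd"] <- c(0.95, 0.95)
  rk2 <- rank_factors(tied)
  expect_equal(rk2$factor[1:2], c("awd", "pop"))  # alphabetical within tie
  expect_true(all(rk2$tied[1:2]))
  expect_equal(rk2$rank[1:2], c(1L, 1L))
})
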