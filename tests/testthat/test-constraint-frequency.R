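test_that("distribution frequency matches hand counts and sums to one", {
  m <- rg(matrix(c(1, 1, 1, 0), 2, 2))
  cov <- rg(matrix(c(1500, 1500, 1550, 9999), 2, 2))
  fr <- distribution_frequency(m, cov, 50)
  expect_equal(fr$frequencies, c(2 / 3, 1 / 3))
  expect_equal(fr$bin_centers, c(1525, 1575))
  expect_equal(sum(fr$frequencies), 1)
  expect_equal(fr$n_oasis_cells, 3)
  expect_error(distribution_frequency(m, cov, 0), "bin_width")
  expect_error(distribution_frequency(rg(matrix(0, 2, 2)), cov, 50),
               "no valid oasis cells")
})

test_that("frequencies agree with a per-cell tally loop on random input", {
  set.seed(41)
  m <- random_mask(50, 50, na_frac = 0.04)
  cov <- rg(matrix(rnorm(2500, 1500, 120), 50, 50))
  cov$values[sample(2500, 60)] <- NA
  fr <- distribution_frequency(m, cov, 50)
  # brute force: loop every cell
  counts <- setNames(numeric(length(fr$bin_centers)),
                     as.character(fr$bin_centers))
  n <- 0
  for (r in 1:50) for (cc in 1:50) {
    mv <- m$values[r, cc]; cv <- cov$values[r, cc]
    if (is.na(mv) || is.na(cv) || mv != 1) next
    n <- n + 1
    ctr <- fr$bin_centers[cv >= fr$bin_centers - 25 &
                            cv < fr$bin_centers + 25]
    counts[as.character(ctr)] <- counts[as.character(ctr)] + 1
  }
  expect_equal(fr$n_oasis_cells, n)
  expect_equal(unname(fr$frequencies), unname(counts / n))
  expect_equal(sum(fr$frequencies), 1, tolerance = 1e-12)
})

test_that("doubling the bin width sums adjacent-bin frequencies", {
  set.seed(42)
  m <- random_mask(30, 30, p = 0.5)
  cov <- rg(matrix(runif(900, 1000, 2000), 30, 30))
  rng <- c(1000, 2000)
  f1 <- distribution_frequency(m, cov, 50, range = rng)
  f2 <- distribution_frequency(m, cov, 100, range = rng)
  # align: pad f1 to the full range before pairing
  full <- seq(1025, 1975, by = 50)
  v1 <- setNames(numeric(length(full)), full)
  v1[as.character(f1$bin_centers)] <- f1$frequencies
  paired <- as.vector(tapply(v1, rep(seq_len(10), each = 2), sum))
  v2 <- setNames(numeric(10), seq(1050, 1950, by = 100))
  v2[as.character(f2$bin_centers)] <- f2$frequencies
  expect_equal(paired, unname(v2), tolerance = 1e-12)
})

test_that("frequency is unaffected by translation of both layers", {
  set.seed(43)
  v <- matrix(rbinom(100, 1, 0.5), 10, 10)
  cv <- matrix(runif(100, 0, 10), 10, 10)
  f1 <- distribution_frequency(rg(v), rg(cv), 1)
  m2 <- raster_grid(v, 90, origin = c(5000, 7000))
  c2 <- raster_grid(cv, 90, origin = c(5000, 7000))
  f2 <- distribution_frequency(m2, c2, 1)
  expect_equal(f1$frequencies, f2$frequencies)
  expect_equal(f1$bin_centers, f2$bin_centers)
})

test_that("categorical shares support the sloped-only denominator", {
  m <- rg(matrix(c(rep(1, 10), rep(0, 6)), 4, 4))
  cl <- rg(matrix(c(1, 1, 1, 1, 2, 2, 3, 8, 0, 0, rep(4, 6)), 4, 4))
  cf <- categorical_frequency(m, cl)
  expect_equal(sum(cf$frequencies), 1)
  expect_equal(cf$frequencies[cf$levels == 1], 0.4)
  # restrict to sloped cells: drop the two flat (0) oasis cells
  cfs <- categorical_frequency(m, cl, exclude = 0)
  expect_equal(cfs$n_oasis_cells, 8)
  expect_equal(cfs$frequencies[cfs$levels == 1], 0.5)
  expect_false(0 %in% cfs$levels)
  # all-flat oasis with sloped-only denominator is an error
  flat <- rg(matrix(0, 4, 4))
  expect_error(categorical_frequency(m, flat, exclude = 0),
               "empty denominator")
})

test_that("Gaussian fit recovers exact parameters from noiseless curves", {
  x <- seq(1000, 2000, by = 50)
  a <- 0.04; mu <- 1500; sigma <- 150
  y <- a * exp(-(x - mu)^2 / (2 * sigma^2))
  fr <- structure(list(covariate_name = "elevation", bin_centers = x,
                       frequencies = y, counts = round(y * 1e4),
                       n_oasis_cells = 10000L, bin_width = 50),
                  class = "frequency_distribution")
  ft <- fit_normal(fr, with_offset = TRUE)
  expect_equal(ft$a, a, tolerance = 1e-6)
  expect_equal(ft$mu, mu, tolerance = 1e-6)
  expect_equal(ft$sigma, sigma, tolerance = 1e-6)
  expect_equal(ft$y0, 0, tolerance = 1e-8)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
  expect_lt(ft$p_value, 0.001)
  ft2 <- fit_normal(fr, with_offset = FALSE)
  expect_equal(ft2$mu, mu, tolerance = 1e-6)
})

test_that("Gaussian fit locates the peak under multiplicative noise", {
  x <- seq(1000, 2000, by = 50)
  truth <- 0.04 * exp(-(x - 1500)^2 / (2 * 150^2))
  hits <- 0
  set.seed(44)
  for (s in 1:20) {
    y <- truth * (1 + rnorm(length(x), 0, 0.05))
    fr <- structure(list(covariate_name = "elevation", bin_centers = x,
                         frequencies = y, counts = y,
                         n_oasis_cells = 1000L, bin_width = 50),
                    class = "frequency_distribution")
    ft <- fit_normal(fr)
    if (abs(ft$mu - 1500) <= 0.5 * 50) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("uniform frequencies carry no Gaussian signal", {
  x <- seq(1000, 2000, by = 100)
  fr <- structure(list(covariate_name = "elevation", bin_centers = x,
                       frequencies = rep(1 / length(x), length(x)),
                       counts = rep(1, length(x)),
                       n_oasis_cells = 11L, bin_width = 100),
                  class = "frequency_distribution")
  res <- tryCatch(fit_normal(fr), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "converge")
  } else {
    expect_gt(res$p_value, 0.05)
  }
})

test_that("threshold support matches brute-force counting", {
  m <- rg(matrix(1, 2, 2))
  cov <- rg(matrix(500, 2, 2))
  expect_equal(threshold_support(m, cov, 400, "ge"), 1)
  cov2 <- rg(matrix(c(500, 500, 300, 300), 2, 2))
  expect_equal(threshold_support(m, cov2, 400, "ge"), 0.5)
  expect_equal(threshold_support(m, cov2, 400, "le"), 0.5)
  set.seed(45)
  mm <- random_mask(25, 25, na_frac = 0.05)
  cc <- rg(matrix(runif(625, 0, 800), 25, 25))
  got <- threshold_support(mm, cc, 400, "ge")
  num <- 0; den <- 0
  for (r in 1:25) for (k in 1:25) {
    mv <- mm$values[r, k]; cv <- cc$values[r, k]
    if (is.na(mv) || is.na(cv) || mv != 1) next
    den <- den + 1
    if (cv >= 400) num <- num + 1
  }
  expect_equal(got, num / den)
})

test_that("stable and maximum extents give identical fits when equal", {
  set.seed(46)
  m <- random_mask(40, 40, p = 0.5)
  ser <- oasis_series(list(m, m, m), c(2000, 2005, 2010))
  cov <- rg(matrix(rnorm(1600, 1500, 150), 40, 40))
  cmp <- compare_stable_maximum(ser, cov, 50)
  expect_equal(cmp$peak_stable, cmp$peak_maximum)
  expect_equal(cmp$sigma_stable, cmp$sigma_maximum)
  expect_false(cmp$maximum_flatter)
})
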