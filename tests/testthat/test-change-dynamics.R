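test_that("oasis_area counts cells times cell area", {
  m <- rg(matrix(c(1, 0, 1, 0, 1, 0), 2, 3))
  expect_equal(oasis_area(m), 3 * 90^2 / 1e6)  # 0.0243 km^2
  expect_equal(oasis_area(rg(matrix(0, 4, 4))), 0)
  expect_equal(oasis_area(rg(matrix(1, 100, 100))), 81)
  expect_error(oasis_area(rg(matrix(2, 2, 2))), "not binary")
})

test_that("change_metrics reproduces endpoint arithmetic", {
  cm <- change_metrics(10707.7, 14950.1, 30)
  expect_equal(cm$percent_change, 39.6, tolerance = 1e-3)
  expect_equal(cm$factor, 1.4, tolerance = 0.005)
  expect_equal(cm$annual_increase, (14950.1 - 10707.7) / 30)
  id <- change_metrics(100, 100, 10)
  expect_equal(id$percent_change, 0)
  expect_equal(id$factor, 1)
  expect_equal(id$annual_increase, 0)
  expect_equal(change_metrics(1.06, 5.07, 30)$percent_change, 378,
               tolerance = 1e-3)
  expect_error(change_metrics(0, 10, 5), "positive")
})

test_that("change_map labels transitions and conserves areas", {
  a <- rg(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  b <- rg(matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  cm <- change_map(a, b)
  expect_equal(cm$categories$values,
               matrix(c(3, 1, 0, 3), 2, 2, byrow = TRUE))
  same <- change_map(a, a)
  expect_true(all(same$categories$values %in% c(0, 3)))
  # conservation identities on random masks, with nodata
  set.seed(21)
  for (i in 1:10) {
    m1 <- random_mask(15, 15, na_frac = 0.05)
    m2 <- random_mask(15, 15, na_frac = 0.05)
    m2$values[is.na(m1$values)] <- NA  # align na for clean counting
    m1$values[is.na(m2$values)] <- NA
    v <- change_map(m1, m2)$categories$values
    n_stable <- sum(v == 3, na.rm = TRUE)
    expect_equal(n_stable + sum(v == 1, na.rm = TRUE),
                 sum(m2$values == 1, na.rm = TRUE))
    expect_equal(n_stable + sum(v == 2, na.rm = TRUE),
                 sum(m1$values == 1, na.rm = TRUE))
  }
  expect_error(change_map(a, rg(matrix(0, 3, 3))), "geometry mismatch")
})

test_that("stable and maximum extents equal per-cell min and max", {
  a <- rg(matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  b <- rg(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  s <- oasis_series(list(a, b), c(2000, 2005))
  expect_equal(stable_oasis(s)$values,
               matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(maximum_oasis(s)$values,
               matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  ident <- oasis_series(list(a, a, a), c(2000, 2005, 2010))
  expect_equal(stable_oasis(ident)$values, a$values)
  expect_equal(maximum_oasis(ident)$values, a$values)
  # brute-force per-cell check on a random 7-period series
  set.seed(22)
  ser <- random_series(20, 20, 7)
  st <- stable_oasis(ser)$values
  mx <- maximum_oasis(ser)$values
  for (r in 1:20) for (cc in 1:20) {
    cellvals <- vapply(ser$masks, function(m) m$values[r, cc], numeric(1))
    expect_identical(st[r, cc], min(cellvals))
    expect_identical(mx[r, cc], max(cellvals))
  }
})

test_that("intersection/union duality and area orderings hold", {
  set.seed(23)
  for (i in 1:5) {
    ser <- random_series(12, 12, 5)
    comp <- oasis_series(lapply(ser$masks, function(m) {
      rg(1 - m$values)
    }), ser$years)
    expect_equal(stable_oasis(ser)$values,
                 1 - maximum_oasis(comp)$values)
    areas <- vapply(ser$masks, oasis_area, numeric(1))
    expect_lte(oasis_area(stable_oasis(ser)), min(areas))
    expect_gte(oasis_area(maximum_oasis(ser)), max(areas))
  }
})

test_that("zonal areas partition the total and shares sum to 100", {
  m <- rg(matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE))
  z <- rg(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE))
  za <- zonal_areas(m, z)
  expect_equal(za$area_km2[za$zone == "1"], 1 * 8100 / 1e6)
  expect_equal(za$area_km2[za$zone == "2"], 2 * 8100 / 1e6)
  expect_equal(sum(za$share_pct[za$zone != "total"]), 100)
  expect_equal(za$area_km2[za$zone == "total"],
               sum(za$area_km2[za$zone != "total"]))
  # a zone with no oasis reports zero area and share
  z3 <- rg(matrix(c(1, 1, 2, 3), 2, 2, byrow = TRUE))
  m3 <- rg(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  za3 <- zonal_areas(m3, z3)
  expect_equal(za3$area_km2[za3$zone == "3"], 0)
  expect_equal(za3$share_pct[za3$zone == "3"], 0)
})
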