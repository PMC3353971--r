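test_that("CSR sampling is uniform over the region", {
  set.seed(21)
  sph <- pe_region()
  pat <- sample_csr(sph, 2e4)
  m <- as.matrix(pat)
  expect_true(all(region_contains(sph, m)))

  # symmetry: per-coordinate mean near 0 (var of a coordinate in the unit
  # ball is 1/5)
  se <- sqrt(1 / 5 / nrow(m))
  expect_true(all(abs(colMeans(m)) < 3 * se))

  # octant occupancy uniform (chi-square, 8 cells, 1%)
  oct <- paste(m[, 1] > 0, m[, 2] > 0, m[, 3] > 0)
  p <- chisq.test(table(oct))$p.value
  expect_gt(p, 0.01)
})

test_that("pattern sizes follow the truncated Poisson law", {
  set.seed(22)
  small <- replicate(2000, draw_pattern_size(6, min_n = 5))
  expect_true(all(small >= 5))

  draws <- replicate(1e4, draw_pattern_size(16, min_n = 5))
  lam <- spatnuc:::truncated_poisson_rate(16, 5)
  target <- trunc_pois_mean_oracle(lam, 5)
  expect_equal(target, 16, tolerance = 1e-6)   # rate calibration
  expect_lt(abs(mean(draws) - target), 3 * sd(draws) / sqrt(length(draws)))

  # truncation nearly never binds at mean 128
  expect_lt(abs(spatnuc:::truncated_poisson_rate(128, 5) - 128), 1e-6)
  expect_error(draw_pattern_size(4, min_n = 5))
})

test_that("distance features measure the advertised geometry", {
  sph <- pe_region()
  expect_lt(distance_feature(sph, c(0, 0, 0), "center"), 1e-3)
  expect_equal(distance_feature(sph, c(1, 0, 0), "polar"), 0)
  expect_equal(distance_feature(sph, c(0.25, 0, 0), "polar"), 0.75)
  expect_equal(distance_feature(sph, c(0, 0.5, 0), "boundary"), 0.5,
               tolerance = 1e-3)
  expect_error(distance_feature(sph, c(0, 0, 0), "spiral"))

  # polar feature uses only the x component
  expect_equal(distance_feature(sph, c(0.5, 0.3, 0.2), "polar"), 0.5)
})

test_that("retention probability is exp(-k d)", {
  expect_equal(retention_probability(c(0, 1, 5), k = 0), c(1, 1, 1))
  expect_equal(retention_probability(0, k = 3), 1)
  expect_equal(retention_probability(1, k = 1), exp(-1))
  expect_true(all(diff(retention_probability(seq(0, 2, 0.1), k = 1)) < 0))
  expect_error(retention_probability(-1, 1))
})

test_that("thinning shifts the targeted feature distance downward", {
  set.seed(23)
  sph <- pe_region()
  n_pool <- 4000

  # center: mean distance-to-centroid below the CSR value 3/4 for a unit ball
  pat <- sample_thinned(sph, "center", expected_n = 64, n = n_pool)
  d <- distance_feature(sph, pat, "center")
  se <- sd(d) / sqrt(n_pool)
  expect_lt(mean(d), 3 / 4 - 3 * se)

  # boundary: mean boundary distance below CSR's
  pat_b <- sample_thinned(sph, "boundary", expected_n = 64, n = n_pool)
  csr <- sample_csr(sph, n_pool)
  db <- distance_feature(sph, pat_b, "boundary")
  dc <- distance_feature(sph, csr, "boundary")
  expect_lt(mean(db), mean(dc) - 3 * sqrt(var(db) / n_pool + var(dc) / n_pool))
})

test_that("zero thinning strength recovers CSR", {
  set.seed(24)
  sph <- pe_region()
  pat <- sample_thinned(sph, "center", expected_n = 64, k = 0, n = 3000)
  csr <- sample_csr(sph, 3000)
  ks <- suppressWarnings(ks.test(distance_feature(sph, pat, "center"),
                                 distance_feature(sph, csr, "center")))
  expect_gt(ks$p.value, 0.01)
})

test_that("samplers attach their region and respect fixed sizes", {
  set.seed(25)
  reg <- pe_region(shape_class_params("flat_sphere", "thin"))
  pat <- sample_thinned(reg, "polar", expected_n = 32)
  expect_identical(pattern_region(pat)$ax, reg$ax)
  expect_gte(nrow(pat), 5)
  expect_true(all(region_contains(reg, pat)))
  expect_equal(nrow(sample_thinned(reg, "csr", expected_n = 32, n = 17)), 17)
})
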