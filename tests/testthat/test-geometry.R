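test_that("octant membership test follows the piecewise-ellipsoid inequality", {
  sph <- pe_region()
  expect_true(region_contains(sph, c(0, 0, 0)))
  expect_false(region_contains(sph, c(1.001, 0, 0)))
  expect_true(region_contains(sph, c(1, 0, 0)))   # boundary counts as inside

  # flat ellipsoid: (1.5/2)^2 + (0.4/0.5)^2 = 1.2025 > 1
  fe <- pe_region(a_plus = 2, c_minus = 0.5)
  expect_false(region_contains(fe, c(1.5, 0, -0.4)))
  expect_true(region_contains(fe, c(1.5, 0, -0.3)))

  # vectorised call agrees with scalar calls
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  expect_equal(region_contains(sph, pts),
               apply(pts, 1, function(p) region_contains(sph, p)))
})

test_that("analytic volume matches the closed forms and MC integration", {
  expect_equal(region_volume(pe_region()), 4 * pi / 3)
  expect_equal(region_volume(pe_region(a_plus = 2)), 2 * pi)
  expect_equal(region_volume(pe_region(shape_class_params("sphere", "thin"))),
               (pi / 6) * 2 * 2 * 0.4)

  set.seed(42)
  for (cl in c("sphere", "ellipsoid", "flat_sphere", "flat_ellipsoid")) {
    reg <- pe_region(shape_class_params(cl))
    mc <- mc_volume_oracle(reg, n = 2e5)
    expect_lt(abs(region_volume(reg) - mc$volume), 3 * mc$se)
  }
})

test_that("boundary distance matches symmetry and the dense-sampling oracle", {
  sph <- pe_region()
  expect_equal(boundary_distance(sph, c(0, 0, 0)), 1, tolerance = 1e-6)
  expect_equal(boundary_distance(sph, c(0.5, 0, 0)), 0.5, tolerance = 1e-6)
  expect_error(boundary_distance(sph, c(2, 0, 0)), "inside")

  set.seed(7)
  fs <- pe_region(shape_class_params("flat_sphere"))
  p <- c(0, 0, -0.25)
  bpts <- as.matrix(sample_boundary_points(fs, 1e5))
  oracle <- sqrt(min(colSums((t(bpts) - p)^2)))
  expect_lt(abs(boundary_distance(fs, p) - oracle), 1e-3)
})

test_that("max chord attains the known diameters and scales linearly", {
  expect_equal(max_chord(pe_region()), 2, tolerance = 1e-8)
  expect_equal(max_chord(pe_region(a_plus = 2)), 3, tolerance = 1e-8)
  s <- 2.5
  set.seed(3)
  ax <- perturb_params(shape_class_params("flat_ellipsoid"), 0.2)
  expect_equal(max_chord(pe_region(ax * s)), s * max_chord(pe_region(ax)),
               tolerance = 1e-6)
})

test_that("parameter perturbation has the right moments and stays positive", {
  base <- shape_class_params("sphere")
  expect_identical(perturb_params(base, 0), base)

  set.seed(11)
  draws <- replicate(1e4, perturb_params(base, 0.2)[["a_plus"]])
  expect_true(all(draws > 0))
  expect_lt(abs(mean(draws) - 1), 0.01)
  expect_lt(abs(sd(draws) - 0.2), 0.02)
})

test_that("shape classes encode the four canonical boundaries", {
  expect_equal(unname(shape_class_params("sphere")), rep(1, 6))
  expect_equal(unname(shape_class_params("flat_ellipsoid")),
               c(2, 1, 1, 1, 1, 0.5))
  expect_equal(shape_class_params("sphere", "thin")[c("c_plus", "c_minus")],
               c(c_plus = 0.2, c_minus = 0.2))
  expect_error(shape_class_params("cube"))

  # thin variants are 5x flatter relative to their own footprint
  thick <- pe_region(shape_class_params("flat_sphere", "thick"))
  thin <- pe_region(shape_class_params("flat_sphere", "thin"))
  height <- function(r) r$ax[["c_plus"]] + r$ax[["c_minus"]]
  expect_equal(height(thin) / max_chord(thin),
               (height(thick) / max_chord(thick)) / 5, tolerance = 1e-6)
})

test_that("boundary samples lie on the surface", {
  set.seed(5)
  sph <- pe_region()
  b <- as.matrix(sample_boundary_points(sph, 500))
  expect_true(all(abs(sqrt(rowSums(b^2)) - 1) < 1e-9))
  expect_error(sample_boundary_points(sph, 0))

  fs <- pe_region(shape_class_params("flat_sphere"))
  b <- as.matrix(sample_boundary_points(fs, 500))
  a <- ifelse(b[, 1] >= 0, fs$ax[["a_plus"]], fs$ax[["a_minus"]])
  bb <- ifelse(b[, 2] >= 0, fs$ax[["b_plus"]], fs$ax[["b_minus"]])
  cc <- ifelse(b[, 3] >= 0, fs$ax[["c_plus"]], fs$ax[["c_minus"]])
  resid <- (b[, 1] / a)^2 + (b[, 2] / bb)^2 + (b[, 3] / cc)^2 - 1
  expect_true(all(abs(resid) < 1e-6))
  expect_lt(max(boundary_distance(fs, b * (1 - 1e-9), refine = FALSE)), 1e-2)
  for (i in 1:10) {
    expect_lt(boundary_distance(fs, b[i, ] * (1 - 1e-9)), 1e-6)
  }
})

test_that("region construction validates parameters", {
  expect_error(pe_region(a_plus = 0))
  expect_error(pe_region(a_plus = -1))
  expect_error(pe_region(c(a_plus = 1, a_minus = 1)))
})
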