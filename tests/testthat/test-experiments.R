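test_that("collections hold the requested perturbed instances per class", {
  coll <- build_collection("thick", n_per_class = 3, seed = 51)
  expect_equal(nrow(coll), 12)
  expect_equal(as.integer(table(coll$class)), rep(3L, 4))
  expect_true(all(vapply(coll$region, inherits, TRUE, "pe_region")))

  # determinism: same seed rebuilds the same regions
  coll2 <- build_collection("thick", n_per_class = 3, seed = 51)
  expect_identical(lapply(coll$region, `[[`, "ax"),
                   lapply(coll2$region, `[[`, "ax"))

  # sigma = 0: all instances of a class identical
  flat <- build_collection("thin", n_per_class = 3, sigma = 0, seed = 52)
  sph <- flat$region[flat$class == "sphere"]
  expect_identical(sph[[1]]$ax, sph[[2]]$ax)
})

test_that("shape heterogeneity separates classes more than instances", {
  expect_equal(shape_heterogeneity_report(list(pe_region()))[, c("max_chord3", "volume")],
               tibble::tibble(max_chord3 = 8, volume = 4 * pi / 3),
               tolerance = 1e-6)

  # scaled copies of one shape fall on a line through the origin
  ax <- shape_class_params("flat_ellipsoid")
  scales <- c(1, 1.5, 2)
  rep_scaled <- shape_heterogeneity_report(lapply(scales, function(s) pe_region(ax * s)))
  ratio <- rep_scaled$max_chord3 / rep_scaled$volume
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)

  # perturbed instances form class-wise clouds: typical between-class centroid
  # separation exceeds the typical within-class spread (sphere and flattened
  # sphere overlap in this projection, so the comparison is on the mean)
  coll <- build_collection("thin", n_per_class = 10, seed = 53)
  rep <- shape_heterogeneity_report(coll)
  feats <- scale(cbind(rep$max_chord3, rep$volume))
  sp <- split(as.data.frame(feats), rep$class)
  within <- mean(vapply(sp, function(d) {
    mean(sqrt(rowSums(sweep(as.matrix(d), 2, colMeans(as.matrix(d)))^2)))
  }, numeric(1)))
  cm <- t(vapply(sp, function(d) colMeans(as.matrix(d)), numeric(2)))
  expect_gt(mean(dist(cm)), within)
})

test_that("SDI studies are reproducible and carry per-nucleus results", {
  coll <- build_collection("thin", n_per_class = 2, seed = 54)
  s1 <- run_sdi_study(coll, "center", 16, n_reps = 50, n_ref = 400, seed = 9)
  s2 <- run_sdi_study(coll, "center", 16, n_reps = 50, n_ref = 400, seed = 9)
  expect_identical(s1$values, s2$values)
  expect_equal(nrow(s1$values), 8)
  expect_true(all(s1$values$sdi >= 0 & s1$values$sdi <= 1))
  expect_true(all(s1$values$n_points >= 5))
  expect_s3_class(glance(s1), "tbl_df")
  expect_identical(tidy(s1), s1$values)
})

test_that("power runners report rejection fractions with binomial intervals", {
  coll <- build_collection("thick", n_per_class = 2, seed = 55)
  row <- run_individual_power(coll, "center", 16, n_null = 50, n_ref = 400, seed = 10)
  expect_equal(row$n, 8)
  expect_true(row$power >= 0 && row$power <= 1)
  expect_true(row$ci_lo <= row$power && row$power <= row$ci_hi)

  mod <- run_modified_power(coll, "center", 16, pooling = "all",
                            n_null = 50, n_ref = 400, seed = 10)
  expect_identical(mod$variant, "pooled_all")

  study <- run_power_study(coll, kinds = "center", expected_ns = c(16, 32),
                           n_null = 50, n_ref = 400, seed = 10)
  expect_equal(nrow(study), 8)  # 2 sizes x 4 variants
  expect_setequal(unique(study$variant),
                  c("individual", "pooled_per_class", "pooled_all", "aggregate"))
})

test_that("plot builders return ggplot objects", {
  coll <- build_collection("thin", n_per_class = 2, seed = 56)
  expect_s3_class(plot_shape_heterogeneity(coll), "ggplot")
  st <- run_sdi_study(coll, "csr", 16, n_reps = 30, n_ref = 200, seed = 3)
  expect_s3_class(autoplot(st), "ggplot")
  sph <- pe_region()
  obs <- estimate_F(sample_csr(sph, 10), sph, n_ref = 300)
  expect_s3_class(autoplot(obs), "ggplot")
  env <- pointwise_envelope(null_F_curves(sph, 10, 30, n_ref = 300))
  et <- envelope_test(obs, env)
  expect_s3_class(autoplot(et), "ggplot")
  expect_s3_class(tidy(et), "tbl_df")
  expect_s3_class(glance(et), "tbl_df")
})
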