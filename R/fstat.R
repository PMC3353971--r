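#' Distance grid for F-function evaluation
#'
#' @param region A region object (ignored when `normalized = TRUE`).
#' @param n_points Number of grid points (default 100).
#' @param normalized If `TRUE`, return the common unit grid from 0 to 1 used
#'   for distance-normalized curves.
#' @return Numeric vector of evenly spaced distances starting at exactly 0.
#' @export
make_r_grid <- function(region = NULL, n_points = 100, normalized = FALSE) {
  if (n_points < 2) abort("`n_points` must be at least 2.")
  upper <- if (normalized) 1 else max_chord(region)
  seq(0, upper, length.out = n_points)
}

new_f_curve <- function(r, value, n_ref = NA_integer_, normalized = FALSE) {
  out <- tibble(r = r, F = value)
  class(out) <- c("f_curve", class(out))
  attr(out, "n_ref") <- n_ref
  attr(out, "normalized") <- normalized
  assert_f_curve(out)
  out
}

# Hard assertions every curve must satisfy: range, monotonicity, F(0) = 0.
assert_f_curve <- function(curve) {
  v <- curve$F
  if (any(v < -1e-12 | v > 1 + 1e-12)) abort("F-curve values outside [0, 1].")
  if (any(diff(v) < -1e-12)) abort("F-curve is not non-decreasing.")
  if (curve$r[1] == 0 && v[1] != 0) abort("F(0) must be 0.")
  invisible(curve)
}

#' Monte-Carlo estimate of the empty-space (F-) function
#'
#' The F-function of a point pattern is the distribution function of the
#' distance from a uniformly random location in the region to the nearest
#' pattern point. It is estimated by drawing `n_ref` CSR reference points in
#' the region and recording, for each grid distance r, the fraction whose
#' nearest-pattern distance is below r. No edge correction is applied: all
#' tests compare against CSR realisations in the same region, so edge effects
#' cancel.
#'
#' @param points The target pattern (tibble/matrix with x, y, z).
#' @param region Containing region; defaults to the pattern's attached region.
#' @param r_grid Distance grid; defaults to [make_r_grid()] over the region.
#' @param n_ref Number of reference points (default 10000).
#' @return An `f_curve` tibble with columns `r` and `F`.
#' @examples
#' reg <- pe_region()
#' Fhat <- estimate_F(sample_csr(reg, 30), reg, n_ref = 2000)
#' @export
estimate_F <- function(points, region = pattern_region(points), r_grid = NULL,
                       n_ref = 10000) {
  m <- as_coord_matrix(points)
  if (nrow(m) < 1) abort("`points` must contain at least one point.")
  if (is.null(region)) abort("`region` is required (pattern carries none).")
  if (is.null(r_grid)) r_grid <- make_r_grid(region)
  ref <- as_coord_matrix(region_sample(region, n_ref))
  d <- cpp_nn_dist(ref, m)
  new_f_curve(r_grid, as.numeric(cpp_ecdf_strict(d, r_grid)), n_ref = n_ref)
}

#' Null F-curves under CSR
#'
#' Generates `n_reps` independent CSR realisations of exactly `pattern_size`
#' points in the region and estimates each one's F-function on a common grid.
#' This is the raw material for envelopes, the SDI reference curve, and the
#' SDI rank transform. Piecewise-ellipsoid regions use a compiled batch path.
#'
#' @param region A region object.
#' @param pattern_size Points per null realisation.
#' @param n_reps Number of realisations (default 500).
#' @inheritParams estimate_F
#' @return An `f_curve_set`: list with `r` (grid) and `curves`
#'   (`n_reps` x `length(r)` matrix, one curve per row).
#' @export
null_F_curves <- function(region, pattern_size, n_reps = 500, r_grid = NULL,
                          n_ref = 10000) {
  if (n_reps < 2) abort("`n_reps` must be at least 2.")
  if (pattern_size < 1) abort("`pattern_size` must be at least 1.")
  if (is.null(r_grid)) r_grid <- make_r_grid(region)
  if (inherits(region, "pe_region")) {
    curves <- cpp_null_fcurves_pe(region$ax, as.integer(pattern_size),
                                  as.integer(n_reps), as.integer(n_ref), r_grid)
  } else {
    curves <- matrix(NA_real_, nrow = n_reps, ncol = length(r_grid))
    for (i in seq_len(n_reps)) {
      pat <- region_sample(region, pattern_size)
      curves[i, ] <- estimate_F(pat, region, r_grid, n_ref)$F
    }
  }
  structure(list(r = r_grid, curves = curves, n_ref = n_ref),
            class = "f_curve_set")
}

curve_matrix <- function(curves) {
  if (inherits(curves, "f_curve_set")) {
    list(r = curves$r, m = curves$curves)
  } else if (is.list(curves) && all(vapply(curves, inherits, TRUE, "f_curve"))) {
    r <- curves[[1]]$r
    for (cv in curves) {
      if (!isTRUE(all.equal(cv$r, r))) abort("Curves must share a common r grid.")
    }
    list(r = r, m = do.call(rbind, lapply(curves, `[[`, "F")))
  } else {
    abort("`curves` must be an f_curve_set or a list of f_curve objects.")
  }
}

#' Pointwise Monte-Carlo envelope
#'
#' Per-distance empirical quantiles of a set of null curves: at each r the
#' lower and upper bounds are the (1-level)/2 and 1-(1-level)/2 quantiles of
#' the null F-values, giving a two-tailed pointwise acceptance band.
#'
#' @param curves An `f_curve_set` (from [null_F_curves()]) or list of
#'   `f_curve` objects on a common grid.
#' @param level Pointwise coverage (default 0.95).
#' @return An `f_envelope` tibble with columns `r`, `lower`, `upper`.
#' @export
pointwise_envelope <- function(curves, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  cm <- curve_matrix(curves)
  alpha <- (1 - level) / 2
  lower <- apply(cm$m, 2, quantile, probs = alpha, names = FALSE)
  upper <- apply(cm$m, 2, quantile, probs = 1 - alpha, names = FALSE)
  out <- tibble(r = cm$r, lower = lower, upper = upper)
  class(out) <- c("f_envelope", class(out))
  attr(out, "level") <- level
  attr(out, "n_null") <- nrow(cm$m)
  out
}

#' Envelope test against CSR
#'
#' Rejects complete spatial randomness when the observed F-curve strictly
#' exits the envelope at any grid distance. Direction of the departure: an
#' observed curve above the upper bound means empty-space distances are
#' shorter than CSR predicts, i.e. the pattern is more evenly spread
#' (`"regular"`); a curve below the lower bound means large empty gaps, i.e.
#' a clustered pattern (`"clustered"`); exits on both sides give `"mixed"`.
#' Values exactly on a bound do not count as exits, and neither do grid
#' points where the band has collapsed to zero width (all null curves agree
#' exactly, as happens at r = 0 and in the saturated tail where every null
#' curve is 1): a zero-width empirical band carries no usable quantile
#' information, and any genuine departure also shows where the band is open.
#'
#' @param observed An `f_curve`.
#' @param envelope An `f_envelope` on the same grid.
#' @return An `envelope_test` object; see [glance.envelope_test()].
#' @export
envelope_test <- function(observed, envelope) {
  if (!isTRUE(all.equal(observed$r, envelope$r))) {
    abort("Observed curve and envelope are on different r grids.")
  }
  open <- envelope$upper > envelope$lower
  above <- open & observed$F > envelope$upper
  below <- open & observed$F < envelope$lower
  reject <- any(above | below)
  direction <- if (!reject) {
    "none"
  } else if (any(above) && any(below)) {
    "mixed"
  } else if (any(above)) "regular" else "clustered"
  first_exit <- if (reject) observed$r[which(above | below)[1]] else NA_real_
  structure(list(reject = reject, direction = direction,
                 first_exit_r = first_exit, observed = observed,
                 envelope = envelope),
            class = "envelope_test")
}

#' @export
print.envelope_test <- function(x, ...) {
  cat("F-function envelope test (level",
      format(attr(x$envelope, "level")), ",", attr(x$envelope, "n_null"),
      "null curves)\n")
  if (x$reject) {
    cat(sprintf("  CSR rejected: %s departure, first exit at r = %.4g\n",
                x$direction, x$first_exit_r))
  } else {
    cat("  No evidence against CSR (curve stays inside the envelope)\n")
  }
  invisible(x)
}

#' Normalize an F-curve to the unit distance scale
#'
#' Divides distances by the region's maximum chord and linearly interpolates
#' the curve onto a common grid on \[0, 1\], making curves from differently
#' sized nuclei commensurate for aggregation.
#'
#' @param observed An `f_curve`.
#' @param region The region the curve was estimated in.
#' @param n_out Points in the output grid (default 100).
#' @return An `f_curve` on the unit grid.
#' @export
normalize_curve <- function(observed, region, n_out = 100) {
  mc <- max_chord(region)
  if (!is.finite(mc) || mc <= 0) abort("Region max chord must be positive.")
  u <- observed$r / mc
  grid <- make_r_grid(n_points = n_out, normalized = TRUE)
  v <- approx(u, observed$F, xout = grid, rule = 2, ties = "ordered")$y
  v[1] <- 0
  v <- cummax(pmin(pmax(v, 0), 1))
  new_f_curve(grid, v, n_ref = attr(observed, "n_ref"), normalized = TRUE)
}

# Null curves evaluated directly on this region's normalized grid: estimating
# on r = u * max_chord makes the values comparable across regions at common u
# without interpolation.
normalized_null_curves <- function(region, pattern_size, n_reps, n_ref,
                                   grid_n = 100) {
  u <- make_r_grid(n_points = grid_n, normalized = TRUE)
  set <- null_F_curves(region, pattern_size, n_reps,
                       r_grid = u * max_chord(region), n_ref = n_ref)
  set$r <- u
  set
}

#' Pooled null envelope over several regions
#'
#' Builds the aggregated null band used by the modified individual test: all
#' regions' normalized null curves are pooled and pointwise quantiles taken
#' over the pool. Heterogeneous shapes widen this band relative to each
#' region's own envelope, which is precisely why pooling loses power.
#'
#' @param regions A list of regions (or a collection tibble with a `region`
#'   column).
#' @param pattern_sizes Pattern size per region (recycled if length 1).
#' @param n_reps_per_region Null realisations per region (default 500).
#' @param level Pointwise coverage (default 0.95).
#' @param n_ref Reference points per F estimate (default 10000).
#' @param grid_n Points in the unit grid (default 100).
#' @return An `f_envelope` on the unit grid.
#' @export
pooled_null_envelope <- function(regions, pattern_sizes,
                                 n_reps_per_region = 500, level = 0.95,
                                 n_ref = 10000, grid_n = 100) {
  regions <- as_region_list(regions)
  if (length(regions) < 1) abort("`regions` must contain at least one region.")
  pattern_sizes <- rep_len(pattern_sizes, length(regions))
  pooled <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    pooled[[i]] <- normalized_null_curves(regions[[i]], pattern_sizes[i],
                                          n_reps_per_region, n_ref, grid_n)$curves
  }
  u <- make_r_grid(n_points = grid_n, normalized = TRUE)
  pointwise_envelope(structure(list(r = u, curves = do.call(rbind, pooled)),
                               class = "f_curve_set"), level)
}

as_region_list <- function(regions) {
  if (inherits(regions, "nuc_region")) return(list(regions))
  if (is.data.frame(regions) && "region" %in% names(regions)) {
    return(regions$region)
  }
  if (is.list(regions)) return(regions)
  abort("`regions` must be a region, a list of regions, or a collection tibble.")
}

#' Aggregate-distance F-function test
#'
#' Population-level envelope test on distance-normalized curves: each
#' nucleus's observed F-curve is normalized by its maximum chord and the
#' normalized curves are averaged across nuclei. The population curve is
#' compared against the aggregated null envelope — per-instance CSR null
#' curves (each with that instance's pattern size) pooled across all
#' instances, with pointwise quantiles over the pool
#' (`null_aggregation = "pooled"`). Because the pooled band carries the full
#' between-nucleus and between-shape variation while the observed average is
#' far less variable, this test is very conservative on heterogeneous
#' collections; that weakness is a property of the method itself.
#' `null_aggregation = "round_mean"` instead builds each null curve by
#' averaging one fresh CSR realisation per instance, giving a band for the
#' mean curve proper.
#'
#' @param patterns List of point patterns (tibbles with x, y, z).
#' @param regions Matching list of regions; defaults to each pattern's
#'   attached region.
#' @param n_reps Null realisations per instance (default 500).
#' @param level Envelope coverage (default 0.95).
#' @param n_ref Reference points per F estimate (default 10000).
#' @param grid_n Points in the unit grid (default 100).
#' @param null_aggregation `"pooled"` (default) or `"round_mean"`; see above.
#' @return An `envelope_test` on the unit grid.
#' @export
aggregate_distance_test <- function(patterns, regions = NULL, n_reps = 500,
                                    level = 0.95, n_ref = 10000, grid_n = 100,
                                    null_aggregation = c("pooled", "round_mean")) {
  null_aggregation <- match.arg(null_aggregation)
  if (length(patterns) < 1) abort("`patterns` must contain at least one pattern.")
  if (is.null(regions)) regions <- lapply(patterns, pattern_region)
  regions <- as_region_list(regions)
  if (length(regions) != length(patterns)) {
    abort("`patterns` and `regions` must have the same length.")
  }
  if (length(patterns) == 1) {
    warn("Single instance: aggregate-distance test reduces to an individual test on the normalized scale.")
  }
  u <- make_r_grid(n_points = grid_n, normalized = TRUE)
  n_inst <- length(patterns)
  obs_sum <- numeric(grid_n)
  null_curves <- vector("list", n_inst)
  for (i in seq_len(n_inst)) {
    reg <- regions[[i]]
    grid_i <- u * max_chord(reg)
    obs_sum <- obs_sum + estimate_F(patterns[[i]], reg, grid_i, n_ref)$F
    size_i <- nrow(patterns[[i]])
    null_curves[[i]] <- null_F_curves(reg, size_i, n_reps, grid_i, n_ref)$curves
  }
  observed <- new_f_curve(u, obs_sum / n_inst, n_ref = n_ref, normalized = TRUE)
  pool <- if (null_aggregation == "pooled") {
    do.call(rbind, null_curves)
  } else {
    Reduce(`+`, null_curves) / n_inst
  }
  nulls <- structure(list(r = u, curves = pool), class = "f_curve_set")
  envelope_test(observed, pointwise_envelope(nulls, level))
}
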