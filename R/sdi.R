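#' Mean null F-curve under CSR
#'
#' Pointwise mean of [null_F_curves()]: the reference curve against which the
#' SDI measures each pattern's departure.
#'
#' @inheritParams null_F_curves
#' @return An `f_curve`.
#' @export
mean_null_F <- function(region, pattern_size, n_reps = 500, r_grid = NULL,
                        n_ref = 10000) {
  set <- null_F_curves(region, pattern_size, n_reps, r_grid, n_ref)
  new_f_curve(set$r, colMeans(set$curves), n_ref = n_ref)
}

#' Largest signed separation between two curves
#'
#' The signed difference observed - reference evaluated at the grid point
#' where its absolute value is largest. A pattern whose F-curve sits below
#' the CSR mean (clustered: large empty spaces) therefore gets a negative
#' separation, and lands in the low tail of the SDI.
#'
#' @param observed,reference `f_curve` objects on a common grid.
#' @return A single signed value in \[-1, 1\].
#' @export
signed_separation <- function(observed, reference) {
  if (!isTRUE(all.equal(observed$r, reference$r))) {
    abort("Curves are on different r grids.")
  }
  d <- observed$F - reference$F
  d[which.max(abs(d))]
}

#' Spatial Distribution Index of a single pattern
#'
#' Two-stage Monte-Carlo rank. Stage one: the mean null F-curve is built from
#' `n_reps` CSR realisations with the pattern's size, and the observed
#' dissimilarity is the largest signed separation between the observed
#' F-curve and that mean. Stage two: the dissimilarities of a further
#' `n_reps` CSR realisations from the same mean curve are recorded, and the
#' SDI is the fraction of them strictly smaller than the observed one. Under
#' CSR the SDI is uniform on \[0, 1\], so a population of nuclei can be
#' tested with [ks_uniform_test()].
#'
#' @param points The target pattern.
#' @param region Containing region; defaults to the pattern's attached region.
#' @param n_reps CSR realisations per stage (default 500).
#' @param r_grid Distance grid; defaults to [make_r_grid()] over the region.
#' @param n_ref Reference points per F estimate (default 10000).
#' @return An object of class `sdi`: list with `sdi`, `delta`, `n_points`,
#'   `n_reps`, `n_ref`.
#' @examples
#' reg <- pe_region()
#' compute_sdi(sample_csr(reg, 20), reg, n_reps = 50, n_ref = 500)
#' @export
compute_sdi <- function(points, region = pattern_region(points), n_reps = 500,
                        r_grid = NULL, n_ref = 10000) {
  m <- as_coord_matrix(points)
  if (is.null(region)) abort("`region` is required (pattern carries none).")
  if (is.null(r_grid)) r_grid <- make_r_grid(region)
  n_pts <- nrow(m)
  reference <- mean_null_F(region, n_pts, n_reps, r_grid, n_ref)
  obs <- estimate_F(m, region, r_grid, n_ref)
  delta_obs <- signed_separation(obs, reference)
  second <- null_F_curves(region, n_pts, n_reps, r_grid, n_ref)$curves
  diffs <- sweep(second, 2, reference$F)
  delta_null <- diffs[cbind(seq_len(n_reps), max.col(abs(diffs), ties.method = "first"))]
  structure(list(sdi = mean(delta_null < delta_obs), delta = delta_obs,
                 n_points = n_pts, n_reps = n_reps, n_ref = n_ref),
            class = "sdi")
}

#' @export
print.sdi <- function(x, ...) {
  cat(sprintf("SDI = %.3f (delta = %+.4f, %d points, %d reps, %d reference points)\n",
              x$sdi, x$delta, x$n_points, x$n_reps, x$n_ref))
  invisible(x)
}

#' Kolmogorov-Smirnov uniformity test of SDI values
#'
#' One-sample two-sided K-S test of a collection of SDI values against
#' Uniform(0, 1), using the asymptotic Kolmogorov p-value (`exact = FALSE`;
#' set `exact = TRUE` for small collections). Rejection indicates the
#' population of patterns is inconsistent with CSR.
#'
#' @param sdi_values Numeric vector of SDI values in \[0, 1\] (or a list of
#'   `sdi` objects), length at least 5.
#' @param exact Use the exact small-sample null distribution.
#' @return A one-row tibble with `statistic` (D), `p_value` and `n`.
#' @export
ks_uniform_test <- function(sdi_values, exact = FALSE) {
  if (is.list(sdi_values) && all(vapply(sdi_values, inherits, TRUE, "sdi"))) {
    sdi_values <- vapply(sdi_values, `[[`, numeric(1), "sdi")
  }
  sdi_values <- as.numeric(sdi_values)
  if (length(sdi_values) < 5) abort("At least 5 SDI values are required.")
  if (any(sdi_values < 0 | sdi_values > 1)) abort("SDI values must lie in [0, 1].")
  kt <- suppressWarnings(ks.test(sdi_values, "punif", exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n = length(sdi_values))
}
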