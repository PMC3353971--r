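#' Tidy an envelope test
#'
#' @param x An `envelope_test`.
#' @param ... Unused.
#' @return One row per grid distance: `r`, `observed`, `lower`, `upper`, and
#'   whether the observed curve exits the band at that distance.
#' @export
tidy.envelope_test <- function(x, ...) {
  tibble(r = x$observed$r, observed = x$observed$F,
         lower = x$envelope$lower, upper = x$envelope$upper,
         exits = x$observed$F > x$envelope$upper | x$observed$F < x$envelope$lower)
}

#' @rdname tidy.envelope_test
#' @return For `glance()`: a one-row tibble with `reject`, `direction`,
#'   `first_exit_r`, `level` and `n_null`.
#' @export
glance.envelope_test <- function(x, ...) {
  tibble(reject = x$reject, direction = x$direction,
         first_exit_r = x$first_exit_r,
         level = attr(x$envelope, "level"),
         n_null = attr(x$envelope, "n_null"))
}

#' Tidy an SDI study
#'
#' @param x An `sdi_study` from [run_sdi_study()].
#' @param ... Unused.
#' @return `tidy()`: the per-nucleus tibble (`id`, `class`, `n_points`,
#'   `delta`, `sdi`). `glance()`: one row with the K-S uniformity statistic,
#'   its p-value and the study configuration.
#' @export
tidy.sdi_study <- function(x, ...) x$values

#' @rdname tidy.sdi_study
#' @export
glance.sdi_study <- function(x, ...) {
  tibble(statistic = x$ks$statistic, p_value = x$ks$p_value, n = x$ks$n,
         kind = x$config$kind, expected_n = x$config$expected_n,
         n_reps = x$config$n_reps, n_ref = x$config$n_ref,
         seed = x$config$seed)
}
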