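#' Canonical synthetic nucleus shape classes
#'
#' The simulator uses four cell-like boundary shapes: a sphere, an ellipsoid
#' extruded along the positive x-axis, and the same two shapes with their
#' underside flattened along the negative z-axis. Each comes in a "thick"
#' variant and a "thin" variant whose height (both c semi-axes) is one fifth
#' of the thick one, mimicking flat adherent fibroblast nuclei.
#'
#' @param class_id One of `"sphere"`, `"ellipsoid"`, `"flat_sphere"`,
#'   `"flat_ellipsoid"`.
#' @param thickness `"thick"` (default) or `"thin"`.
#' @return A named numeric vector of the six semi-axis parameters, suitable
#'   for [pe_region()].
#' @examples
#' shape_class_params("flat_ellipsoid")          # a_plus=2, c_minus=0.5
#' pe_region(shape_class_params("sphere", "thin"))
#' @export
shape_class_params <- function(class_id = c("sphere", "ellipsoid",
                                            "flat_sphere", "flat_ellipsoid"),
                               thickness = c("thick", "thin")) {
  class_id <- match.arg(class_id)
  thickness <- match.arg(thickness)
  ax <- c(a_plus = 1, a_minus = 1, b_plus = 1, b_minus = 1,
          c_plus = 1, c_minus = 1)
  if (class_id %in% c("ellipsoid", "flat_ellipsoid")) ax[["a_plus"]] <- 2
  if (class_id %in% c("flat_sphere", "flat_ellipsoid")) ax[["c_minus"]] <- 0.5
  if (thickness == "thin") {
    ax[["c_plus"]] <- ax[["c_plus"]] / 5
    ax[["c_minus"]] <- ax[["c_minus"]] / 5
  }
  ax
}

#' Randomly perturb shape parameters
#'
#' Each of the six semi-axis parameters is independently multiplied by
#' \eqn{1 + \epsilon} with \eqn{\epsilon \sim N(0, \sigma^2)}, redrawing any
#' factor that falls at or below 0.2 so perturbed shapes cannot collapse.
#' The default scale 0.2 produces convincingly variable but non-pathological
#' nuclei.
#'
#' @param params Named parameter vector as from [shape_class_params()].
#' @param sigma Standard deviation of the multiplicative perturbation
#'   (`sigma = 0` returns `params` unchanged).
#' @return A perturbed parameter vector.
#' @export
perturb_params <- function(params, sigma = 0.2) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number.")
  }
  if (sigma == 0) return(params)
  out <- params
  for (i in seq_along(out)) {
    repeat {
      f <- 1 + rnorm(1, 0, sigma)
      if (f > 0.2) break
    }
    out[i] <- out[i] * f
  }
  out
}

#' @rdname perturb_params
#' @param region A [pe_region()] to perturb.
#' @export
perturb_region <- function(region, sigma = 0.2) {
  stopifnot(inherits(region, "pe_region"))
  pe_region(perturb_params(region$ax, sigma))
}
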