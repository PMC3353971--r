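#' Sample a completely spatially random (CSR) pattern
#'
#' Draws `n` independent uniform points inside the region — the homogeneous
#' Poisson process conditioned on its size, the null model of every test in
#' the package.
#'
#' @param region A region object.
#' @param n Number of points.
#' @return A tibble of coordinates (columns x, y, z) with the region attached
#'   as the `region` attribute.
#' @examples
#' pat <- sample_csr(pe_region(), 25)
#' @export
sample_csr <- function(region, n) {
  region_sample(region, n)
}

#' Draw a truncated-Poisson pattern size
#'
#' Pattern sizes follow a Poisson law conditioned on being at least `min_n`,
#' so simulated nuclei are never empty or nearly so. `expected_n` is the mean
#' of the truncated law itself: the underlying Poisson rate is adjusted by
#' root finding so that E(N | N >= min_n) equals `expected_n` (for
#' `expected_n` of 16 or more the adjustment is negligible).
#'
#' @param expected_n Target mean of the truncated distribution; must exceed
#'   `min_n`.
#' @param min_n Lower truncation point (default 5).
#' @return An integer pattern size, at least `min_n`.
#' @export
draw_pattern_size <- function(expected_n, min_n = 5) {
  lambda <- truncated_poisson_rate(expected_n, min_n)
  repeat {
    k <- rpois(1, lambda)
    if (k >= min_n) return(as.integer(k))
  }
}

# Mean of Poisson(lambda) conditioned on >= min_n:
# E[N 1{N >= m}] = lambda * P(N >= m - 1), so
# E[N | N >= m] = lambda * P(N >= m - 1) / P(N >= m).
truncated_poisson_mean <- function(lambda, min_n) {
  if (min_n <= 0) return(lambda)
  lambda * stats::ppois(min_n - 2, lambda, lower.tail = FALSE) /
    stats::ppois(min_n - 1, lambda, lower.tail = FALSE)
}

truncated_poisson_rate <- function(expected_n, min_n = 5) {
  if (length(expected_n) != 1 || !is.finite(expected_n) || expected_n <= min_n) {
    abort("`expected_n` must be a single number greater than `min_n`.")
  }
  if (min_n <= 0) return(expected_n)
  f <- function(l) truncated_poisson_mean(l, min_n) - expected_n
  if (f(1e-8) >= 0) return(1e-8)
  uniroot(f, c(1e-8, expected_n), tol = 1e-10)$root
}

#' Spatial preference distance features
#'
#' The distance each thinned process penalises: `"polar"` is the distance
#' (along the x-axis only) to the nearer of the two poles where the boundary
#' meets the x-axis; `"center"` is the Euclidean distance to the mean of the
#' boundary surface; `"boundary"` is the distance to the nearest boundary
#' point.
#'
#' @param region A region object.
#' @param points Interior points (data frame/matrix with x, y, z).
#' @param kind One of `"polar"`, `"center"`, `"boundary"`.
#' @return Numeric vector of distances.
#' @export
distance_feature <- function(region, points, kind = c("polar", "center", "boundary")) {
  kind <- match.arg(kind)
  m <- as_coord_matrix(points)
  if (!all(region_contains(region, m))) {
    abort("distance_feature() requires all points inside the region.")
  }
  out <- switch(kind,
    polar = {
      poles <- region_poles(region)
      pmin(abs(m[, 1] - poles[1, 1]), abs(m[, 1] - poles[2, 1]))
    },
    center = {
      cen <- boundary_centroid(region)
      sqrt((m[, 1] - cen[["x"]])^2 + (m[, 2] - cen[["y"]])^2 + (m[, 3] - cen[["z"]])^2)
    },
    boundary = boundary_distance(region, m, refine = FALSE)
  )
  unname(out)
}

#' Thinning retention probability
#'
#' A candidate CSR point at feature distance `d` is kept with probability
#' \eqn{\exp(-k d)}: 1 at the preferred location, decaying with distance, and
#' identically 1 when `k = 0` (recovering CSR). Larger `k` gives stronger
#' aggregation; `k = 1` on unit-scale nuclei yields patterns that are hard to
#' tell from CSR by eye.
#'
#' @param d Non-negative distance(s).
#' @param k Non-negative thinning strength.
#' @return Retention probabilities in (0, 1].
#' @export
retention_probability <- function(d, k = 1) {
  if (any(d < 0) || k < 0) abort("`d` and `k` must be non-negative.")
  exp(-k * d)
}

#' Sample a thinned (non-CSR) point pattern
#'
#' Draws the pattern size from the truncated Poisson law, then repeatedly
#' proposes CSR candidates and retains each with probability
#' `retention_probability(distance_feature(...), k)` until the drawn size is
#' reached. `kind = "csr"` skips thinning entirely.
#'
#' @param region A region object.
#' @param kind `"csr"`, `"polar"`, `"center"` or `"boundary"`.
#' @param expected_n Mean of the truncated-Poisson pattern size.
#' @param k Thinning strength (default 1).
#' @param min_n Truncation point of the size distribution (default 5).
#' @param n Optional fixed pattern size, bypassing the size draw.
#' @return A tibble of coordinates with the region attached; the realised
#'   size and process kind are attached as attributes `n` and `kind`.
#' @examples
#' reg <- pe_region(shape_class_params("flat_sphere", "thin"))
#' pat <- sample_thinned(reg, "center", expected_n = 32)
#' @export
sample_thinned <- function(region, kind = c("csr", "polar", "center", "boundary"),
                           expected_n = 64, k = 1, min_n = 5, n = NULL) {
  kind <- match.arg(kind)
  size <- if (is.null(n)) draw_pattern_size(expected_n, min_n) else as.integer(n)
  if (size < 1) abort("Pattern size must be at least 1.")
  if (kind == "csr" || k == 0) {
    out <- sample_csr(region, size)
  } else {
    acc <- matrix(numeric(0), ncol = 3)
    tried <- 0
    kept <- 0
    while (nrow(acc) < size) {
      batch <- max(64L, 2L * (size - nrow(acc)))
      cand <- as_coord_matrix(region_sample(region, batch))
      p <- retention_probability(distance_feature(region, cand, kind), k)
      keep <- runif(batch) < p
      tried <- tried + batch
      kept <- kept + sum(keep)
      if (any(keep)) acc <- rbind(acc, cand[keep, , drop = FALSE])
      if (tried >= 1e4 && kept / tried < 1e-4) {
        abort("Thinning acceptance rate below 1e-4; `k` too large for this region scale.")
      }
    }
    out <- coord_tibble(acc[seq_len(size), , drop = FALSE])
  }
  attr(out, "region") <- region
  attr(out, "n") <- size
  attr(out, "kind") <- kind
  out
}

#' Region attached to a point pattern
#'
#' @param points A pattern produced by the package samplers.
#' @return The region stored in the pattern's `region` attribute, or `NULL`.
#' @export
pattern_region <- function(points) attr(points, "region", exact = TRUE)
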