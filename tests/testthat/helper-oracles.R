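# Independent brute-force oracles used to validate the analytic /
# Monte-Carlo implementations. These deliberately share no code with the
# package internals they check.

# Rejection Monte-Carlo volume: fraction of bounding-box draws inside.
mc_volume_oracle <- function(region, n = 2e5) {
  bb <- region_bbox(region)
  pts <- cbind(runif(n, bb[1, 1], bb[2, 1]),
               runif(n, bb[1, 2], bb[2, 2]),
               runif(n, bb[1, 3], bb[2, 3]))
  vbox <- prod(bb[2, ] - bb[1, ])
  p <- mean(region_contains(region, pts))
  list(volume = p * vbox, se = vbox * sqrt(p * (1 - p) / n))
}

# Deterministic grid-integration F oracle: voxelize the bounding box at
# resolution h and take the fraction of inside voxel centres whose nearest
# pattern distance is below r.
grid_F_oracle <- function(pattern, region, r_values, h = 0.05) {
  bb <- region_bbox(region)
  gx <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  gy <- seq(bb[1, 2] + h / 2, bb[2, 2], by = h)
  gz <- seq(bb[1, 3] + h / 2, bb[2, 3], by = h)
  g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  g <- g[region_contains(region, g), , drop = FALSE]
  pm <- as.matrix(pattern[, c("x", "y", "z")])
  nn <- apply(g, 1, function(p) sqrt(min(colSums((t(pm) - p)^2))))
  vapply(r_values, function(r) mean(nn < r), numeric(1))
}

# Brute-force one-sample K-S statistic against Uniform(0,1): scan both sides
# of every ECDF step.
ks_D_oracle <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  max(pmax(seq_len(n) / n - xs, xs - (seq_len(n) - 1) / n))
}

# Brute-force largest signed separation between two curves on a shared grid.
signed_sep_oracle <- function(v1, v2) {
  d <- v1 - v2
  best <- 0
  for (i in seq_along(d)) if (abs(d[i]) > abs(best)) best <- d[i]
  best
}

# Truncated-Poisson mean by direct enumeration of the conditioned pmf.
trunc_pois_mean_oracle <- function(lambda, min_n, kmax = 500) {
  k <- min_n:kmax
  p <- dpois(k, lambda)
  sum(k * p) / sum(p)
}

# Build an f_curve by hand for curve-level unit tests.
make_curve <- function(r, values) spatnuc:::new_f_curve(r, values)

# A small collection of perturbed instances of one shape class.
single_class_collection <- function(class_id, thickness, n, sigma = 0.2, seed = 1) {
  base <- shape_class_params(class_id, thickness)
  rows <- lapply(seq_len(n), function(i) {
    set.seed(seed * 7919L + i)
    tibble::tibble(id = i, class = class_id, thickness = thickness,
                   region = list(pe_region(perturb_params(base, sigma))))
  })
  dplyr::bind_rows(rows)
}
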