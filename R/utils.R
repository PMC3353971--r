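# Internal helpers shared across modules.

# Deterministic Fibonacci lattice of n near-uniform directions on the unit
# sphere; used wherever a dense, reproducible direction set is needed
# (boundary caches, centroid quadrature, max-chord seeding).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

# Derive a per-unit 32-bit seed from a master seed and an index, so study
# runners can give every nucleus its own reproducible stream.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483563) + 1L
}

as_coord_matrix <- function(points, arg = "points") {
  if (is.matrix(points)) {
    if (ncol(points) != 3) abort(sprintf("`%s` must have 3 columns (x, y, z).", arg))
    m <- points
    colnames(m) <- c("x", "y", "z")
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points))) {
      abort(sprintf("`%s` must have columns x, y and z.", arg))
    }
    m <- cbind(x = as.numeric(points$x), y = as.numeric(points$y),
               z = as.numeric(points$z))
  } else if (is.numeric(points) && length(points) == 3) {
    m <- matrix(points, nrow = 1, dimnames = list(NULL, c("x", "y", "z")))
  } else {
    abort(sprintf("`%s` must be a data frame, 3-column matrix or length-3 vector.", arg))
  }
  if (!all(is.finite(m))) abort(sprintf("`%s` contains non-finite coordinates.", arg))
  m
}

coord_tibble <- function(m) {
  tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}
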