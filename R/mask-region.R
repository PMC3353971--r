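#' Voxel-mask region for user-supplied segmented nuclei
#'
#' Wraps a binary 3D mask (for example a segmented nucleus from a confocal
#' z-stack) as a region usable by every sampler and test in the package.
#' Voxel centres carry the geometry: a point is inside when it falls into an
#' occupied voxel, the volume is the occupied-voxel count times the voxel
#' volume, and boundary geometry is derived from occupied voxels that touch
#' an unoccupied 6-neighbour (or the array edge).
#'
#' @param mask 3D array; non-zero entries mark the nucleus interior.
#' @param spacing Physical voxel size along x, y, z (for example micrometres
#'   per voxel); length 3, all positive.
#' @param origin Physical coordinate of the corner of voxel (1,1,1); default
#'   the origin.
#' @return An object of class `mask_region` (also `nuc_region`).
#' @export
mask_region <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3) abort("`mask` must be a 3D array.")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes (x, y, z).")
  }
  m <- array(as.logical(mask != 0), dim = dim(mask))
  if (!any(m)) abort("`mask` is empty: no occupied voxels.")
  ncomp <- mask_n_components(m)
  if (ncomp > 1) {
    warn(sprintf("Mask has %d connected components; treating their union as one region.", ncomp))
  }
  dm <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  centers <- sweep(sweep(idx - 0.5, 2, spacing, `*`), 2, origin, `+`)
  colnames(centers) <- c("x", "y", "z")

  region <- structure(
    list(mask = m, spacing = as.numeric(spacing), origin = as.numeric(origin),
         dim = dm, inside_idx = idx),
    class = c("mask_region", "nuc_region"))
  region$volume <- nrow(idx) * prod(spacing)
  region$centroid <- stats::setNames(colMeans(centers), c("x", "y", "z"))
  region$bbox <- rbind(lower = apply(centers, 2, min) - spacing / 2,
                       upper = apply(centers, 2, max) + spacing / 2)
  bidx <- mask_boundary_voxels(m)
  bpts <- sweep(sweep(bidx - 0.5, 2, spacing, `*`), 2, origin, `+`)
  colnames(bpts) <- c("x", "y", "z")
  region$boundary_points <- bpts
  region$boundary_centroid <- stats::setNames(colMeans(bpts), c("x", "y", "z"))
  sub <- bpts
  if (nrow(sub) > 2000) sub <- sub[round(seq(1, nrow(sub), length.out = 2000)), , drop = FALSE]
  region$max_chord <- cpp_max_pairwise(sub)$dist
  region
}

# Occupied voxels with at least one unoccupied (or out-of-array) 6-neighbour.
mask_boundary_voxels <- function(m) {
  dm <- dim(m)
  pad <- array(FALSE, dm + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

# Number of 6-connected components among occupied voxels (flood fill).
mask_n_components <- function(m) {
  dm <- dim(m)
  lab <- array(0L, dm)
  ncomp <- 0L
  strides <- c(1L, dm[1], dm[1] * dm[2])
  todo <- which(m)
  for (s in todo) {
    if (lab[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    lab[s] <- ncomp
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      a <- arrayInd(v, dm)
      for (d in 1:3) {
        for (step in c(-1L, 1L)) {
          a2 <- a
          a2[d] <- a2[d] + step
          if (a2[d] < 1 || a2[d] > dm[d]) next
          v2 <- v + step * strides[d]
          if (m[v2] && lab[v2] == 0L) {
            lab[v2] <- ncomp
            queue <- c(queue, v2)
          }
        }
      }
    }
  }
  ncomp
}

mask_voxel_index <- function(region, m) {
  idx <- sweep(sweep(m, 2, region$origin, `-`), 2, region$spacing, `/`)
  ceiling(idx)
}

#' @export
region_contains.mask_region <- function(region, points, ...) {
  m <- as_coord_matrix(points)
  idx <- mask_voxel_index(region, m)
  ok <- idx[, 1] >= 1 & idx[, 1] <= region$dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= region$dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= region$dim[3]
  out <- logical(nrow(m))
  if (any(ok)) {
    out[ok] <- region$mask[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  }
  out
}

#' @export
region_sample.mask_region <- function(region, n, ...) {
  if (length(n) != 1 || !is.finite(n) || n < 1) abort("`n` must be at least 1.")
  n <- as.integer(n)
  pick <- region$inside_idx[sample.int(nrow(region$inside_idx), n, replace = TRUE), , drop = FALSE]
  jitter <- matrix(runif(3 * n), ncol = 3)
  pts <- sweep(sweep(pick - 1 + jitter, 2, region$spacing, `*`), 2, region$origin, `+`)
  colnames(pts) <- c("x", "y", "z")
  out <- coord_tibble(pts)
  attr(out, "region") <- region
  out
}

#' @export
boundary_distance.mask_region <- function(region, points, refine = TRUE, ...) {
  m <- as_coord_matrix(points)
  if (!all(region_contains(region, m))) {
    abort("boundary_distance() requires all points inside the region.")
  }
  as.numeric(cpp_nn_dist(m, region$boundary_points))
}

#' @export
sample_boundary_points.mask_region <- function(region, n, ...) {
  if (length(n) != 1 || !is.finite(n) || n < 1) abort("`n` must be at least 1.")
  n <- as.integer(n)
  pick <- region$boundary_points[sample.int(nrow(region$boundary_points), n,
                                            replace = TRUE), , drop = FALSE]
  coord_tibble(pick)
}

#' @export
region_poles.mask_region <- function(region, ...) {
  cen <- region$centroid
  idx <- region$inside_idx
  centers <- sweep(sweep(idx - 0.5, 2, region$spacing, `*`), 2, region$origin, `+`)
  off <- (centers[, 2] - cen[["y"]])^2 + (centers[, 3] - cen[["z"]])^2
  near <- off <= min(off) + sum(region$spacing[2:3]^2) / 4
  sel <- centers[near, , drop = FALSE]
  rbind(p1 = sel[which.max(sel[, 1]), ], p2 = sel[which.min(sel[, 1]), ])
}
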