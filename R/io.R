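#' Read and write point patterns
#'
#' Patterns are stored either as CSV (header `x,y,z`, one row per point,
#' '.' decimal, UTF-8) or JSON (`{"points": [[x,y,z], ...]}`). Coordinates
#' are written with 17 significant digits so a write/read round trip is exact.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `read_point_pattern()` a tibble with columns x, y, z;
#'   `write_point_pattern()` the path, invisibly.
#' @export
read_point_pattern <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "csv") {
    raw <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                    error = function(e) abort(sprintf("Malformed CSV %s: %s", path, conditionMessage(e))))
    if (!all(c("x", "y", "z") %in% names(raw))) {
      abort(sprintf("%s: header must contain columns x, y, z.", path))
    }
    if (nrow(raw) == 0) abort(sprintf("%s: no points.", path))
    bad <- which(!stats::complete.cases(raw[c("x", "y", "z")]) |
                   !is.finite(raw$x) | !is.finite(raw$y) | !is.finite(raw$z))
    if (length(bad)) {
      abort(sprintf("%s: non-finite or missing coordinate at data row %d.", path, bad[1]))
    }
    tibble(x = raw$x, y = raw$y, z = raw$z)
  } else {
    obj <- jsonlite::fromJSON(path)
    pts <- obj$points
    if (is.null(pts) || length(pts) == 0) abort(sprintf("%s: no \"points\" array.", path))
    m <- if (is.matrix(pts)) pts else do.call(rbind, pts)
    if (ncol(m) != 3 || !all(is.finite(m))) {
      abort(sprintf("%s: points must be finite [x, y, z] triples.", path))
    }
    tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  }
}

#' @rdname read_point_pattern
#' @param points Pattern to write (tibble/matrix with x, y, z).
#' @export
write_point_pattern <- function(points, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  m <- as_coord_matrix(points)
  if (format == "csv") {
    df <- data.frame(x = sprintf("%.17g", m[, 1]), y = sprintf("%.17g", m[, 2]),
                     z = sprintf("%.17g", m[, 3]))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(points = unname(m)), path, digits = I(17))
  }
  invisible(path)
}

#' Read and write piecewise-ellipsoid shape parameters
#'
#' JSON with the six keys `a_plus` ... `c_minus`; collections are arrays of
#' such objects, optionally with `class` and `id` labels.
#'
#' @param path File path.
#' @return `read_region_json()` a [pe_region()] (or list of them for an
#'   array); `write_region_json()` the path, invisibly.
#' @export
read_region_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  build <- function(p) pe_region(unlist(p[c("a_plus", "a_minus", "b_plus",
                                            "b_minus", "c_plus", "c_minus")]))
  if (is.data.frame(obj)) {
    lapply(seq_len(nrow(obj)), function(i) build(as.list(obj[i, ])))
  } else {
    build(obj)
  }
}

#' @rdname read_region_json
#' @param region A [pe_region()] or list of them.
#' @export
write_region_json <- function(region, path) {
  to_list <- function(r) as.list(r$ax)
  payload <- if (inherits(region, "pe_region")) to_list(region) else lapply(region, to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a segmented nucleus mask from a multi-page TIFF z-stack
#'
#' Each TIFF page is one z-slice; non-zero pixels mark the nucleus. The page
#' row/column axes map to y/x and the page index to z.
#'
#' @param path TIFF file path.
#' @param spacing Physical voxel size along x, y, z (all three required).
#' @return A [mask_region()].
#' @export
read_mask_region <- function(path, spacing) {
  if (missing(spacing) || length(spacing) != 3) {
    abort("`spacing` must give the voxel size along x, y and z.")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  p1 <- pages[[1]]
  if (length(dim(p1)) == 3) p1 <- p1[, , 1]
  mask <- array(FALSE, c(ncol(p1), nrow(p1), nz))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    mask[, , k] <- t(pg != 0)
  }
  mask_region(mask, spacing)
}

#' Write curves, envelopes and SDI results to CSV/JSON
#'
#' Curves as CSV columns `r,value`; envelopes as `r,lower,upper`; SDI studies
#' as a per-nucleus CSV plus a JSON summary with the K-S result and the run
#' configuration (reference points, realisation counts, level, seed).
#'
#' @param x Object to serialize.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_result <- function(x, path) UseMethod("write_result")

#' @export
write_result.f_curve <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(r = x$r, value = x$F,
                              n_ref = attr(x, "n_ref"),
                              normalized = isTRUE(attr(x, "normalized"))),
                         path, auto_unbox = TRUE, digits = I(17))
  } else {
    utils::write.csv(data.frame(r = x$r, value = x$F), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_result.f_envelope <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(r = x$r, lower = x$lower, upper = x$upper,
                              level = attr(x, "level"),
                              n_null = attr(x, "n_null")),
                         path, auto_unbox = TRUE, digits = I(17))
  } else {
    utils::write.csv(data.frame(r = x$r, lower = x$lower, upper = x$upper),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_result.sdi_study <- function(x, path) {
  utils::write.csv(as.data.frame(x$values), path, row.names = FALSE)
  summary_path <- sub("\\.csv$", ".json", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".json")
  jsonlite::write_json(list(ks = as.list(x$ks), config = x$config),
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
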