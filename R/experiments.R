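#' Build a collection of perturbed synthetic nuclei
#'
#' Generates `n_per_class` perturbed instances of each of the four shape
#' classes (sphere, ellipsoid, flat sphere, flat ellipsoid) at the requested
#' thickness — the synthetic populations over which the power and SDI studies
#' run (defaults give 200 nuclei). Every instance gets its own RNG stream
#' derived from `seed`, so the collection is reproducible instance by
#' instance.
#'
#' @param thickness `"thick"` or `"thin"`.
#' @param n_per_class Instances per shape class (default 50).
#' @param sigma Perturbation scale passed to [perturb_params()] (default 0.2).
#' @param seed Master seed for the collection; drawn from the current RNG
#'   when omitted.
#' @return A tibble with columns `id`, `class`, `thickness` and a `region`
#'   list-column of [pe_region()] objects.
#' @examples
#' coll <- build_collection("thin", n_per_class = 2, seed = 1)
#' @export
build_collection <- function(thickness = c("thick", "thin"), n_per_class = 50,
                             sigma = 0.2, seed = NULL) {
  thickness <- match.arg(thickness)
  if (n_per_class < 1) abort("`n_per_class` must be at least 1.")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  classes <- c("sphere", "ellipsoid", "flat_sphere", "flat_ellipsoid")
  rows <- vector("list", length(classes) * n_per_class)
  i <- 0L
  for (cl in classes) {
    base <- shape_class_params(cl, thickness)
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      set.seed(derive_seed(seed, i))
      rows[[i]] <- tibble(id = i, class = cl, thickness = thickness,
                          region = list(pe_region(perturb_params(base, sigma))))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "sigma") <- sigma
  out
}

#' Per-instance shape heterogeneity summary
#'
#' Reports the cube of the maximum chord against the enclosed volume for each
#' instance. If all boundaries were scaled copies of one shape these points
#' would fall on a line through the origin; the scatter within and between
#' shape classes quantifies how heterogeneous the collection is, and hence
#' how much information distance normalization discards.
#'
#' @param regions A collection tibble (from [build_collection()]) or list of
#'   regions.
#' @return A tibble with `id`, `class` (when available), `volume`,
#'   `max_chord` and `max_chord3`.
#' @export
shape_heterogeneity_report <- function(regions) {
  lst <- as_region_list(regions)
  if (length(lst) < 1) abort("At least one region is required.")
  out <- tibble(
    id = if (is.data.frame(regions) && "id" %in% names(regions)) regions$id else seq_along(lst),
    class = if (is.data.frame(regions) && "class" %in% names(regions)) regions$class else NA_character_,
    volume = vapply(lst, region_volume, numeric(1)),
    max_chord = vapply(lst, max_chord, numeric(1)))
  out$max_chord3 <- out$max_chord^3
  out
}

study_seed <- function(seed) {
  if (is.null(seed)) sample.int(2147483646L, 1) else as.integer(seed)
}

#' SDI study over a collection of nuclei
#'
#' Draws one pattern per nucleus from the requested process, computes each
#' nucleus's SDI, and tests the collection of SDI values for uniformity with
#' the two-sided one-sample K-S test — the population-level CSR test.
#'
#' @param collection A collection tibble from [build_collection()].
#' @param kind Process: `"csr"`, `"polar"`, `"center"` or `"boundary"`.
#' @param expected_n Mean pattern size (truncated Poisson, minimum `min_n`).
#' @param k Thinning strength (default 1).
#' @param min_n Size truncation (default 5).
#' @param n_reps CSR realisations per SDI stage (default 500).
#' @param n_ref Reference points per F estimate (default 10000).
#' @param seed Master seed; every nucleus gets a derived stream.
#' @return An `sdi_study` object: `values` (per-nucleus tibble with `id`,
#'   `class`, `n_points`, `delta`, `sdi`), `ks` (the [ks_uniform_test()]
#'   row), and `config`.
#' @export
run_sdi_study <- function(collection, kind, expected_n, k = 1, min_n = 5,
                          n_reps = 500, n_ref = 10000, seed = NULL) {
  seed <- study_seed(seed)
  n <- nrow(collection)
  sdi <- delta <- npts <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 1000L + i))
    reg <- collection$region[[i]]
    pat <- sample_thinned(reg, kind, expected_n = expected_n, k = k, min_n = min_n)
    res <- compute_sdi(pat, reg, n_reps = n_reps, n_ref = n_ref)
    sdi[i] <- res$sdi
    delta[i] <- res$delta
    npts[i] <- res$n_points
  }
  values <- tibble(id = collection$id, class = collection$class,
                   n_points = npts, delta = delta, sdi = sdi)
  structure(list(values = values, ks = ks_uniform_test(sdi),
                 config = list(kind = kind, expected_n = expected_n, k = k,
                               min_n = min_n, n_reps = n_reps, n_ref = n_ref,
                               seed = seed)),
            class = "sdi_study")
}

#' @export
print.sdi_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("SDI study: %s process, expected n = %g, %d nuclei\n",
              cfg$kind, cfg$expected_n, nrow(x$values)))
  cat(sprintf("  K-S uniformity: D = %.3f, p = %.3g\n",
              x$ks$statistic, x$ks$p_value))
  invisible(x)
}

binom_ci <- function(x, n, level = 0.95) {
  ci <- stats::binom.test(x, n, conf.level = level)$conf.int
  c(lo = ci[1], hi = ci[2])
}

# Shared engine: generates one pattern plus its null curves per nucleus once,
# then scores every requested test variant from the same material (the
# pooled-envelope variants pool exactly the per-nucleus null curves the
# individual test uses, as the modified test prescribes).
power_engine <- function(collection, kind, expected_n, alpha = 0.05, k = 1,
                         min_n = 5, n_null = 500, n_ref = 10000, seed = NULL,
                         variants = c("individual", "per_class", "all", "aggregate"),
                         grid_n = 100) {
  seed <- study_seed(seed)
  n <- nrow(collection)
  level <- 1 - alpha
  u <- make_r_grid(n_points = grid_n, normalized = TRUE)
  obs <- matrix(NA_real_, n, grid_n)
  nulls <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 2000L + i))
    reg <- collection$region[[i]]
    pat <- sample_thinned(reg, kind, expected_n = expected_n, k = k, min_n = min_n)
    grid_i <- u * max_chord(reg)
    obs[i, ] <- estimate_F(pat, reg, grid_i, n_ref)$F
    nulls[[i]] <- null_F_curves(reg, nrow(pat), n_null, grid_i, n_ref)$curves
  }
  test_against <- function(i, env) {
    envelope_test(new_f_curve(u, obs[i, ], normalized = TRUE), env)$reject
  }
  out <- list(seed = seed, n = n)
  if ("individual" %in% variants) {
    out$individual <- vapply(seq_len(n), function(i) {
      env <- pointwise_envelope(structure(list(r = u, curves = nulls[[i]]),
                                          class = "f_curve_set"), level)
      test_against(i, env)
    }, logical(1))
  }
  if ("per_class" %in% variants) {
    rej <- logical(n)
    for (cl in unique(collection$class)) {
      sel <- which(collection$class == cl)
      env <- pointwise_envelope(structure(list(r = u, curves = do.call(rbind, nulls[sel])),
                                          class = "f_curve_set"), level)
      for (i in sel) rej[i] <- test_against(i, env)
    }
    out$per_class <- rej
  }
  if ("all" %in% variants) {
    env <- pointwise_envelope(structure(list(r = u, curves = do.call(rbind, nulls)),
                                        class = "f_curve_set"), level)
    out$all <- vapply(seq_len(n), test_against, logical(1), env = env)
  }
  if ("aggregate" %in% variants) {
    # population mean curve against the pooled per-instance null envelope
    env <- pointwise_envelope(structure(list(r = u, curves = do.call(rbind, nulls)),
                                        class = "f_curve_set"), level)
    agg_obs <- new_f_curve(u, colMeans(obs), normalized = TRUE)
    out$aggregate <- envelope_test(agg_obs, env)
  }
  out
}

power_row <- function(process, expected_n, variant, reject, alpha) {
  n <- length(reject)
  x <- sum(reject)
  ci <- binom_ci(x, n)
  tibble(process = process, expected_n = expected_n, variant = variant,
         n = n, rejections = x, power = x / n,
         ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], alpha = alpha)
}

#' Power of the individual F-function envelope test
#'
#' One pattern per nucleus, each tested with its own CSR envelope; power is
#' the fraction of nuclei that reject, with an exact binomial 95% interval.
#'
#' @inheritParams run_sdi_study
#' @param alpha Test size: envelope level is `1 - alpha` (default 0.05).
#' @param n_null Null realisations per envelope (default 500).
#' @return A one-row tibble: `process`, `expected_n`, `variant`, `n`,
#'   `rejections`, `power`, `ci_lo`, `ci_hi`, `alpha`.
#' @export
run_individual_power <- function(collection, kind, expected_n, alpha = 0.05,
                                 k = 1, min_n = 5, n_null = 500, n_ref = 10000,
                                 seed = NULL) {
  eng <- power_engine(collection, kind, expected_n, alpha, k, min_n, n_null,
                      n_ref, seed, variants = "individual")
  power_row(kind, expected_n, "individual", eng$individual, alpha)
}

#' Power of the modified individual test with pooled null envelope
#'
#' Each nucleus's normalized observed curve is tested against an envelope
#' pooled from the null curves of several nuclei: all instances of the same
#' shape class (`pooling = "per_class"`) or the whole collection
#' (`pooling = "all"`).
#'
#' @inheritParams run_individual_power
#' @param pooling `"per_class"` or `"all"`.
#' @return A one-row tibble as in [run_individual_power()].
#' @export
run_modified_power <- function(collection, kind, expected_n,
                               pooling = c("per_class", "all"), alpha = 0.05,
                               k = 1, min_n = 5, n_null = 500, n_ref = 10000,
                               seed = NULL) {
  pooling <- match.arg(pooling)
  eng <- power_engine(collection, kind, expected_n, alpha, k, min_n, n_null,
                      n_ref, seed, variants = pooling)
  power_row(kind, expected_n, paste0("pooled_", pooling), eng[[pooling]], alpha)
}

#' Run all test variants over a grid of processes and pattern sizes
#'
#' Orchestrates the full synthetic study: for every (process, expected size)
#' cell it draws one pattern per nucleus, runs the individual test, both
#' pooled-envelope variants and the aggregate-distance test from shared null
#' material, and returns one row per (cell, variant).
#'
#' @inheritParams run_individual_power
#' @param kinds Character vector of processes.
#' @param expected_ns Integer vector of expected pattern sizes.
#' @param variants Subset of `c("individual", "per_class", "all", "aggregate")`.
#' @return A tibble of power rows; aggregate-test rows report the single
#'   collection-level decision in `rejections` (0 or 1) with `n = 1`.
#' @export
run_power_study <- function(collection, kinds = c("polar", "center", "boundary"),
                            expected_ns = c(16, 32, 64, 128),
                            variants = c("individual", "per_class", "all", "aggregate"),
                            alpha = 0.05, k = 1, min_n = 5, n_null = 500,
                            n_ref = 10000, seed = NULL) {
  seed <- study_seed(seed)
  rows <- list()
  cell <- 0L
  for (kind in kinds) {
    for (en in expected_ns) {
      cell <- cell + 1L
      eng <- power_engine(collection, kind, en, alpha, k, min_n, n_null,
                          n_ref, derive_seed(seed, cell), variants = variants)
      for (v in intersect(variants, c("individual", "per_class", "all"))) {
        lab <- if (v == "individual") "individual" else paste0("pooled_", v)
        rows[[length(rows) + 1L]] <- power_row(kind, en, lab, eng[[v]], alpha)
      }
      if ("aggregate" %in% variants) {
        rej <- eng$aggregate$reject
        rows[[length(rows) + 1L]] <-
          tibble(process = kind, expected_n = en, variant = "aggregate",
                 n = 1L, rejections = as.integer(rej), power = as.numeric(rej),
                 ci_lo = NA_real_, ci_hi = NA_real_, alpha = alpha)
      }
    }
  }
  dplyr::bind_rows(rows)
}
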