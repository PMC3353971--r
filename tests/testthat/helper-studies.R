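# Shared study material for the slow population-level tests. Collections and
# the power-study grid are computed once per test run and reused by the
# blocks that assert different properties of the same experiment. Sizes
# follow the package's scaled study mode (200 realisations, 2000 reference
# points) with the full 200-nucleus collections: power differences between
# processes are a few percentage points, so the binomial resolution of the
# full collection is needed for the ordering checks to be meaningful.
study_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = study_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = study_cache)
  }
  get(name, envir = study_cache, inherits = FALSE)
}

sdi_collection <- function(thickness) {
  cached(paste0("sdi_coll_", thickness),
         build_collection(thickness, n_per_class = 50, seed = 424242))
}

power_collection <- function(thickness) {
  cached(paste0("pow_coll_", thickness),
         build_collection(thickness, n_per_class = 50, seed = 515151))
}

sdi_D <- function(thickness, kind, expected_n) {
  cached(sprintf("sdi_%s_%s_%d", thickness, kind, expected_n), {
    st <- run_sdi_study(sdi_collection(thickness), kind, expected_n,
                        n_reps = 200, n_ref = 2000,
                        seed = 5000 + expected_n + nchar(kind))
    st$ks$statistic
  })
}

power_grid <- function(thickness) {
  cached(paste0("power_grid_", thickness),
         run_power_study(power_collection(thickness),
                         kinds = c("polar", "center", "boundary"),
                         expected_ns = c(16, 32, 64, 128),
                         n_null = 200, n_ref = 2000,
                         seed = if (thickness == "thick") 616161 else 717171))
}

power_of <- function(grid, kind, en, variant) {
  grid$power[grid$process == kind & grid$expected_n == en & grid$variant == variant]
}

# 95% binomial margin for comparing two rejection fractions out of n each.
binom_margin <- function(p1, p2, n) {
  1.96 * sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
}
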