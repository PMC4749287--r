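# Simulated change-score data at the study's design scale.

# One-trait cohort config; level architecture fixed, change architecture the
# quantity under test.
change_config <- function(n_per_zyg, var_change, seed, beta_time = 0,
                          var_level = c(0.5, 0, 0, 0.5), n_dz = NULL, ...) {
  sim_config(
    n_mz_pairs = n_per_zyg, n_dz_pairs = if (is.null(n_dz)) n_per_zyg else n_dz,
    traits = list(trait_spec("y", var_level = var_level,
                             var_change = var_change, beta_time = beta_time, ...)),
    seed = seed
  )
}

# Cohort -> cleaned delta table for trait "y".
gen_deltas <- function(n_per_zyg, var_change, seed, beta_time = 0, ...) {
  cfg <- change_config(n_per_zyg, var_change, seed, beta_time, ...)
  preprocess_trait(simulate_cohort(cfg), "y")$deltas
}

# Minimal cohort-shaped table from explicit values (one trait "y").
toy_cohort <- function(values, zygosity = "MZ") {
  n_ind <- length(values) / 2
  tibble::tibble(
    pair_id = rep(sprintf("P%03d", seq_len(ceiling(n_ind / 2))), each = 4)[seq_along(values)],
    twin_id = rep(sprintf("I%03d", seq_len(n_ind)), each = 2),
    zygosity = zygosity,
    sex = 0L,
    age_baseline = 40,
    time = rep(1:2, n_ind),
    y = values
  )
}

# Delta table straight from per-pair change values (bypasses the cohort).
toy_deltas <- function(pairs_mz = NULL, pairs_dz = NULL) {
  mk <- function(m, zyg, off) {
    if (is.null(m)) return(NULL)
    n <- nrow(m)
    tibble::tibble(
      pair_id = rep(sprintf("%s%04d", zyg, seq_len(n) + off), each = 2),
      twin_id = paste0(rep(sprintf("%s%04d", zyg, seq_len(n) + off), each = 2),
                       "_", rep(1:2, n)),
      zygosity = zyg, sex = rep(0L, 2 * n), age_baseline = 40,
      baseline_value = 0, delta = as.numeric(t(m))
    )
  }
  dplyr::bind_rows(mk(pairs_mz, "MZ", 0), mk(pairs_dz, "DZ", 10000))
}
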