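#' Simulate a longitudinal twin cohort with known variance architecture
#'
#' Generates a long-format cohort table (one row per individual per
#' occasion) under the classical twin model, separately for the baseline
#' level and the change between the two occasions. Latent additive-genetic
#' scores correlate 1 within MZ and 0.5 within DZ pairs, dominance scores
#' 1 and 0.25, shared-environment scores 1 in both zygosities, and
#' unique-environment scores are independent; each latent score is standard
#' normal and scaled by the square root of its variance proportion times the
#' total SD, so the within-pair covariance algebra of the ACE/ADE model
#' holds exactly by construction. The follow-up value is the baseline value
#' plus the trait's mean change (`beta_time`) plus the latent change draw;
#' age and sex affect the level and therefore carry over to both occasions.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `pair_id`, `twin_id`, `zygosity`
#'   (`"MZ"`/`"DZ"`), `sex` (0 male / 1 female), `age_baseline`, `time`
#'   (1/2) and one column per trait. `2 * (n_mz + n_dz) * 2` rows.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_mz_pairs = 5, n_dz_pairs = 5, seed = 7))
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_mz <- config$n_mz_pairs
  n_dz <- config$n_dz_pairs
  n_pairs <- n_mz + n_dz

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  w_a <- ifelse(zyg == "MZ", 1, 0.5)   # additive-genetic sharing
  w_d <- ifelse(zyg == "MZ", 1, 0.25)  # dominance sharing
  age <- runif(n_pairs, config$age_range[1], config$age_range[2])

  # MZ co-twins are always same-sex; DZ pairs may be opposite-sex.
  sex_pair <- rbinom(n_pairs, 1, config$prop_female)
  sex1 <- sex_pair
  sex2 <- ifelse(zyg == "MZ", sex_pair, rbinom(n_pairs, 1, config$prop_female))

  pid <- sprintf("P%04d", seq_len(n_pairs))
  base <- tibble::tibble(
    pair_id = rep(pid, each = 2L),
    twin_id = paste0(rep(pid, each = 2L), "_", rep(1:2, n_pairs)),
    zygosity = rep(zyg, each = 2L),
    sex = as.integer(rbind(sex1, sex2)),
    age_baseline = rep(age, each = 2L)
  )

  # One latent draw set per trait; twin 1 and twin 2 stacked as two columns.
  shared_component <- function(w) {
    sh <- rnorm(n_pairs)
    i1 <- rnorm(n_pairs); i2 <- rnorm(n_pairs)
    cbind(sqrt(w) * sh + sqrt(1 - w) * i1,
          sqrt(w) * sh + sqrt(1 - w) * i2)
  }
  latent_score <- function(props) {
    a <- shared_component(w_a)
    c_ <- { sh <- rnorm(n_pairs); cbind(sh, sh) }
    d <- shared_component(w_d)
    e <- cbind(rnorm(n_pairs), rnorm(n_pairs))
    sqrt(props[1]) * a + sqrt(props[2]) * c_ + sqrt(props[3]) * d + sqrt(props[4]) * e
  }

  for (tr in config$traits) {
    lev <- latent_score(tr$var_level)
    chg <- latent_score(tr$var_change)
    sexm <- cbind(sex1, sex2)
    y1 <- tr$mu_baseline + tr$beta_age * age + tr$beta_sex * sexm +
      tr$total_sd_level * lev
    y2 <- y1 + tr$beta_time + tr$total_sd_change * chg
    if (tr$lognormal) { y1 <- exp(y1); y2 <- exp(y2) }
    # interleave twins: per-individual values at time 1 and time 2
    base[[tr$name]] <- as.numeric(t(y1))
    base[[paste0(".t2_", tr$name)]] <- as.numeric(t(y2))
  }

  trait_names <- vapply(config$traits, `[[`, "", "name")
  t1 <- dplyr::select(base, !dplyr::starts_with(".t2_")) |>
    dplyr::mutate(time = 1L, .after = "age_baseline")
  t2 <- base
  for (nm in trait_names) t2[[nm]] <- t2[[paste0(".t2_", nm)]]
  t2 <- dplyr::select(t2, !dplyr::starts_with(".t2_")) |>
    dplyr::mutate(time = 2L, .after = "age_baseline")
  dplyr::bind_rows(t1, t2) |>
    dplyr::arrange(.data$pair_id, .data$twin_id, .data$time)
}

#' Displace a fraction of records to exercise the outlier mask
#'
#' Moves a seeded random subset of records of one trait away from the trait
#' mean by a fixed number of pooled standard deviations (random sign), and
#' returns the identifiers of the perturbed records so tests can check that
#' the 3-SD mask removes exactly those records.
#'
#' @param table A cohort tibble from [simulate_cohort()].
#' @param spec The trait's [trait_spec()]; `outlier_rate` and
#'   `outlier_magnitude` control the perturbation.
#' @param seed Integer seed for the record selection and signs.
#' @return A list with `table` (the perturbed cohort) and `ids`
#'   (a tibble of `twin_id`, `time` for each displaced record).
#' @export
inject_outliers <- function(table, spec, seed = 1L) {
  rate <- spec$outlier_rate
  if (rate < 0 || rate >= 1) abort("outlier_rate must be in [0, 1).")
  if (rate > 0 && spec$outlier_magnitude <= 3) {
    warn("outlier_magnitude <= 3: displaced records may survive a 3-SD mask.")
  }
  ids <- tibble::tibble(twin_id = character(), time = integer())
  if (rate == 0) return(list(table = table, ids = ids))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  x <- table[[spec$name]]
  obs <- which(!is.na(x))
  n_out <- round(rate * length(obs))
  if (n_out == 0) return(list(table = table, ids = ids))
  idx <- sample(obs, n_out)
  s <- sd(x, na.rm = TRUE)
  m <- mean(x, na.rm = TRUE)
  sign <- sample(c(-1, 1), n_out, replace = TRUE)
  table[[spec$name]][idx] <- m + sign * spec$outlier_magnitude * s
  list(
    table = table,
    ids = tibble::tibble(twin_id = table$twin_id[idx], time = table$time[idx])
  )
}

#' Write / read a cohort table as CSV
#'
#' Plain comma-separated UTF-8 with `.` decimal marks; missing values are
#' written as empty fields.
#'
#' @param table A cohort (or delta) tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}
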