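#' Natural-log transform one trait
#'
#' Applied before outlier masking to reduce skew in right-skewed metabolic
#' phenotypes. Missing values are preserved; non-positive values are a
#' domain error and are reported by record.
#'
#' @param table A cohort tibble.
#' @param trait Trait column name.
#' @return The cohort tibble with the trait log-transformed.
#' @export
log_transform <- function(table, trait) {
  x <- table[[trait]]
  if (is.null(x)) abort(sprintf("Unknown trait '%s'.", trait))
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Trait '%s' has non-positive values; cannot log-transform (e.g. twin_id %s, time %s).",
      trait, table$twin_id[bad[1]], table$time[bad[1]]
    ))
  }
  table[[trait]] <- log(x)
  table
}

#' Mask outlying trait values beyond k standard deviations
#'
#' The mean and sample SD are computed once over all non-missing values of
#' the trait, pooling both occasions, and values more than `k_sd` SDs from
#' that mean are set to missing. The rule is applied in a single pass; the
#' mean and SD are not re-estimated after masking.
#'
#' @param table A cohort tibble.
#' @param trait Trait column name.
#' @param k_sd Cut-off in SD multiples (default 3).
#' @return A list with `table` (masked cohort) and `masked_ids` (tibble of
#'   `twin_id`, `time` of masked records).
#' @export
mask_outliers <- function(table, trait, k_sd = 3) {
  x <- table[[trait]]
  if (is.null(x)) abort(sprintf("Unknown trait '%s'.", trait))
  obs <- !is.na(x)
  if (sum(obs) < 2) abort(sprintf("Trait '%s': need >= 2 non-missing values.", trait))
  m <- mean(x[obs])
  s <- sd(x[obs])
  if (s == 0) {
    warn(sprintf("Trait '%s' has zero SD; nothing masked.", trait))
    return(list(table = table,
                masked_ids = tibble::tibble(twin_id = character(), time = integer())))
  }
  mask <- obs & abs(x - m) > k_sd * s
  table[[trait]][mask] <- NA_real_
  list(
    table = table,
    masked_ids = tibble::tibble(twin_id = table$twin_id[mask], time = table$time[mask])
  )
}

#' Build per-individual change scores for one trait
#'
#' The change score is the follow-up value minus the baseline value for each
#' individual; the baseline value is carried along for covariate adjustment.
#' If either occasion is missing the change is missing.
#'
#' @param table A cleaned cohort tibble.
#' @param trait Trait column name.
#' @return A tibble with one row per individual: `pair_id`, `twin_id`,
#'   `zygosity`, `sex`, `age_baseline`, `baseline_value`, `delta`.
#' @export
compute_delta <- function(table, trait) {
  if (is.null(table[[trait]])) abort(sprintf("Unknown trait '%s'.", trait))
  wide <- table |>
    dplyr::select(dplyr::all_of(c("pair_id", "twin_id", "zygosity", "sex",
                                  "age_baseline", "time", trait))) |>
    tidyr::pivot_wider(names_from = "time", values_from = dplyr::all_of(trait),
                       names_prefix = "t")
  if (!all(c("t1", "t2") %in% names(wide))) {
    abort("Cohort table must contain both time points 1 and 2.")
  }
  wide |>
    dplyr::mutate(baseline_value = .data$t1, delta = .data$t2 - .data$t1) |>
    dplyr::select(!dplyr::all_of(c("t1", "t2")))
}

#' Clean one trait and build its change scores
#'
#' Runs the fixed preprocessing order: optional natural-log transform, then
#' the single-pass `k_sd`-SD outlier mask (on the transformed scale, both
#' occasions pooled), then the change score. Re-running the pipeline on its
#' own output is idempotent apart from the already-applied transform.
#'
#' @inheritParams mask_outliers
#' @param log_transform Logical; log-transform before masking?
#' @return A list with `deltas` (see [compute_delta()]), `cleaned` (the
#'   cleaned cohort table) and `masked_ids`.
#' @export
preprocess_trait <- function(table, trait, log_transform = FALSE, k_sd = 3) {
  if (log_transform) table <- twindelta::log_transform(table, trait)
  masked <- mask_outliers(table, trait, k_sd = k_sd)
  list(
    deltas = compute_delta(masked$table, trait),
    cleaned = masked$table,
    masked_ids = masked$masked_ids
  )
}

#' Keep only pairs in which both co-twins have an observed change score
#'
#' Pairwise likelihoods (intra-pair correlation, biometric twin models) need
#' complete pairs; individuals from incomplete pairs remain usable in the
#' mixed-model stage.
#'
#' @param deltas A delta tibble from [compute_delta()].
#' @return The delta tibble restricted to complete pairs.
#' @export
complete_delta_pairs <- function(deltas) {
  deltas |>
    dplyr::filter(!is.na(.data$delta), !is.na(.data$baseline_value)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::filter(dplyr::n() == 2L) |>
    dplyr::ungroup()
}
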