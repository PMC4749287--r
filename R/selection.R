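#' Choose the best-fitting twin model by likelihood-ratio parsimony
#'
#' Nested models whose LRT against the full model is non-significant
#' (`p > alpha`) are candidates; among candidates the one with the fewest
#' free parameters wins, ties broken by lower AIC. If no nested model is a
#' candidate the full model is kept. Parsimony by LRT overrides AIC against
#' the full model: a nested model may be selected even when its AIC exceeds
#' the full model's.
#'
#' @param fit_full The full-model fit (`"ACE"` or `"ADE"`).
#' @param nested_fits Named list of nested fits (`AE`, `CE`, `E` under ACE;
#'   `AE`, `E` under ADE). The DE model is never fitted: dominance without
#'   additive effects cannot explain a DZ correlation that low relative to
#'   the MZ correlation.
#' @param lrt_table Tibble of LRT results from [lrt()], one row per nested
#'   fit.
#' @param alpha Significance level for the LRTs.
#' @return The label of the selected model.
#' @export
select_best_model <- function(fit_full, nested_fits, lrt_table, alpha = 0.05) {
  cand <- lrt_table$nested[lrt_table$p.value > alpha]
  if (length(cand) == 0) return(fit_full$model)
  ks <- vapply(nested_fits[cand], function(f) as.numeric(f$k), 0)
  cand <- cand[ks == min(ks)]
  if (length(cand) > 1) {
    aics <- vapply(nested_fits[cand], `[[`, 0, "aic")
    cand <- cand[which.min(aics)]
  }
  cand
}

#' Full biometric decomposition of a change score with model selection
#'
#' Fits both full models (ACE and ADE) and all admissible nested models
#' (AE, CE, E) to the complete pairs of a delta table, chooses the full
#' model by AIC (the ICC heuristic `rMZ > 2 rDZ` is also reported), runs
#' the LRT cascade against the chosen full model, and applies parsimony
#' selection. Nested solutions seed the full-model optimizations, so a full
#' model's log-likelihood is never below that of its nested models.
#'
#' @inheritParams fit_twin_model
#' @param alpha Significance level for the LRT cascade.
#' @param boot_reps If positive, pair-level bootstrap replicates for the
#'   best model's component confidence intervals.
#' @param level Confidence level for the bootstrap intervals.
#' @return A `twindelta_selection` object: `fits` (all five models),
#'   `full_model` (AIC rule), `full_model_icc_rule`, `lrt` (tibble),
#'   `best_model`, `best_fit`, and `icc` (the MZ/DZ correlations used by
#'   the heuristic).
#' @export
fit_twin_cascade <- function(deltas, covariates = FALSE, alpha = 0.05,
                             n_starts = 5, seed = 1L,
                             boot_reps = 0, level = 0.95) {
  data <- twin_pair_data(deltas, covariates)
  fit_e <- fit_twin_model(data, "E", covariates)
  fit_ae <- fit_twin_model(data, "AE", covariates)
  fit_ce <- fit_twin_model(data, "CE", covariates)
  fit_ace <- fit_twin_model(data, "ACE", covariates, n_starts = n_starts,
                            seed = derive_seed(seed, 11),
                            extra_starts = list(fit_ae$components,
                                                fit_ce$components,
                                                fit_e$components))
  ade_start <- fit_ae$components  # AE is the shared boundary of ACE and ADE
  fit_ade <- fit_twin_model(data, "ADE", covariates, n_starts = n_starts,
                            seed = derive_seed(seed, 12),
                            extra_starts = list(ade_start, fit_e$components))
  fits <- list(ACE = fit_ace, ADE = fit_ade, AE = fit_ae, CE = fit_ce, E = fit_e)

  rmz <- with(data$MZ, stats::cor(y1, y2))
  rdz <- with(data$DZ, stats::cor(y1, y2))
  full_icc <- choose_full_model_icc(rmz, rdz)
  full <- choose_full_model_aic(fit_ace, fit_ade)
  nested_names <- if (full == "ACE") c("AE", "CE", "E") else c("AE", "E")
  lrt_table <- purrr::map_dfr(fits[nested_names], function(f) lrt(fits[[full]], f))
  best <- select_best_model(fits[[full]], fits[nested_names], lrt_table, alpha)
  best_fit <- fits[[best]]
  if (boot_reps > 0) {
    best_fit$ci <- bootstrap_components_ci(
      deltas, best, covariates = covariates, reps = boot_reps,
      level = level, seed = derive_seed(seed, 13)
    )
    fits[[best]] <- best_fit
  }
  structure(list(
    fits = fits, full_model = full, full_model_icc_rule = full_icc,
    icc = c(MZ = rmz, DZ = rdz),
    lrt = lrt_table, best_model = best, best_fit = best_fit,
    alpha = alpha, covariates = covariates
  ), class = "twindelta_selection")
}

#' Bootstrap confidence intervals for standardized variance components
#'
#' Resamples complete pairs with replacement, stratified by zygosity, refits
#' the given model on each resample and returns percentile intervals for
#' each standardized component. Non-convergent replicates are dropped and
#' counted; more than 5% drops triggers a warning.
#'
#' @inheritParams fit_twin_model
#' @param reps Number of bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed Integer seed; intervals are deterministic given it.
#' @return A tibble with `component`, `low`, `high` plus attributes
#'   `dropped` and `reps`.
#' @export
bootstrap_components_ci <- function(deltas, model, covariates = FALSE,
                                    reps = 1000, level = 0.95, seed = 1L,
                                    n_starts = 2) {
  if (reps < 100) abort("reps must be >= 100.")
  data <- twin_pair_data(deltas, covariates)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, reps, 4, dimnames = list(NULL, comp_names))
  dropped <- 0L
  for (b in seq_len(reps)) {
    res <- data
    for (z in c("MZ", "DZ")) {
      idx <- sample.int(data[[z]]$n, data[[z]]$n, replace = TRUE)
      res[[z]] <- list(n = data[[z]]$n,
                       y1 = data[[z]]$y1[idx], y2 = data[[z]]$y2[idx],
                       X1 = data[[z]]$X1[idx, , drop = FALSE],
                       X2 = data[[z]]$X2[idx, , drop = FALSE])
    }
    fit <- tryCatch(
      suppressWarnings(fit_twin_model(res, model, covariates,
                                      n_starts = n_starts, seed = b)),
      error = function(e) NULL
    )
    if (is.null(fit)) dropped <- dropped + 1L else draws[b, ] <- fit$components
  }
  if (dropped > 0.05 * reps) {
    warn(sprintf("%d of %d bootstrap replicates failed to converge.", dropped, reps))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- tibble::tibble(
    component = comp_names,
    low = apply(draws, 2, quantile, probs[1], na.rm = TRUE),
    high = apply(draws, 2, quantile, probs[2], na.rm = TRUE)
  )
  attr(out, "dropped") <- dropped
  attr(out, "reps") <- reps
  out
}

#' @export
print.twindelta_selection <- function(x, ...) {
  cat(sprintf("Full model: %s (AIC rule; ICC heuristic: %s)\n",
              x$full_model, x$full_model_icc_rule))
  cat(sprintf("Best model: %s\n", x$best_model))
  print(x$best_fit)
  invisible(x)
}

#' @method tidy twindelta_selection
#' @export
tidy.twindelta_selection <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(model = f$model, logLik = f$loglik, k = f$k, aic = f$aic,
                   a2 = f$components[["a2"]], c2 = f$components[["c2"]],
                   d2 = f$components[["d2"]], e2 = f$components[["e2"]])
  }) |>
    dplyr::left_join(
      dplyr::select(x$lrt, dplyr::all_of(c("nested", "statistic", "df", "p.value"))),
      by = c(model = "nested")
    ) |>
    dplyr::mutate(
      full_model = .data$model == x$full_model,
      best_model = .data$model == x$best_model
    )
}

#' @method glance twindelta_selection
#' @export
glance.twindelta_selection <- function(x, ...) {
  b <- x$best_fit
  tibble::tibble(
    full_model = x$full_model, full_model_icc_rule = x$full_model_icc_rule,
    best_model = x$best_model,
    a2 = b$components[["a2"]], c2 = b$components[["c2"]],
    d2 = b$components[["d2"]], e2 = b$components[["e2"]],
    aic_full = x$fits[[x$full_model]]$aic, aic_best = b$aic
  )
}
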