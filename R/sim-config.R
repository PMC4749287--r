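#' Specify the generative architecture of one simulated trait
#'
#' A trait specification fixes the fixed effects and the variance
#' architecture of a simulated phenotype, separately for its baseline
#' *level* and its longitudinal *change*. Variance architectures are given
#' as standardized proportions `(a2, c2, d2, e2)` of additive-genetic,
#' shared-environmental, dominance-genetic and unique-environmental
#' variance; each set must be non-negative, sum to 1, and may not contain
#' both a shared-environment and a dominance component (C and D are not
#' jointly identifiable in twins reared together, and the generator mirrors
#' that restriction).
#'
#' @param name Trait name; becomes a column of the simulated cohort.
#' @param mu_baseline Mean baseline value, in trait units (log-scale units
#'   when `lognormal = TRUE`).
#' @param var_level Numeric length-4 vector `(a2, c2, d2, e2)` of variance
#'   proportions for the baseline level.
#' @param var_change Same, for the change between the two occasions.
#' @param total_sd_level,total_sd_change Total standard deviations (trait
#'   units) of level and change.
#' @param beta_time Mean change between occasions (trait units).
#' @param beta_age Fixed age effect on the level, per year of baseline age.
#' @param beta_sex Fixed effect of sex (female vs male) on the level.
#' @param lognormal If `TRUE` the trait is generated on the log scale and
#'   exponentiated, producing a positive, right-skewed phenotype that
#'   exercises the log-transform step of the preprocessing pipeline.
#' @param outlier_rate Fraction of records displaced by [inject_outliers()].
#' @param outlier_magnitude Displacement size, in multiples of the pooled SD.
#'
#' @return A `trait_spec` list.
#' @export
#' @examples
#' trait_spec("glu", mu_baseline = 5, var_change = c(0.4, 0, 0, 0.6))
trait_spec <- function(name,
                       mu_baseline = 0,
                       var_level = c(0.5, 0, 0, 0.5),
                       var_change = c(0.3, 0, 0, 0.7),
                       total_sd_level = 1,
                       total_sd_change = 1,
                       beta_time = 0,
                       beta_age = 0,
                       beta_sex = 0,
                       lognormal = FALSE,
                       outlier_rate = 0,
                       outlier_magnitude = 6) {
  spec <- list(
    name = as.character(name), mu_baseline = mu_baseline,
    var_level = as.numeric(var_level), var_change = as.numeric(var_change),
    total_sd_level = total_sd_level, total_sd_change = total_sd_change,
    beta_time = beta_time, beta_age = beta_age, beta_sex = beta_sex,
    lognormal = isTRUE(lognormal),
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude
  )
  validate_trait_spec(spec)
  structure(spec, class = "trait_spec")
}

validate_var_props <- function(p, what, trait) {
  if (length(p) != 4L || anyNA(p) || any(p < 0)) {
    abort(sprintf("Trait '%s': %s must be 4 non-negative proportions (a2, c2, d2, e2).",
                  trait, what))
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("Trait '%s': %s proportions must sum to 1 (got %.6f).",
                  trait, what, sum(p)))
  }
  if (p[2] > 0 && p[3] > 0) {
    abort(sprintf("Trait '%s': %s may not have both c2 and d2 positive.",
                  trait, what))
  }
  if (p[4] <= 0) {
    abort(sprintf("Trait '%s': %s must have e2 > 0.", trait, what))
  }
  invisible(p)
}

validate_trait_spec <- function(spec) {
  validate_var_props(spec$var_level, "var_level", spec$name)
  validate_var_props(spec$var_change, "var_change", spec$name)
  if (spec$total_sd_level <= 0 || spec$total_sd_change <= 0) {
    abort(sprintf("Trait '%s': total SDs must be positive.", spec$name))
  }
  if (spec$outlier_rate < 0 || spec$outlier_rate >= 1) {
    abort(sprintf("Trait '%s': outlier_rate must be in [0, 1).", spec$name))
  }
  invisible(spec)
}

#' Configure a simulated longitudinal twin cohort
#'
#' The defaults reproduce the design of a Danish-style adult twin cohort:
#' 226 MZ and 276 DZ complete pairs, baseline ages uniform on 18--67 years,
#' roughly balanced sexes, and two measurement occasions 12 years apart.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of complete MZ and DZ pairs.
#' @param traits List of [trait_spec()] objects.
#' @param age_range Length-2 numeric, min and max baseline age in years.
#' @param prop_female Expected fraction of female individuals.
#' @param follow_up_years Years between the two occasions (metadata only;
#'   the change model is per-occasion, not per-year).
#' @param seed Integer seed; the generator is deterministic given it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mz_pairs = 226,
                       n_dz_pairs = 276,
                       traits = list(trait_spec("trait1")),
                       age_range = c(18, 67),
                       prop_female = 0.5,
                       follow_up_years = 12,
                       seed = 1L) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    traits = traits, age_range = as.numeric(age_range),
    prop_female = prop_female, follow_up_years = follow_up_years,
    seed = as.integer(seed)
  )
  if (cfg$n_mz_pairs < 0 || cfg$n_dz_pairs < 0) abort("Pair counts must be >= 0.")
  if (prop_female < 0 || prop_female > 1) abort("prop_female must be in [0, 1].")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2]) {
    abort("age_range must be (min, max) with min <= max.")
  }
  for (tr in cfg$traits) validate_trait_spec(tr)
  nm <- vapply(cfg$traits, `[[`, "", "name")
  if (anyDuplicated(nm)) abort("Trait names must be unique.")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds the [sim_config()] fields as top-level keys and a `traits`
#' block mapping trait names to [trait_spec()] fields.
#'
#' @param path Path to a YAML configuration file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  traits <- purrr::imap(raw$traits %||% list(), function(fields, nm) {
    do.call(trait_spec, c(list(name = nm), fields))
  })
  raw$traits <- unname(traits)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}
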