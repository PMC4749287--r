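twin_models <- list(
  ACE = c("a2", "c2"),
  ADE = c("a2", "d2"),
  AE  = "a2",
  CE  = "c2",
  E   = character()
)

comp_names <- c("a2", "c2", "d2", "e2")

#' Expected co-twin covariance of a biometric twin model
#'
#' Under the classical twin model the expected within-pair covariance of a
#' trait is `(a2 + c2 + d2) * total_var` for MZ pairs and
#' `(a2/2 + c2 + d2/4) * total_var` for DZ pairs, with variance `total_var`
#' on the diagonal.
#'
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param comps Named numeric with entries `a2`, `c2`, `d2`, `e2`
#'   (standardized proportions summing to 1); components outside the model
#'   must be zero.
#' @param total_var Total variance of the trait.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 2x2 covariance matrix.
#' @export
#' @examples
#' expected_twin_cov("ACE", c(a2 = 0.4, c2 = 0.2, d2 = 0, e2 = 0.4), 1, "MZ")
expected_twin_cov <- function(model, comps, total_var, zygosity) {
  model <- match.arg(model, names(twin_models))
  comps <- comps[comp_names]
  names(comps) <- comp_names
  comps[is.na(comps)] <- 0
  outside <- setdiff(setdiff(comp_names, "e2"), twin_models[[model]])
  if (any(comps[outside] != 0)) {
    abort(sprintf("Component(s) %s must be zero under the %s model.",
                  paste(outside[comps[outside] != 0], collapse = ", "), model))
  }
  r <- zygosity_cor(comps, zygosity)
  total_var * matrix(c(1, r, r, 1), 2, 2)
}

zygosity_cor <- function(comps, zygosity) {
  if (zygosity == "MZ") {
    comps[["a2"]] + comps[["c2"]] + comps[["d2"]]
  } else {
    comps[["a2"]] / 2 + comps[["c2"]] + comps[["d2"]] / 4
  }
}

#' Negative log-likelihood of paired change scores under a twin model
#'
#' Sums, over complete pairs of both zygosities, the negative log of the
#' bivariate-normal density with mean from the covariate model and
#' covariance from [expected_twin_cov()]. A non-positive-definite covariance
#' yields `Inf` (rejected by the optimizer) rather than an error.
#'
#' @param data Pair data from [twin_pair_data()].
#' @param comps Standardized components (named, summing to 1).
#' @param total_var Total residual variance of the change score.
#' @param beta Mean-model coefficients (intercept first).
#' @return A single number.
#' @export
twin_negloglik <- function(data, comps, total_var, beta) {
  if (total_var <= 0) return(Inf)
  nll <- 0
  for (z in c("MZ", "DZ")) {
    pz <- data[[z]]
    if (is.null(pz) || pz$n == 0) next
    r <- zygosity_cor(comps, z)
    if (1 - r^2 <= 0) return(Inf)
    r1 <- pz$y1 - drop(pz$X1 %*% beta)
    r2 <- pz$y2 - drop(pz$X2 %*% beta)
    quad <- sum(r1^2 + r2^2 - 2 * r * r1 * r2) / (total_var * (1 - r^2))
    nll <- nll + pz$n * log(2 * pi) +
      0.5 * pz$n * log(total_var^2 * (1 - r^2)) + 0.5 * quad
  }
  nll
}

#' Arrange change scores as complete co-twin pairs with covariate designs
#'
#' @param deltas A delta tibble from [compute_delta()].
#' @param covariates If `TRUE` the mean model has intercept, sex, baseline
#'   age and baseline trait value; otherwise intercept only.
#' @return A list with elements `MZ` and `DZ` (each `n`, `y1`, `y2`, `X1`,
#'   `X2`) and `p` (mean-model dimension).
#' @export
twin_pair_data <- function(deltas, covariates = FALSE) {
  out <- list(p = if (covariates) 4L else 1L)
  for (z in c("MZ", "DZ")) {
    d <- complete_delta_pairs(deltas) |>
      dplyr::filter(.data$zygosity == z) |>
      dplyr::arrange(.data$pair_id, .data$twin_id)
    n <- nrow(d) / 2L
    i1 <- seq(1, by = 2, length.out = n); i2 <- i1 + 1L
    X <- if (covariates) {
      cbind(1, d$sex, d$age_baseline, d$baseline_value)
    } else {
      matrix(1, nrow(d), 1)
    }
    out[[z]] <- list(n = n, y1 = d$delta[i1], y2 = d$delta[i2],
                     X1 = X[i1, , drop = FALSE], X2 = X[i2, , drop = FALSE])
  }
  out
}

# Concentrated negative log-likelihood: for fixed standardized components the
# mean coefficients are GLS and the total variance has a closed form, so the
# optimizer only searches the (low-dimensional) component simplex.
conc_nll <- function(props, data) {
  rz <- c(MZ = zygosity_cor(props, "MZ"), DZ = zygosity_cor(props, "DZ"))
  if (any(1 - rz^2 <= 1e-12)) return(list(nll = Inf))
  p <- data$p
  M <- matrix(0, p, p); vv <- numeric(p); N <- 0
  for (z in c("MZ", "DZ")) {
    pz <- data[[z]]; if (pz$n == 0) next
    r <- rz[[z]]; w <- 1 / (1 - r^2)
    M <- M + w * (crossprod(pz$X1) + crossprod(pz$X2) -
                    r * (crossprod(pz$X1, pz$X2) + crossprod(pz$X2, pz$X1)))
    vv <- vv + w * (crossprod(pz$X1, pz$y1 - r * pz$y2) +
                      crossprod(pz$X2, pz$y2 - r * pz$y1))
    N <- N + pz$n
  }
  beta <- tryCatch(drop(solve(M, vv)), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = Inf))
  s <- 0
  for (z in c("MZ", "DZ")) {
    pz <- data[[z]]; if (pz$n == 0) next
    r <- rz[[z]]
    r1 <- pz$y1 - drop(pz$X1 %*% beta)
    r2 <- pz$y2 - drop(pz$X2 %*% beta)
    s <- s + sum(r1^2 + r2^2 - 2 * r * r1 * r2) / (1 - r^2)
  }
  total_var <- s / (2 * N)
  if (total_var <= 0) return(list(nll = Inf))
  nll <- N * log(2 * pi) + N +
    sum(vapply(c("MZ", "DZ"),
               function(z) data[[z]]$n * (log(total_var) + 0.5 * log(1 - rz[[z]]^2)),
               0))
  list(nll = nll, beta = beta, total_var = total_var)
}

props_from_free <- function(model, free_vals) {
  props <- setNames(c(0, 0, 0, 1), comp_names)
  free <- twin_models[[model]]
  if (length(free)) {
    props[free] <- free_vals
    props["e2"] <- 1 - sum(free_vals)
  }
  props
}

#' Moment (Falconer) starting values from twin correlations
#'
#' `a2 = 2 (rMZ - rDZ)` and `c2 = 2 rDZ - rMZ`, clipped to the unit simplex
#' with `e2` the remainder. Used to initialize the likelihood optimization.
#'
#' @param rmz,rdz MZ and DZ intra-pair correlations.
#' @return Named numeric `(a2, c2, d2, e2)`.
#' @export
#' @examples
#' falconer_start(0.50, 0.18)  # a2 = 0.64, c2 = 0, e2 = 0.36
falconer_start <- function(rmz, rdz) {
  a2 <- min(max(2 * (rmz - rdz), 0), 1)
  c2 <- min(max(2 * rdz - rmz, 0), 1)
  if (a2 + c2 > 0.99) {
    sc <- 0.99 / (a2 + c2)
    a2 <- a2 * sc; c2 <- c2 * sc
  }
  setNames(c(a2, c2, 0, 1 - a2 - c2), comp_names)
}

#' Full-model choice from the intra-pair correlations
#'
#' The dominance (ADE) decomposition is indicated when the MZ correlation
#' exceeds twice the DZ correlation; otherwise the shared-environment (ACE)
#' decomposition is used. Ties go to ACE. Vectorized.
#'
#' @param rmz,rdz MZ and DZ intra-pair correlations.
#' @return `"ACE"` or `"ADE"` (character vector).
#' @export
#' @examples
#' choose_full_model_icc(0.50, 0.18)  # ADE
#' choose_full_model_icc(0.29, 0.26)  # ACE
choose_full_model_icc <- function(rmz, rdz) {
  ifelse(rmz > 2 * rdz, "ADE", "ACE")
}

#' Full-model choice by AIC
#'
#' @param fit_ace,fit_ade Fits from [fit_twin_model()] on the same data.
#' @return `"ACE"` or `"ADE"`; ties go to ACE.
#' @export
choose_full_model_aic <- function(fit_ace, fit_ade) {
  if (fit_ade$aic < fit_ace$aic) "ADE" else "ACE"
}

#' Akaike information criterion from a log-likelihood
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @return `2 * k - 2 * loglik`.
#' @export
twin_aic <- function(loglik, k) 2 * k - 2 * loglik

#' Fit one biometric twin model to change scores by maximum likelihood
#'
#' Standardized variance components are parameterized through unconstrained
#' path-style coordinates (squares normalized onto the simplex) so each
#' component stays in `[0, 1]`, the components sum to one, and zero is
#' attainable. The mean coefficients and the total variance are concentrated
#' out in closed form; the remaining 0--2 dimensional search uses golden
#' section (one free component) or Nelder--Mead with multiple starts (the
#' Falconer moment start, seeded random restarts, and any supplied extra
#' starts), keeping the best.
#'
#' @inheritParams twin_pair_data
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param n_starts Number of starts for the two-component search (the
#'   Falconer start plus seeded random restarts).
#' @param seed Seed for the random restarts.
#' @param extra_starts Optional list of component vectors used as additional
#'   candidate starts (e.g. solutions of nested models).
#' @return A `twindelta_twinfit` object: `model`, `components`, `total_var`,
#'   `mean_coefs`, `loglik`, `k`, `aic`, `n_pairs`.
#' @export
fit_twin_model <- function(deltas, model, covariates = FALSE,
                           n_starts = 5, seed = 1L, extra_starts = list()) {
  model <- match.arg(model, names(twin_models))
  data <- if (is.list(deltas) && !is.data.frame(deltas) && !is.null(deltas$p)) {
    deltas
  } else {
    twin_pair_data(deltas, covariates)
  }
  for (z in c("MZ", "DZ")) {
    if (data[[z]]$n < 3) abort(sprintf("Need >= 3 complete %s pairs.", z))
    if (data[[z]]$n < 10) warn(sprintf("Fewer than 10 complete %s pairs.", z))
  }
  free <- twin_models[[model]]
  m <- length(free)

  best <- NULL
  consider <- function(free_vals) {
    props <- props_from_free(model, free_vals)
    sol <- conc_nll(props, data)
    if (is.finite(sol$nll) && (is.null(best) || sol$nll < best$nll)) {
      best <<- c(sol, list(props = props))
    }
    sol$nll
  }

  if (m == 0) {
    consider(numeric())
  } else if (m == 1) {
    opt <- optimize(function(x) consider(x), interval = c(0, 1 - 1e-9), tol = 1e-10)
    consider(0)  # boundary (pure E) is an exact candidate
    for (st in extra_starts) consider(min(max(st[free], 0), 1 - 1e-9))
  } else {
    # squares normalized to the simplex: free_j = t_j^2 / (1 + sum t^2)
    to_free <- function(theta) theta^2 / (1 + sum(theta^2))
    to_theta <- function(fv) {
      e2 <- max(1 - sum(fv), 1e-6)
      sqrt(pmax(fv, 0) / e2)
    }
    fal <- {
      rmz <- with(data$MZ, stats::cor(y1, y2))
      rdz <- with(data$DZ, stats::cor(y1, y2))
      falconer_start(rmz, rdz)
    }
    starts <- list(pmin(fal[free], 0.95))
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    for (i in seq_len(max(n_starts - 1, 0))) {
      fv <- runif(2, 0, 0.6)
      if (sum(fv) > 0.95) fv <- fv * 0.95 / sum(fv)
      starts <- c(starts, list(fv))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    for (st in extra_starts) {
      fv <- pmin(pmax(st[free], 0), 1)
      if (sum(fv) > 0.999) fv <- fv * 0.999 / sum(fv)
      starts <- c(starts, list(fv))
      consider(fv)  # the start itself is an exact candidate
    }
    for (st in starts) {
      optim(to_theta(st), function(th) consider(to_free(th)),
            method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-12))
    }
  }
  if (is.null(best)) {
    abort(sprintf("Twin-model likelihood could not be evaluated for %s.", model))
  }

  k <- data$p + 1L + m
  loglik <- -best$nll
  structure(list(
    model = model, components = best$props, total_var = best$total_var,
    mean_coefs = best$beta, loglik = loglik, k = k,
    aic = twin_aic(loglik, k),
    n_pairs = c(MZ = data$MZ$n, DZ = data$DZ$n),
    covariates = covariates,
    ci = NULL
  ), class = "twindelta_twinfit")
}

#' Likelihood-ratio test of a nested against a full twin model
#'
#' @param fit_full,fit_nested Fits from [fit_twin_model()] on the same data;
#'   the nested model's free components must be a subset of the full's.
#' @return A tibble with `statistic` (2 * difference in log-likelihood,
#'   floored at 0), `df` (difference in free parameters) and `p.value` from
#'   the chi-square upper tail (no boundary mixture).
#' @export
lrt <- function(fit_full, fit_nested) {
  if (!all(twin_models[[fit_nested$model]] %in% twin_models[[fit_full$model]])) {
    abort(sprintf("%s is not nested in %s.", fit_nested$model, fit_full$model))
  }
  if (fit_nested$loglik > fit_full$loglik + 1e-6) {
    warn(sprintf(
      "Nested %s log-likelihood exceeds full %s; the full-model optimization should be refit.",
      fit_nested$model, fit_full$model))
  }
  x2 <- max(2 * (fit_full$loglik - fit_nested$loglik), 0)
  df <- fit_full$k - fit_nested$k
  tibble::tibble(
    full = fit_full$model, nested = fit_nested$model,
    statistic = x2, df = df,
    p.value = pchisq(x2, df, lower.tail = FALSE)
  )
}

#' @export
print.twindelta_twinfit <- function(x, ...) {
  cat(sprintf("%s model (%d MZ / %d DZ pairs)\n", x$model,
              x$n_pairs[["MZ"]], x$n_pairs[["DZ"]]))
  cat(sprintf("  a2 = %.3f  c2 = %.3f  d2 = %.3f  e2 = %.3f\n",
              x$components[["a2"]], x$components[["c2"]],
              x$components[["d2"]], x$components[["e2"]]))
  cat(sprintf("  total var = %.4g, logLik = %.3f, k = %d, AIC = %.2f\n",
              x$total_var, x$loglik, x$k, x$aic))
  invisible(x)
}

#' @method tidy twindelta_twinfit
#' @export
tidy.twindelta_twinfit <- function(x, ...) {
  out <- tibble::tibble(
    component = comp_names,
    estimate = unname(x$components[comp_names]),
    free = comp_names %in% c(twin_models[[x$model]], "e2")
  )
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "component")
  out
}

#' @method glance twindelta_twinfit
#' @export
glance.twindelta_twinfit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, k = x$k, aic = x$aic,
    total_var = x$total_var,
    n_pairs_mz = x$n_pairs[["MZ"]], n_pairs_dz = x$n_pairs[["DZ"]]
  )
}
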