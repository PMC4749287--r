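#' Intra-twin-pair correlation of the change score
#'
#' Fits the exchangeable bivariate-normal model to pair-ordered change
#' scores of one zygosity by maximum likelihood: co-twins share a mean model
#' (optionally adjusted for sex, baseline age and baseline trait value), a
#' common variance and a common intra-pair correlation. Because the
#' likelihood is symmetric in the co-twins, the estimate is invariant to
#' within-pair ordering. The correlation equals the between-pair share of
#' the total variance, `icc = sigma2_s / (sigma2_s + sigma2_e)`, and may be
#' negative.
#'
#' The MLE is computed by iterated generalized least squares: given the
#' correlation, the mean coefficients are the GLS solution; given residuals,
#' the exchangeable covariance has a closed-form MLE through the sum/
#' difference rotation of each pair. Without covariates the fit is exact in
#' one step.
#'
#' @param deltas A delta tibble from [compute_delta()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param covariates If `TRUE`, adjust the mean for sex, baseline age and
#'   baseline trait value inside the likelihood.
#' @return A `twindelta_icc` object with fields `zygosity`, `icc`,
#'   `sigma2_s` (between-pair variance), `sigma2_e` (within-pair variance),
#'   `n_pairs`, `mean_coefs`, `loglik`, and `ci_low`/`ci_high` (`NA` until
#'   [bootstrap_icc_ci()] is used).
#' @export
estimate_icc <- function(deltas, zygosity, covariates = FALSE) {
  pd <- icc_pair_data(deltas, zygosity, covariates)
  if (pd$n < 3) abort(sprintf("Need >= 3 complete %s pairs (got %d).", zygosity, pd$n))
  est <- icc_ml(pd)
  if (!is.finite(est$rho)) abort("Zero total variance: ICC undefined.")
  structure(list(
    zygosity = zygosity, icc = est$rho,
    sigma2_s = est$c, sigma2_e = est$v - est$c,
    n_pairs = pd$n, mean_coefs = est$beta, loglik = est$loglik,
    ci_low = NA_real_, ci_high = NA_real_, covariates = covariates
  ), class = "twindelta_icc")
}

# Arrange complete pairs of one zygosity as (y1, y2) with per-twin design rows.
icc_pair_data <- function(deltas, zygosity, covariates) {
  d <- complete_delta_pairs(deltas) |>
    dplyr::filter(.data$zygosity == !!zygosity) |>
    dplyr::arrange(.data$pair_id, .data$twin_id)
  n <- nrow(d) / 2L
  i1 <- seq(1, by = 2, length.out = n)
  i2 <- i1 + 1L
  X <- if (covariates) {
    cbind(1, d$sex, d$age_baseline, d$baseline_value)
  } else {
    matrix(1, nrow(d), 1)
  }
  list(n = n, y1 = d$delta[i1], y2 = d$delta[i2],
       X1 = X[i1, , drop = FALSE], X2 = X[i2, , drop = FALSE])
}

# ML of the exchangeable bivariate normal via iterated GLS. The rotation
# z+ = (r1 + r2)/sqrt(2), z- = (r1 - r2)/sqrt(2) diagonalizes the
# exchangeable covariance, so given the mean the MLE of (variance,
# covariance) is (m+ + m-)/2 and (m+ - m-)/2 with m the mean squares.
icc_ml <- function(pd, max_iter = 50, tol = 1e-12) {
  n <- pd$n
  rho <- 0
  beta <- rep(0, ncol(pd$X1))
  for (iter in seq_len(max_iter)) {
    # GLS for beta given rho (total variance cancels)
    w <- 1 / (1 - rho^2)
    M <- w * (crossprod(pd$X1) + crossprod(pd$X2) -
                rho * (crossprod(pd$X1, pd$X2) + crossprod(pd$X2, pd$X1)))
    vv <- w * (crossprod(pd$X1, pd$y1 - rho * pd$y2) +
                 crossprod(pd$X2, pd$y2 - rho * pd$y1))
    beta_new <- drop(solve(M, vv))
    r1 <- pd$y1 - drop(pd$X1 %*% beta_new)
    r2 <- pd$y2 - drop(pd$X2 %*% beta_new)
    m_plus <- mean((r1 + r2)^2) / 2
    m_minus <- mean((r1 - r2)^2) / 2
    v <- (m_plus + m_minus) / 2
    cc <- (m_plus - m_minus) / 2
    rho_new <- if (is.finite(v) && v > 0) cc / v else NaN
    done <- !is.finite(rho_new) ||
      (max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol)
    beta <- beta_new
    rho <- rho_new
    if (done) break
    # keep the GLS weights finite when the correlation hits the boundary
    rho <- min(max(rho, -1 + 1e-9), 1 - 1e-9)
  }
  if (!is.finite(rho)) return(list(rho = NaN, v = 0, c = 0, beta = beta, loglik = NA_real_))
  rho <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
  v <- max(v, 1e-300)
  # |Sigma| = v^2 (1 - rho^2); -loglik per pair = log(2pi) + 0.5 log|Sigma| + 0.5 quad_i
  quad <- sum((r1^2 + r2^2) - 2 * rho * r1 * r2) / (v * (1 - rho^2))
  loglik <- -(n * log(2 * pi) + 0.5 * n * log(v^2 * (1 - rho^2)) + 0.5 * quad)
  list(rho = rho, v = v, c = cc, beta = beta, loglik = loglik)
}

#' Bootstrap confidence interval for the intra-pair correlation
#'
#' Resamples complete pairs (not individuals) with replacement within one
#' zygosity, re-estimates the ICC on each resample and returns the
#' percentile interval. Degenerate resamples (zero total variance) are
#' skipped and counted.
#'
#' @inheritParams estimate_icc
#' @param reps Number of bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed Integer seed; the interval is deterministic given it.
#' @return The `twindelta_icc` fit with `ci_low`, `ci_high` filled in and a
#'   `boot` field holding the resample estimates and skip count.
#' @export
bootstrap_icc_ci <- function(deltas, zygosity, covariates = FALSE,
                             reps = 1000, level = 0.95, seed = 1L) {
  if (reps < 100) abort("reps must be >= 100.")
  fit <- estimate_icc(deltas, zygosity, covariates)
  pd <- icc_pair_data(deltas, zygosity, covariates)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  est <- icc_boot_draws(pd, reps)
  qs <- quantile(est$rho, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  fit$ci_low <- unname(qs[1]); fit$ci_high <- unname(qs[2])
  fit$boot <- list(rho = est$rho, skipped = est$skipped, reps = reps, level = level)
  fit
}

# Draw `reps` pair-bootstrap ICC estimates from prepared pair data.
icc_boot_draws <- function(pd, reps) {
  rho <- rep(NA_real_, reps)
  skipped <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(pd$n, pd$n, replace = TRUE)
    pb <- list(n = pd$n, y1 = pd$y1[idx], y2 = pd$y2[idx],
               X1 = pd$X1[idx, , drop = FALSE], X2 = pd$X2[idx, , drop = FALSE])
    est <- tryCatch(icc_ml(pb), error = function(e) list(rho = NaN))
    if (is.finite(est$rho)) rho[b] <- est$rho else skipped <- skipped + 1L
  }
  list(rho = rho, skipped = skipped)
}

#' Bootstrap test for equal MZ and DZ intra-pair correlations
#'
#' Bootstraps the MZ and DZ ICCs independently (pair-level resampling) and
#' returns a two-sided percentile-of-zero p-value for the difference
#' `icc_MZ - icc_DZ`.
#'
#' @inheritParams bootstrap_icc_ci
#' @return A tibble with `icc_mz`, `icc_dz`, `diff` and `p.value`.
#' @export
compare_icc <- function(deltas, covariates = FALSE, reps = 1000, seed = 1L) {
  mz <- estimate_icc(deltas, "MZ", covariates)
  dz <- estimate_icc(deltas, "DZ", covariates)
  pd_mz <- icc_pair_data(deltas, "MZ", covariates)
  pd_dz <- icc_pair_data(deltas, "DZ", covariates)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  bmz <- icc_boot_draws(pd_mz, reps)$rho
  bdz <- icc_boot_draws(pd_dz, reps)$rho
  diffs <- bmz - bdz
  diffs <- diffs[is.finite(diffs)]
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  tibble::tibble(icc_mz = mz$icc, icc_dz = dz$icc,
                 diff = mz$icc - dz$icc, p.value = min(p, 1))
}

#' @export
print.twindelta_icc <- function(x, ...) {
  cat(sprintf("Intra-pair correlation (%s, %d pairs): %.3f", x$zygosity, x$n_pairs, x$icc))
  if (is.finite(x$ci_low)) cat(sprintf(" [%.3f, %.3f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' @method tidy twindelta_icc
#' @export
tidy.twindelta_icc <- function(x, ...) {
  tibble::tibble(
    zygosity = x$zygosity, icc = x$icc, sigma2_s = x$sigma2_s,
    sigma2_e = x$sigma2_e, ci_low = x$ci_low, ci_high = x$ci_high,
    n_pairs = x$n_pairs
  )
}

#' @method glance twindelta_icc
#' @export
glance.twindelta_icc <- function(x, ...) {
  tibble::tibble(zygosity = x$zygosity, icc = x$icc, logLik = x$loglik,
                 n_pairs = x$n_pairs)
}
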