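#' Mixed-effect kinship model for mean longitudinal change
#'
#' Tests whether a phenotype changed on average between the two occasions by
#' maximum (Gaussian) likelihood on the long-format cohort: fixed effects
#' for intercept, baseline age, sex and occasion (0 at time 1, 1 at time 2),
#' plus pair-structured random effects. The random structure has a genetic
#' effect correlated 1 between MZ and 0.5 between DZ co-twins (constant over
#' the two occasions of one person), an individual-level random intercept
#' linking the two occasions of each person, and an independent residual,
#' giving a block covariance per pair of up to 4 observations. Incomplete
#' pairs and missing single measurements are retained with the covariance
#' block restricted to the observed entries. The p-value for the occasion
#' effect is a Wald test against the standard normal.
#'
#' Variances are optimized on the standard-deviation scale (squared
#' internally) so zero variances are attainable; the fit is ML, not REML, so
#' log-likelihoods of nested variance structures are comparable.
#'
#' @param table A cohort tibble (cleaned, long format).
#' @param trait Trait column name.
#' @param free Named logical vector; set `genetic` or `individual` to
#'   `FALSE` to fix that variance component at zero.
#' @return A `twindelta_mixed` object: use [tidy()] for the fixed effects,
#'   [glance()] for variances / likelihood, and `residuals()` for
#'   fixed-effect residuals by occasion.
#' @export
fit_mixed_change <- function(table, trait,
                             free = c(genetic = TRUE, individual = TRUE)) {
  y_all <- table[[trait]]
  if (is.null(y_all)) abort(sprintf("Unknown trait '%s'.", trait))
  d <- table[!is.na(y_all), c("pair_id", "twin_id", "zygosity", "sex",
                              "age_baseline", "time")]
  d$y <- y_all[!is.na(y_all)]
  if (nrow(d) < 8) abort("Too few observations for the mixed model.")

  X <- cbind(`(Intercept)` = 1, age = d$age_baseline, sex = d$sex,
             time = as.numeric(d$time == 2))
  if (qr(X)$rank < ncol(X)) {
    abort("Singular fixed-effect design (a covariate or the time column is constant).")
  }

  blocks <- build_pair_blocks(d, X)
  n_obs <- nrow(d)
  vy <- var(d$y)
  floor_e <- 1e-10 * max(vy, 1e-8)

  free_g <- isTRUE(free[["genetic"]])
  free_p <- isTRUE(free[["individual"]])
  sd0 <- sqrt(max(vy, 1e-8))
  par0 <- c(if (free_g) sd0 / 2, if (free_p) sd0 / 2, sd0 / 2)

  unpack <- function(par) {
    i <- 1L
    vg <- if (free_g) { v <- par[i]^2; i <- i + 1L; v } else 0
    vp <- if (free_p) { v <- par[i]^2; i <- i + 1L; v } else 0
    c(vg, vp, par[i]^2 + floor_e)
  }
  nll <- function(par) mixed_profile_nll(unpack(par), blocks, n_obs)$nll

  # Nelder-Mead with restarts: a restart from the incumbent recovers from
  # simplex degeneracy at boundary optima (variance components at zero)
  fit <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  for (i in 1:3) {
    if (fit$convergence == 0) break
    refit <- optim(fit$par, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    if (refit$value > fit$value - 1e-10 && refit$convergence != 0) {
      fit <- refit
      break
    }
    fit <- refit
  }
  if (fit$value >= 1e10) {
    abort("Mixed-model optimization failed: no valid variance configuration found.")
  }
  v <- unpack(fit$par)
  sol <- mixed_profile_nll(v, blocks, n_obs)
  se <- sqrt(diag(solve(sol$M)))
  beta <- drop(sol$beta)
  zstat <- beta / se
  coefs <- tibble::tibble(
    term = c("(Intercept)", "age", "sex", "time"),
    estimate = beta, std.error = se, statistic = zstat,
    p.value = 2 * pnorm(-abs(zstat))
  )
  resid_tbl <- d |>
    dplyr::mutate(fitted = drop(X %*% beta), residual = .data$y - .data$fitted) |>
    tibble::as_tibble()
  structure(list(
    trait = trait, coefficients = coefs,
    sigma2_g = v[1], sigma2_p = v[2], sigma2_e = v[3],
    loglik = -fit$value, n_obs = n_obs,
    n_pairs = length(unique(d$pair_id)),
    p_time = coefs$p.value[coefs$term == "time"],
    residuals = resid_tbl
  ), class = "twindelta_mixed")
}

# Group pair blocks by (zygosity x missingness pattern) so each likelihood
# evaluation inverts each distinct block covariance once.
build_pair_blocks <- function(d, X) {
  ord <- order(d$pair_id, d$twin_id, d$time)
  d <- d[ord, ]; X <- X[ord, , drop = FALSE]
  # slot within pair: twin index (1/2 by twin_id order) x time
  twin_idx <- stats::ave(as.integer(factor(d$twin_id)), d$pair_id,
                         FUN = function(z) as.integer(factor(z)))
  slot <- (twin_idx - 1L) * 2L + d$time
  pattern <- vapply(split(slot, d$pair_id), paste, "", collapse = ",")
  key <- paste(d$zygosity, pattern[d$pair_id], sep = "|")

  p <- ncol(X)
  lapply(split(seq_len(nrow(d)), key), function(idx) {
    zyg <- d$zygosity[idx[1]]
    r <- if (zyg == "MZ") 1 else 0.5
    sl <- slot[idx][seq_len(sum(d$pair_id[idx] == d$pair_id[idx[1]]))]
    dd <- length(sl)
    person <- outer(ceiling(sl / 2), ceiling(sl / 2), "==")
    K <- ifelse(person, 1, r)
    P <- person * 1
    n_g <- length(idx) / dd
    Y <- matrix(d$y[idx], nrow = dd)
    Xarr <- array(t(X[idx, , drop = FALSE]), c(p, dd, n_g))
    Xflat <- matrix(aperm(Xarr, c(2, 3, 1)), nrow = dd)  # dd x (n_g * p)
    list(K = K, P = P, I = diag(dd), d = dd, n = n_g, Y = Y, Xflat = Xflat, p = p)
  })
}

mixed_profile_nll <- function(v, blocks, n_obs) {
  p <- blocks[[1]]$p
  M <- matrix(0, p, p); vv <- numeric(p)
  yy <- 0; logdet <- 0
  for (b in blocks) {
    S <- v[1] * b$K + v[2] * b$P + v[3] * b$I
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = 1e10, M = diag(p), beta = rep(0, p)))
    A <- chol2inv(ch)
    logdet <- logdet + 2 * b$n * sum(log(diag(ch)))
    AY <- A %*% b$Y
    AX <- A %*% b$Xflat
    Xtall <- matrix(b$Xflat, nrow = b$d * b$n)   # (d*n) x p
    AXtall <- matrix(AX, nrow = b$d * b$n)
    M <- M + crossprod(Xtall, AXtall)
    vv <- vv + drop(crossprod(AXtall, as.numeric(b$Y)))
    yy <- yy + sum(b$Y * AY)
  }
  beta <- tryCatch(solve(M, vv), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10, M = diag(p), beta = rep(0, p)))
  quad <- yy - sum(beta * vv)
  list(nll = 0.5 * (logdet + quad + n_obs * log(2 * pi)), M = M, beta = beta)
}

#' @export
print.twindelta_mixed <- function(x, ...) {
  cat("Mixed-effect kinship model for trait '", x$trait, "'\n", sep = "")
  cat(sprintf("  %d observations, %d pairs; logLik = %.3f\n",
              x$n_obs, x$n_pairs, x$loglik))
  cat(sprintf("  variances: genetic %.4g, individual %.4g, residual %.4g\n",
              x$sigma2_g, x$sigma2_p, x$sigma2_e))
  cat(sprintf("  time effect p = %.3g\n", x$p_time))
  invisible(x)
}

#' @method tidy twindelta_mixed
#' @export
tidy.twindelta_mixed <- function(x, ...) x$coefficients

#' @method glance twindelta_mixed
#' @export
glance.twindelta_mixed <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, sigma2_g = x$sigma2_g, sigma2_p = x$sigma2_p,
    sigma2_e = x$sigma2_e, logLik = x$loglik,
    n_obs = x$n_obs, n_pairs = x$n_pairs, p_time = x$p_time
  )
}

#' @export
residuals.twindelta_mixed <- function(object, ...) object$residuals
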