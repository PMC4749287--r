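test_that("expected co-twin covariance follows the ACE/ADE algebra", {
  expect_equal(expected_twin_cov("ACE", c(a2 = 0.4, c2 = 0.2, d2 = 0, e2 = 0.4),
                                 1, "MZ")[1, 2], 0.6)
  expect_equal(expected_twin_cov("ADE", c(a2 = 0.4, c2 = 0, d2 = 0.2, e2 = 0.4),
                                 1, "DZ")[1, 2], 0.25)
  cv <- expected_twin_cov("E", c(a2 = 0, c2 = 0, d2 = 0, e2 = 1), 2.5, "MZ")
  expect_equal(cv, matrix(c(2.5, 0, 0, 2.5), 2, 2))
  expect_error(
    expected_twin_cov("ACE", c(a2 = 0.4, c2 = 0, d2 = 0.2, e2 = 0.4), 1, "MZ"),
    "d2"
  )
})

test_that("the pairwise negative log-likelihood matches a direct bivariate-normal oracle", {
  # one standardized pair at the origin, independent co-twins: log(2*pi)
  one <- toy_deltas(pairs_mz = cbind(0, 0))
  pd <- twin_pair_data(one)
  comps_e <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 1)
  expect_equal(twin_negloglik(pd, comps_e, 1, 0), log(2 * pi), tolerance = 1e-12)

  # additivity: duplicating every pair doubles the value
  set.seed(21)
  m <- cbind(rnorm(10), rnorm(10))
  d1 <- toy_deltas(pairs_mz = m, pairs_dz = m + 1)
  d2 <- toy_deltas(pairs_mz = rbind(m, m), pairs_dz = rbind(m + 1, m + 1))
  comps <- c(a2 = 0.5, c2 = 0.1, d2 = 0, e2 = 0.4)
  v1 <- twin_negloglik(twin_pair_data(d1), comps, 1.3, 0.2)
  v2 <- twin_negloglik(twin_pair_data(d2), comps, 1.3, 0.2)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)

  # agreement with the independently coded density on random pairs
  pd1 <- twin_pair_data(d1)
  oracle <- -(sum(dbvn_log(pd1$MZ$y1, pd1$MZ$y2, 0.2, 0.2, 1.3, 0.6)) +
                sum(dbvn_log(pd1$DZ$y1, pd1$DZ$y2, 0.2, 0.2, 1.3, 0.35)))
  expect_equal(v1, oracle, tolerance = 1e-10)
})

test_that("Falconer moment starts and the full-model rules are exact", {
  expect_equal(unname(falconer_start(0.6, 0.3)[c("a2", "c2", "e2")]),
               c(0.6, 0, 0.4))
  expect_equal(unname(falconer_start(0.50, 0.18)[c("a2", "c2", "e2")]),
               c(0.64, 0, 0.36))
  expect_equal(unname(falconer_start(0, 0)[c("a2", "c2", "e2")]), c(0, 0, 1))

  expect_equal(choose_full_model_icc(0.50, 0.18), "ADE")
  expect_equal(choose_full_model_icc(0.29, 0.26), "ACE")
  expect_equal(choose_full_model_icc(0.40, 0.20), "ACE")  # tie goes to ACE

  f1 <- list(aic = -100); f2 <- list(aic = -101)
  expect_equal(choose_full_model_aic(f1, f2), "ADE")
  expect_equal(choose_full_model_aic(f1, list(aic = -100)), "ACE")
})

test_that("likelihood-ratio statistics and AIC follow their definitions", {
  mk <- function(model, loglik, k) list(model = model, loglik = loglik, k = k)
  same <- lrt(mk("ACE", -100, 4), mk("AE", -100, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 1)
  expect_equal(same$p.value, 1)

  # chi-square upper tail at the conventions used in published twin tables
  expect_equal(pchisq(1.40, 1, lower.tail = FALSE), 0.237, tolerance = 0.002)
  expect_equal(twin_aic(-100, 3), 206)
  expect_equal(twin_aic(0, 0), 0)

  expect_warning(lrt(mk("ACE", -101, 4), mk("AE", -100, 3)), "refit")
})

test_that("null-heritability data are recovered as almost pure unique environment", {
  d <- gen_deltas(2000, c(0, 0, 0, 1), seed = 23)
  fit <- fit_twin_model(d, "AE")
  expect_lte(fit$components[["a2"]], 0.05)
  expect_gte(fit$components[["e2"]], 0.95)
})

test_that("ACE maximum likelihood agrees with moment and grid oracles and sums to one", {
  d <- gen_deltas(5000, c(0.5, 0.2, 0, 0.3), seed = 24)
  pd <- twin_pair_data(d)
  fit <- fit_twin_model(d, "ACE")
  expect_equal(sum(fit$components), 1, tolerance = 1e-8)
  mom <- moments_oracle(pd)
  expect_lt(abs(fit$components[["a2"]] - mom[["a2"]]), 0.03)
  expect_lt(abs(fit$components[["c2"]] - mom[["c2"]]), 0.03)

  # small-sample AE fit against an exhaustive grid search of the likelihood
  d40 <- gen_deltas(20, c(0.5, 0, 0, 0.5), seed = 25)
  fit40 <- fit_twin_model(d40, "AE")
  expect_equal(-fit40$loglik, grid_oracle_ae(twin_pair_data(d40)), tolerance = 1e-3)
})

test_that("full-model log-likelihoods dominate their nested models", {
  for (seed in c(31, 32)) {
    d <- gen_deltas(400, c(0.4, 0.2, 0, 0.4), seed = seed)
    sel <- fit_twin_cascade(d, boot_reps = 0, seed = seed)
    ll <- vapply(sel$fits, `[[`, 0, "loglik")
    expect_gte(ll[["ACE"]], ll[["AE"]] - 1e-6)
    expect_gte(ll[["ACE"]], ll[["CE"]] - 1e-6)
    expect_gte(ll[["ACE"]], ll[["E"]] - 1e-6)
    expect_gte(ll[["ADE"]], ll[["AE"]] - 1e-6)
    expect_gte(ll[["ADE"]], ll[["E"]] - 1e-6)
    # AIC identity on a fitted pair: AIC_nested = AIC_full + X2 - 2 * df
    tab <- sel$lrt
    for (i in seq_len(nrow(tab))) {
      expect_equal(sel$fits[[tab$nested[i]]]$aic,
                   sel$fits[[tab$full[i]]]$aic + tab$statistic[i] - 2 * tab$df[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("component bootstrap intervals are reproducible subsets of the unit interval", {
  d <- gen_deltas(150, c(0.5, 0, 0, 0.5), seed = 26)
  a <- bootstrap_components_ci(d, "AE", reps = 100, seed = 7)
  b <- bootstrap_components_ci(d, "AE", reps = 100, seed = 7)
  expect_identical(a$low, b$low)
  expect_identical(a$high, b$high)
  expect_true(all(a$low >= 0 & a$high <= 1))
  expect_true(all(a$low <= a$high))
})
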