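mk_fit <- function(model, loglik, k) {
  list(model = model, loglik = loglik, k = k, aic = twin_aic(loglik, k))
}

test_that("parsimony selection follows the LRT cascade rules", {
  # full ADE; AE non-significant -> AE wins even though only one candidate
  full <- mk_fit("ADE", -391.25, 4)
  ae <- mk_fit("AE", -391.95, 3)   # X2 = 1.40, p ~ 0.24
  e <- mk_fit("E", -400, 2)        # strongly rejected
  tab <- dplyr::bind_rows(lrt(full, ae), lrt(full, e))
  expect_equal(select_best_model(full, list(AE = ae, E = e), tab), "AE")

  # all nested rejected -> full retained
  tab2 <- dplyr::bind_rows(lrt(full, mk_fit("AE", -399, 3)), lrt(full, e))
  expect_equal(select_best_model(full, list(AE = mk_fit("AE", -399, 3), E = e), tab2),
               "ADE")

  # parsimony overrides AIC: nested AIC may exceed the full model's
  ae_higher <- mk_fit("AE", -392.8, 3)     # X2 = 3.1, p ~ 0.078; higher AIC than full
  tab3 <- dplyr::bind_rows(lrt(full, ae_higher), lrt(full, e))
  expect_gt(ae_higher$aic, full$aic)
  expect_equal(select_best_model(full, list(AE = ae_higher, E = e), tab3), "AE")

  # among equal-parameter candidates the lower AIC wins
  full_ace <- mk_fit("ACE", -100, 4)
  ae2 <- mk_fit("AE", -100.5, 3)
  ce2 <- mk_fit("CE", -100.2, 3)
  tab4 <- dplyr::bind_rows(lrt(full_ace, ae2), lrt(full_ace, ce2))
  expect_equal(select_best_model(full_ace, list(AE = ae2, CE = ce2), tab4), "CE")

  # the most parsimonious non-rejected model wins over better-fitting ones
  e2 <- mk_fit("E", -100.8, 2)     # p ~ 0.45, fewest parameters
  tab5 <- dplyr::bind_rows(lrt(full_ace, ae2), lrt(full_ace, ce2), lrt(full_ace, e2))
  expect_equal(select_best_model(full_ace, list(AE = ae2, CE = ce2, E = e2), tab5), "E")
})

test_that("the cascade reports both full-model rules and never fits a DE model", {
  d <- gen_deltas(800, c(0.5, 0, 0, 0.5), seed = 41)
  sel <- fit_twin_cascade(d, boot_reps = 0, seed = 41)
  expect_setequal(names(sel$fits), c("ACE", "ADE", "AE", "CE", "E"))
  expect_true(sel$full_model %in% c("ACE", "ADE"))
  expect_true(sel$full_model_icc_rule %in% c("ACE", "ADE"))
  expect_true(all(sel$lrt$nested %in% c("AE", "CE", "E")))
  # excluded components are exactly zero in every fit
  expect_identical(sel$fits$AE$components[["c2"]], 0)
  expect_identical(sel$fits$AE$components[["d2"]], 0)
  expect_identical(sel$fits$E$components[["a2"]], 0)
})

test_that("pure unique-environment data select a minimal model with negligible familial components", {
  d <- gen_deltas(2000, c(0, 0, 0, 1), seed = 42)
  sel <- fit_twin_cascade(d, boot_reps = 0, seed = 42)
  best <- sel$best_fit
  expect_true(sel$best_model %in% c("E", "AE", "CE"))
  expect_lte(best$components[["a2"]], 0.05)
  expect_lte(best$components[["c2"]], 0.05)
  expect_gte(best$components[["e2"]], 0.95)
})

test_that("the end-to-end pipeline recovers a known additive architecture", {
  # a single draw can land near the rMZ > 2 rDZ boundary, so require a
  # majority of replicate cohorts rather than any one run
  runs <- lapply(43:47, function(s) {
    cfg <- change_config(2000, c(0.5, 0, 0, 0.5), seed = s)
    report <- run_pipeline(pipeline_config(cfg, boot_reps = 100,
                                           covariates = FALSE, seed = s))
    report$best_models
  })
  best <- vapply(runs, function(r) r$best_model, "")
  expect_gte(sum(best == "AE"), 4L)
  a2 <- vapply(runs[best == "AE"], function(r) r$A, 0)
  expect_true(all(a2 >= 0.42 & a2 <= 0.58))
})
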