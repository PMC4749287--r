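test_that("degenerate and textbook ICC cases are exact", {
  # identical co-twins: all variance is between pairs
  d <- toy_deltas(pairs_mz = cbind(c(1, 2, 3, 5), c(1, 2, 3, 5)))
  expect_equal(estimate_icc(d, "MZ")$icc, 1, tolerance = 1e-9)

  # fewer than 3 pairs
  expect_error(estimate_icc(toy_deltas(pairs_mz = cbind(1:2, 3:4)), "MZ"), ">= 3")

  # zero total variance
  expect_error(estimate_icc(toy_deltas(pairs_mz = cbind(rep(1, 5), rep(1, 5))), "MZ"),
               "Zero total variance")
})

test_that("the ML estimator matches a hand-coded ANOVA intraclass estimator", {
  y1 <- c(0, 2, 4); y2 <- c(1, 3, 5)
  d <- toy_deltas(pairs_mz = cbind(y1, y2))
  expect_equal(estimate_icc(d, "MZ")$icc, icc_anova_oracle(y1, y2), tolerance = 1e-6)

  # and on a larger random sample
  set.seed(12)
  s <- rnorm(200); y1 <- s + rnorm(200); y2 <- s + rnorm(200)
  d <- toy_deltas(pairs_mz = cbind(y1, y2))
  fit <- estimate_icc(d, "MZ")
  expect_equal(fit$icc, icc_anova_oracle(y1, y2), tolerance = 1e-6)
  expect_equal(fit$icc, fit$sigma2_s / (fit$sigma2_s + fit$sigma2_e), tolerance = 1e-12)
})

test_that("equal between- and within-pair variances give an ICC of one half", {
  set.seed(13)
  n <- 5000
  s <- rnorm(n)
  d <- toy_deltas(pairs_mz = cbind(s + rnorm(n), s + rnorm(n)))
  expect_equal(estimate_icc(d, "MZ")$icc, 0.5, tolerance = 0.03 / 0.5)
})

test_that("independent co-twins give an ICC near zero", {
  set.seed(14)
  d <- toy_deltas(pairs_mz = cbind(rnorm(5000), rnorm(5000)))
  expect_lt(abs(estimate_icc(d, "MZ")$icc), 0.03)
})

test_that("the estimate is invariant to within-pair ordering", {
  d <- gen_deltas(300, c(0.5, 0, 0, 0.5), seed = 15)
  base <- estimate_icc(d, "MZ", covariates = TRUE)$icc
  # swap co-twin order in every pair by reversing the twin label ordering
  swapped <- d |>
    dplyr::group_by(pair_id) |>
    dplyr::mutate(twin_id = rev(twin_id)) |>
    dplyr::ungroup()
  expect_lt(abs(estimate_icc(swapped, "MZ", covariates = TRUE)$icc - base), 1e-10)
})

test_that("covariate adjustment removes mean structure tied to baseline and sex", {
  d <- gen_deltas(800, c(0.5, 0, 0, 0.5), seed = 16, beta_age = 0.05, beta_sex = 1)
  raw <- estimate_icc(d, "MZ")$icc
  adj <- estimate_icc(d, "MZ", covariates = TRUE)$icc
  expect_true(is.finite(raw) && is.finite(adj))
  expect_equal(adj, 0.5, tolerance = 0.1)
})

test_that("pair bootstrap intervals are deterministic, ordered, and collapse for degenerate data", {
  d <- gen_deltas(120, c(0.5, 0, 0, 0.5), seed = 17)
  a <- bootstrap_icc_ci(d, "MZ", reps = 200, seed = 99)
  b <- bootstrap_icc_ci(d, "MZ", reps = 200, seed = 99)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_lte(a$ci_low, a$icc)
  expect_gte(a$ci_high, a$icc)

  dup <- toy_deltas(pairs_mz = matrix(rep(c(1, 2), each = 50), ncol = 2))
  ci <- bootstrap_icc_ci(dup, "MZ", reps = 100, seed = 1)
  expect_equal(ci$ci_high - ci$ci_low, 0)
})

test_that("the MZ/DZ comparison is calibrated under the null and detects genetic sharing", {
  # identical MZ and DZ data: null true by construction
  set.seed(18)
  s <- rnorm(300); m <- cbind(s + rnorm(300), s + rnorm(300))
  d <- toy_deltas(pairs_mz = m, pairs_dz = m)
  p <- compare_icc(d, reps = 400, seed = 3)$p.value
  expect_gt(p, 0.9)

  # strongly genetic change: rMZ = 0.6 vs rDZ = 0.3 at 2000 pairs/zygosity
  d2 <- gen_deltas(2000, c(0.6, 0, 0, 0.4), seed = 19)
  p2 <- compare_icc(d2, reps = 400, seed = 4)$p.value
  expect_lt(p2, 0.05)
})
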