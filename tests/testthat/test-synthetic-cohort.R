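test_that("the generator is deterministic given a seed and has exact design structure", {
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 40,
                    traits = list(trait_spec("a"), trait_spec("b", lognormal = TRUE,
                                                              mu_baseline = 1)),
                    seed = 11)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1, t2)

  expect_equal(nrow(t1), 2 * (30 + 40) * 2)
  expect_equal(anyDuplicated(t1[, c("twin_id", "time")]), 0L)
  counts <- dplyr::count(dplyr::distinct(t1, pair_id, twin_id), pair_id)
  expect_true(all(counts$n == 2))
  zyg <- dplyr::distinct(t1, pair_id, zygosity) |> dplyr::count(zygosity)
  expect_equal(sort(zyg$n), c(30, 40))
  # co-twins share birth date
  expect_true(all(tapply(t1$age_baseline, t1$pair_id, function(a) length(unique(a))) == 1))
  # log-normal trait is positive
  expect_true(all(t1$b > 0))
})

test_that("different seeds give different data", {
  cfg1 <- sim_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 1)
  cfg2 <- sim_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 2)
  expect_false(identical(simulate_cohort(cfg1)$trait1, simulate_cohort(cfg2)$trait1))
})

test_that("invalid trait specifications are rejected with the trait named", {
  expect_error(trait_spec("bad", var_change = c(0.5, 0.2, 0.2, 0.1)), "bad")
  expect_error(trait_spec("bad", var_change = c(0.6, 0.2, 0, 0.1)), "sum to 1")
  expect_error(trait_spec("bad", var_change = c(0.6, 0.4, 0, 0)), "e2 > 0")
  expect_error(trait_spec("bad", total_sd_change = 0), "positive")
  expect_error(sim_config(prop_female = 1.5), "prop_female")
  expect_error(sim_config(age_range = c(60, 20)), "age_range")
})

test_that("intra-pair correlations of simulated change match the twin covariance algebra", {
  # pure unique environment: co-twin changes are independent
  d0 <- gen_deltas(5000, c(0, 0, 0, 1), seed = 21)
  pd0 <- twin_pair_data(d0)
  expect_lt(abs(cor(pd0$MZ$y1, pd0$MZ$y2)), 0.04)
  expect_lt(abs(cor(pd0$DZ$y1, pd0$DZ$y2)), 0.04)

  # a2 = 0.5, c2 = 0.2: rMZ = 0.70, rDZ = 0.45
  d1 <- gen_deltas(5000, c(0.5, 0.2, 0, 0.3), seed = 22)
  pd <- twin_pair_data(d1)
  expect_equal(cor(pd$MZ$y1, pd$MZ$y2), 0.70, tolerance = 0.03 / 0.70)
  expect_equal(cor(pd$DZ$y1, pd$DZ$y2), 0.45, tolerance = 0.03 / 0.45)

  # near-pure additive: rMZ = 0.9, rDZ = 0.45
  d2 <- gen_deltas(5000, c(0.9, 0, 0, 0.1), seed = 23)
  pd <- twin_pair_data(d2)
  expect_equal(cor(pd$MZ$y1, pd$MZ$y2), 0.90, tolerance = 0.03 / 0.90)
  expect_equal(cor(pd$DZ$y1, pd$DZ$y2), 0.45, tolerance = 0.03 / 0.45)

  # near-pure dominance: rMZ = 0.9, rDZ = 0.225
  d3 <- gen_deltas(5000, c(0, 0, 0.9, 0.1), seed = 24)
  pd <- twin_pair_data(d3)
  expect_equal(cor(pd$MZ$y1, pd$MZ$y2), 0.90, tolerance = 0.03 / 0.90)
  expect_equal(cor(pd$DZ$y1, pd$DZ$y2), 0.225, tolerance = 0.03 / 0.225)

  # near-pure shared environment: rMZ = rDZ = 0.9
  d4 <- gen_deltas(5000, c(0, 0.9, 0, 0.1), seed = 25)
  pd <- twin_pair_data(d4)
  expect_equal(cor(pd$MZ$y1, pd$MZ$y2), 0.90, tolerance = 0.03 / 0.90)
  expect_equal(cor(pd$DZ$y1, pd$DZ$y2), 0.90, tolerance = 0.03 / 0.90)
})

test_that("total variance and mean of simulated change match the trait settings", {
  cfg <- change_config(5000, c(0.4, 0, 0, 0.6), seed = 31, beta_time = 0.8,
                       total_sd_change = 1.5)
  d <- compute_delta(simulate_cohort(cfg), "y")  # generator output, unmasked
  expect_equal(var(d$delta), 1.5^2, tolerance = 0.05)
  expect_equal(mean(d$delta), 0.8, tolerance = 0.05)
})

test_that("injected outliers are tracked and removed by the SD mask", {
  cfg <- sim_config(n_mz_pairs = 1250, n_dz_pairs = 1250,
                    traits = list(trait_spec("y", outlier_rate = 0.01,
                                             outlier_magnitude = 6)),
                    seed = 41)
  co <- simulate_cohort(cfg)  # 10,000 records
  spec <- cfg$traits[[1]]

  out0 <- inject_outliers(co, trait_spec("y", outlier_rate = 0), seed = 1)
  expect_identical(out0$table, co)
  expect_equal(nrow(out0$ids), 0L)

  out <- inject_outliers(co, spec, seed = 2)
  moved <- out$table$y != co$y
  expect_equal(nrow(out$ids), sum(moved))
  expect_equal(nrow(out$ids), round(0.01 * nrow(co)))

  # every displaced record is masked; the filter may additionally catch
  # natural tail values of the unbounded trait
  masked <- mask_outliers(out$table, "y", k_sd = 3)
  still_unmasked <- dplyr::anti_join(out$ids, masked$masked_ids,
                                     by = c("twin_id", "time"))
  expect_equal(nrow(still_unmasked), 0L)

  expect_warning(inject_outliers(co, trait_spec("y", outlier_rate = 0.01,
                                                outlier_magnitude = 2), seed = 3),
                 "survive")
})
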