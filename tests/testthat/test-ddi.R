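test_that("no inhibition gives AUC ratios centred at one", {
  s <- simulate_ddi_population(ddi_scenario(r = 0), models_tab1, 2000,
                               seed = 21)
  expect_equal(s$mean_aucr, 1, tolerance = 0.1)
  expect_equal(stats::median(log(s$subjects$aucr)), 0, tolerance = 0.02)
  # and with all variability off the ratio is exactly one
  s0 <- simulate_ddi_population(ddi_scenario(r = 0), models_novar, 5,
                                seed = 22)
  expect_equal(s0$subjects$aucr, rep(1, 5))
})

test_that("mean AUCR increases strictly over the inhibitor potency grid", {
  rr <- c(0.025, 0.05, 0.1, 0.25, 1, 2, 5, 10, 20)
  means <- vapply(rr, function(r) {
    simulate_ddi_population(ddi_scenario(r), models_tab1, 500,
                            seed = 23)$mean_aucr
  }, 1)
  expect_true(all(diff(means) > 0))
})

test_that("ddi simulation replays deterministically and responds to options", {
  a <- simulate_ddi_population(ddi_scenario(1), models_tab1, 200, seed = 31)
  b <- simulate_ddi_population(ddi_scenario(1), models_tab1, 200, seed = 31)
  expect_identical(a$subjects, b$subjects)
  nv <- simulate_ddi_population(ddi_scenario(1), models_novar, 1, seed = 31,
                                opts = ddi_options(noise = FALSE))
  nv2 <- simulate_ddi_population(ddi_scenario(1), models_novar, 1, seed = 31,
                                 opts = ddi_options(noise = FALSE,
                                                    vshift = FALSE))
  expect_false(isTRUE(all.equal(nv$subjects$aucr, nv2$subjects$aucr)))
})

test_that("synthesis-inhibition scenarios nest the transporter-only case", {
  out <- ksyn_scenario_profiles(c(0, 0.1, 10), models_tab1, 400, seed = 41)
  ref <- simulate_ddi_population(ddi_scenario(r = 1, rho = 0), models_tab1,
                                 400, seed = 41)
  # rho = 0 is bitwise the transporter-only simulation at the same seed
  expect_identical(out[["0"]]$subjects, ref$subjects)
  # stronger synthesis suppression lowers the apparent DDI
  expect_gt(out[["0"]]$mean_aucr, out[["0.1"]]$mean_aucr)
  expect_gt(out[["0.1"]]$mean_aucr, out[["10"]]$mean_aucr)
  # extreme synthesis shutdown pushes the ratio below one
  s_inf <- simulate_ddi_population(ddi_scenario(r = 1, rho = 1000),
                                   models_novar, 1, seed = 42,
                                   opts = ddi_options(noise = FALSE))
  expect_lt(s_inf$subjects$aucr, 1)
})

test_that("median inhibited profile exceeds the baseline and is returned", {
  s <- simulate_ddi_population(ddi_scenario(1), models_tab1, 300, seed = 51)
  expect_false(is.null(s$median_profile))
  css <- cpi_baseline(models_tab1$cpi$fixed)
  expect_gt(max(s$median_profile$conc), 2 * css)
})

test_that("type-I error of the power machinery is calibrated at the null", {
  pw <- power_curve(ddi_scenario(r = 0), alpha = 0.01, n_grid = 12,
                    n_reps = 3000, seed = 61, models = models_tab1)
  ci <- 0.01 + c(-3, 3) * sqrt(0.01 * 0.99 / 3000)
  expect_gt(pw$power, ci[1])
  expect_lt(pw$power, ci[2])
})

test_that("power grows with sample size and with inhibitor strength", {
  pw <- power_curve(ddi_scenario(r = 0.1), alpha = 0.01,
                    n_grid = c(3, 6, 12, 24), n_reps = 800, seed = 62,
                    models = models_tab1)
  expect_true(all(diff(pw$power) > -0.03))
  pw_hi <- power_curve(ddi_scenario(r = 0.5), alpha = 0.01, n_grid = 6,
                       n_reps = 800, seed = 62, models = models_tab1)
  expect_gt(pw_hi$power, pw$power[pw$n_grid == 6])
  # deterministic replay
  pw2 <- power_curve(ddi_scenario(r = 0.1), alpha = 0.01,
                     n_grid = c(3, 6, 12, 24), n_reps = 800, seed = 62,
                     models = models_tab1)
  expect_identical(pw$power, pw2$power)
})

test_that("reduced-replicate power estimates stay close to high-replicate ones", {
  p500 <- power_curve(ddi_scenario(r = 0.1), alpha = 0.01, n_grid = 8,
                      n_reps = 500, seed = 63, models = models_tab1)$power
  p5000 <- power_curve(ddi_scenario(r = 0.1), alpha = 0.01, n_grid = 8,
                       n_reps = 5000, seed = 64, models = models_tab1)$power
  expect_lt(abs(p500 - p5000), 0.05)
})
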