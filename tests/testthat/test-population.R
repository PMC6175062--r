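test_that("CV/variance conversions are mutually inverse log-normal forms", {
  cv <- c(2.9, 14.3, 35.2, 69.1)
  expect_equal(omega2_to_cv(cv_to_omega2(cv)), cv)
  expect_equal(cv_to_omega2(0), 0)
})

test_that("individual parameters follow theta * exp(eta + kappa)", {
  pop <- models_tab1$cpi
  p0 <- individual_params(pop)
  expect_equal(unlist(unclass(p0)), unlist(unclass(pop$fixed)))
  p2 <- individual_params(pop, eta = c(CLb = log(2)))
  expect_equal(p2$CLb, 2 * pop$fixed$CLb)
  p3 <- individual_params(pop, eta = c(CLb = log(2)), kappa = c(CLb = log(3)))
  expect_equal(p3$CLb, 6 * pop$fixed$CLb)
  expect_error(individual_params(pop, eta = c(nope = 1)), "unknown eta")
})

test_that("rifampicin-condition covariate shift is applied and reversible", {
  pop <- models_tab1$cpi
  on <- individual_params(pop, rif_present = TRUE)
  off <- individual_params(pop, rif_present = FALSE)
  expect_equal(on$V, pop$fixed$V_rif)
  expect_equal(off$V, pop$fixed$V)
  rsv_on <- individual_params(models_tab1$rsv, rif_present = TRUE)
  expect_equal(rsv_on$V1, models_tab1$rsv$fixed$V1_rif)
  expect_equal(rsv_on$Q, models_tab1$rsv$fixed$Q_rif)
  expect_equal(rsv_on$V2, models_tab1$rsv$fixed$V2_rif)
  # removing the flag restores the baseline parameters exactly
  expect_equal(unlist(unclass(individual_params(models_tab1$rsv))),
               unlist(unclass(models_tab1$rsv$fixed)))
})

test_that("sampled parameters have log-normal median and CV", {
  set.seed(42)
  pop <- models_tab1$cpi
  re <- draw_random_effects(pop, 20000, 2)
  clb <- pop$fixed$CLb * exp(re$eta[, "CLb"])
  expect_equal(stats::median(clb), pop$fixed$CLb, tolerance = 0.01)
  cv_emp <- stats::sd(clb) / mean(clb) * 100
  expect_equal(cv_emp, omega2_to_cv(pop$re$omega2[["CLb"]]),
               tolerance = 0.03)
  # IIV constant across occasions, IOV independent between occasions
  expect_equal(dim(re$kappa), c(20000, 2, 2))
  expect_lt(abs(stats::cor(re$kappa[, "CLb", 1], re$kappa[, "CLb", 2])),
            0.03)
})

test_that("residual-error variance and sampling match the combined model", {
  err <- models_tab1$cpi$err
  expect_equal(predict_observation(0, "plasma", err)$variance, 0.001^2)
  expect_equal(predict_observation(1, "plasma", err)$variance,
               0.139^2 * 1 + 0.001^2)
  expect_equal(round(predict_observation(1, "plasma", err)$variance, 6),
               0.019322)
  err0 <- residual_error_spec(plasma = c(prop = 0, add = 1e-12))
  expect_equal(sample_observation(rep(2, 5), "plasma", err0), rep(2, 5),
               tolerance = 1e-9)
  set.seed(7)
  f <- 5
  y <- sample_observation(rep(f, 1e5), "plasma", err)
  expect_lt(abs(mean(y) - f), 3 * stats::sd(y) / sqrt(1e5))
  v_theory <- 0.139^2 * f^2 + 0.001^2
  expect_equal(stats::var(y), v_theory, tolerance = 0.05)
  # LLOQ censoring switch
  yc <- sample_observation(rep(0.001, 100), "plasma", err, lloq = 0.001)
  expect_true(anyNA(yc))
})

test_that("packaged parameter file reproduces the estimation report values", {
  m <- load_parameters()
  expect_equal(m$cpi$fixed$ksyn, 12.7)
  expect_equal(m$cpi$fixed$V_rif, 3.4)
  expect_equal(m$rif$fixed$n, 8.63)
  expect_equal(m$rsv$fixed$CLb, 124)
  expect_equal(omega2_to_cv(m$cpi$re$omega2[["V"]]), 35.2)
  expect_equal(omega2_to_cv(m$cpi$re$pi2[["CLb"]]), 18.3)
  expect_equal(m$cpi$err$plasma[["prop"]], 0.139)
  expect_equal(m$rif$err$plasma[["add"]], 0.01)
  expect_equal(m$constants$fu_rif, 0.11)
})
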