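p_rif <- models_tab1$rif$fixed
p_cpi <- models_tab1$cpi$fixed
p_rsv <- models_tab1$rsv$fixed

test_that("transit input is zero at t = 0, conserves mass, peaks at n*MTT/(n+1)", {
  expect_equal(rif_input_rate(p_rif, 0), 0)
  expect_error(rif_input_rate(p_rif, -1), "non-negative")
  tt <- seq(0, 48, by = 0.005)
  rate <- rif_input_rate(p_rif, tt)
  total <- sum(diff(tt) * (head(rate, -1) + tail(rate, -1)) / 2)
  expect_equal(total, dose_umol(p_rif), tolerance = 1e-3)
  t_peak_analytic <- p_rif$n * p_rif$MTT / (p_rif$n + 1)
  expect_lt(abs(tt[which.max(rate)] - t_peak_analytic), 0.006)
  # stationarity at the analytic peak
  h <- 1e-5
  expect_lt(abs(rif_input_rate(p_rif, t_peak_analytic + h) -
                  rif_input_rate(p_rif, t_peak_analytic - h)) / (2 * h),
            1e-3 * max(rate))
})

test_that("rifampicin profile: zero dose, terminal slope, AUC mass balance", {
  p0 <- rif_params(dose_mg = 0)
  expect_true(all(simulate_rif(p0, 0:24)$conc == 0))
  prof <- simulate_rif(p_rif, c(24, 30), engine = "ode")
  # after absorption is complete the decline is mono-exponential with CL/V
  thalf <- log(2) * 6 / log(prof$conc[1] / prof$conc[2])
  expect_equal(thalf, log(2) * p_rif$V / p_rif$CL, tolerance = 1e-3)
  expect_equal(log(2) * p_rif$V / p_rif$CL, 4.31, tolerance = 0.001)
  fine <- simulate_rif(p_rif, seq(0, 400, 0.25), engine = "grid")
  auc <- auc_trapezoid(fine$time, fine$conc)$auc
  expect_equal(auc, dose_umol(p_rif) / p_rif$CL, tolerance = 0.01)
})

test_that("grid propagator matches the adaptive ODE solution within 0.5%", {
  tt <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  a <- simulate_rif(p_rif, tt, engine = "ode")
  b <- simulate_rif(p_rif, tt, engine = "grid")
  expect_lt(max(abs(a$conc - b$conc)) / max(a$conc), 0.005)
  rifprof <- simulate_rif(p_rif, seq(0, 24, 1 / 32), engine = "grid")
  s1 <- simulate_cpi(p_cpi, rifprof, times = seq(-7, 24, 0.5), engine = "ode")
  s2 <- simulate_cpi(p_cpi, rifprof, times = seq(-7, 24, 0.5), engine = "grid")
  expect_lt(max(abs(s1$plasma$conc - s2$plasma$conc) / s1$plasma$conc), 0.005)
  r1 <- simulate_rsv(p_rsv, times = 0:24, engine = "ode")
  r2 <- simulate_rsv(p_rsv, times = 0:24, engine = "grid")
  expect_lt(max(abs(r1$plasma$conc - r2$plasma$conc)) / max(r1$plasma$conc),
            0.005)
})

test_that("CPI baseline steady state", {
  expect_equal(cpi_baseline(p_cpi), 12.7 / (12.3 + 1.64))
  expect_equal(round(cpi_baseline(p_cpi), 3), 0.911)
  p2 <- p_cpi; p2$CLR <- 1e-12
  expect_equal(cpi_baseline(p2), p_cpi$ksyn / p_cpi$CLb, tolerance = 1e-9)
  p3 <- p_cpi; p3$ksyn <- 2 * p_cpi$ksyn
  expect_equal(cpi_baseline(p3), 2 * cpi_baseline(p_cpi))
})

test_that("CPI turnover derivatives: steady state, limits, inhibitor at Ki", {
  css <- cpi_baseline(p_cpi)
  d0 <- cpi_rhs(c(C = css, U = 0), p_cpi, c_rif = 0)
  expect_equal(unname(d0["C"]), 0, tolerance = 1e-12)
  expect_equal(unname(d0["U"]), p_cpi$CLR * css)
  # c_rif -> infinity removes the biliary term
  dinf <- cpi_rhs(c(C = css, U = 0), p_cpi, c_rif = 1e12)
  expect_equal(unname(dinf["C"]), (p_cpi$ksyn - p_cpi$CLR * css) / p_cpi$V,
               tolerance = 1e-6)
  # at C = Css and c_rif = Ki half the biliary clearance is released
  dki <- cpi_rhs(c(C = css, U = 0), p_cpi, c_rif = p_cpi$Ki)
  expect_equal(unname(dki["C"]), (p_cpi$CLb * css / 2) / p_cpi$V)
  # inhibited form reduces exactly to baseline at c_rif = 0
  expect_identical(cpi_rhs(c(C = 1.2, U = 0), p_cpi, c_rif = 0),
                   cpi_rhs(c(C = 1.2, U = 0), p_cpi, c_rif = 0,
                           scenario = ddi_scenario(r = 0)))
})

test_that("CPI simulation: baseline urine amount, inhibition, washout", {
  css <- cpi_baseline(p_cpi)
  s0 <- simulate_cpi(p_cpi, NULL, times = seq(-7, 24, 0.5))
  expect_equal(s0$plasma$conc, rep(css, nrow(s0$plasma)), tolerance = 1e-8)
  expect_equal(s0$urine$amount[1], 1.64 * css * 7, tolerance = 1e-6)
  expect_equal(round(s0$urine$amount[1], 2), 10.46)
  rifprof <- simulate_rif(p_rif, seq(0, 24, 1 / 32), engine = "grid")
  s1 <- simulate_cpi(p_cpi, rifprof, times = seq(-7, 24, 0.5))
  auc <- auc_trapezoid(s1$plasma$time, s1$plasma$conc, c(0, 24))$auc
  expect_gt(auc, 24 * css)
  # long after the inhibitor is gone the level returns to baseline
  rifl <- simulate_rif(p_rif, seq(0, 120, 1 / 16), engine = "grid")
  sw <- simulate_cpi(p_cpi, rifl, times = c(-7, seq(0, 120, 4)),
                     urine_intervals = list(c(0, 120)))
  expect_equal(tail(sw$plasma$conc, 1), css, tolerance = 1e-3)
})

test_that("CPI AUC is non-decreasing in the inhibition multiplier r", {
  rifprof <- simulate_rif(p_rif, seq(0, 24, 1 / 32), engine = "grid")
  aucs <- vapply(c(0, 0.1, 0.5, 1, 5, 20), function(r) {
    s <- simulate_cpi(p_cpi, rifprof, scenario = ddi_scenario(r),
                      times = seq(0, 24, 0.5), engine = "grid")
    auc_trapezoid(s$plasma$time, s$plasma$conc)$auc
  }, 1)
  expect_true(all(diff(aucs) > 0))
})

test_that("urinary amount equals CLR times the plasma AUC of the interval", {
  rifprof <- simulate_rif(p_rif, seq(0, 24, 1 / 32), engine = "grid")
  s <- simulate_cpi(p_cpi, rifprof, times = seq(-7, 24, 1 / 32))
  for (iv in list(c(-7, 0), c(0, 7), c(7, 24))) {
    keep <- s$plasma$time >= iv[1] & s$plasma$time <= iv[2]
    auc <- auc_trapezoid(s$plasma$time[keep], s$plasma$conc[keep])$auc
    amt <- s$urine$amount[s$urine$start == iv[1]]
    expect_equal(amt, p_cpi$CLR * auc, tolerance = 1e-4)
  }
})

test_that("mass conservation holds for each compound", {
  # rifampicin: absorbed = in body + eliminated
  tt <- seq(0, 48, 1 / 32)
  prof <- simulate_rif(p_rif, tt, engine = "grid")
  absorbed <- dose_umol(p_rif) *
    stats::pgamma((p_rif$n + 1) / p_rif$MTT * tail(tt, 1), p_rif$n + 1)
  eliminated <- p_rif$CL * auc_trapezoid(tt, prof$conc)$auc
  in_body_frac <- 1 - (eliminated) / absorbed
  # after 48 h only the depot/central residue is unaccounted
  expect_lt(abs(in_body_frac), 0.01)
  # rosuvastatin: renal + biliary split of total elimination
  r <- simulate_rsv(p_rsv, times = seq(0, 400, 0.5), engine = "grid",
                    urine_intervals = list(c(0, 400)))
  fe <- r$urine$amount[1] / dose_umol(p_rsv)
  expect_equal(fe, p_rsv$CLR / (p_rsv$CLR + p_rsv$CLb), tolerance = 1e-3)
})

test_that("rosuvastatin model: mass balance, Ki limit, renal fraction", {
  fine <- simulate_rsv(p_rsv, times = seq(0, 600, 0.25), engine = "grid")
  auc <- auc_trapezoid(fine$plasma$time, fine$plasma$conc)$auc
  expect_equal(auc, dose_umol(p_rsv) / (p_rsv$CLb + p_rsv$CLR),
               tolerance = 0.005)
  # infinite Ki: profile identical to control even with inhibitor present
  pki <- p_rsv; pki$Ki <- 1e12
  rifprof <- simulate_rif(p_rif, seq(0, 24, 1 / 32), engine = "grid")
  a <- simulate_rsv(p_rsv, times = 0:24, engine = "grid")
  b <- simulate_rsv(pki, rifprof, times = 0:24, rif_present = FALSE,
                    engine = "grid")
  expect_equal(a$plasma$conc, b$plasma$conc, tolerance = 1e-9)
  expect_equal(round(100 * p_rsv$CLR / (p_rsv$CLR + p_rsv$CLb)), 6)
})

test_that("clearance fractions and unbound Ki reproduce the reported values", {
  expect_equal(round(clearance_fraction(12.3, 1.64), 2), 0.88)
  expect_equal(round(clearance_fraction(124, 8.48), 2), 0.94)
  expect_equal(clearance_fraction(5, 0), 1.0)
  expect_equal(round(unbound_ki(1.15, 0.11), 2), 0.13)
  expect_equal(round(unbound_ki(2.23, 0.11), 2), 0.25)
  expect_equal(unbound_ki(3.7, 1), 3.7)
})
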