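# cached small synthetic trial shared across blocks
ds_est <- simulate_trial(seed = 501, models = models_tab1)
rif_truth <- rif_true_params(default_design(), models_tab1, 501)

test_that("Laplace matches adaptive quadrature on one-random-effect models", {
  set.seed(11)
  cases <- list(list(theta = 2, om = 0.09, sig = c(0.1, 0.05), n = 5),
                list(theta = 10, om = 0.3, sig = c(0.2, 0.01), n = 8),
                list(theta = 0.5, om = 0.02, sig = c(0.05, 0.2), n = 3))
  for (cs in cases) {
    eta_true <- rnorm(1, 0, sqrt(cs$om))
    f <- cs$theta * exp(eta_true)
    y <- f * (1 + rnorm(cs$n, 0, cs$sig[1])) + rnorm(cs$n, 0, cs$sig[2])
    pred <- function(eta) rep(cs$theta * exp(eta), cs$n)
    lap <- laplace_marginal_nll(y, pred, cs$om, cs$sig)
    quad <- quadrature_nll_1d(y, pred, cs$om, cs$sig)
    expect_lt(abs(lap - quad), 0.1)
  }
})

test_that("compiled CPI deviance agrees with an independent R Laplace route", {
  ds1 <- ds_est[ds_est$ID == 1 & ds_est$OCC == 1, ]
  class(ds1) <- c("pk_dataset", "data.frame")
  rif1 <- rif_truth[rif_truth$ID == 1 & rif_truth$OCC == 1, ]
  pop <- models_tab1$cpi
  ofv_cpp <- marginal_neg2ll(ds1, pop, rif_ebes = rif1)

  # independent route: deSolve simulation + generic optimisation over the
  # random effects + exact numerical curvature
  om <- sapply(c("ksyn", "CLb", "CLR", "V", "Ki"),
               function(p) pop$re$omega2[[p]])
  pi2 <- sapply(c("ksyn", "CLb"), function(p) pop$re$pi2[[p]])
  uvar <- c(om, pi2)
  obs_pl <- ds1[ds1$STREAM %in% "cpi_plasma", ]
  obs_ur <- ds1[ds1$STREAM %in% "cpi_urine", ]
  sig <- pop$err
  joint <- function(u) {
    nll <- 0
    for (k in 1) {
      eta <- c(ksyn = u[1], CLb = u[2], CLR = u[3], V = u[4], Ki = u[5])
      kap <- c(ksyn = u[6], CLb = u[7])
      rif_on <- TRUE
      p <- individual_params(pop, eta, kap, rif_present = rif_on)
      prof <- NULL
      if (rif_on) {
        r <- rif1[rif1$OCC == k, ]
        gg <- seq(0, 24, 1 / 32)
        prof <- data.frame(time = gg, conc = as.numeric(
          copropk:::cpp_rif_grid(gg, r$ka, r$CL, r$V, r$MTT, r$n, r$famt, 0)))
      }
      pk <- obs_pl[obs_pl$OCC == k, ]
      uk <- obs_ur[obs_ur$OCC == k, ]
      sim <- simulate_cpi(p, prof, ddi_scenario(r = as.numeric(rif_on)),
                          times = pk$TIME,
                          urine_intervals = lapply(seq_len(nrow(uk)),
                                                   function(i) c(uk$TSTART[i], uk$TIME[i])),
                          rif_present = FALSE, engine = "ode")
      fp <- sim$plasma$conc
      vp <- sig$plasma[["prop"]]^2 * fp^2 + sig$plasma[["add"]]^2
      fu <- sim$urine$amount
      vu <- sig$urine[["prop"]]^2 * fu^2 + sig$urine[["add"]]^2
      nll <- nll + 0.5 * sum(log(2 * pi * vp) + (pk$DV - fp)^2 / vp) +
        0.5 * sum(log(2 * pi * vu) + (uk$DV - fu)^2 / vu)
    }
    nll + 0.5 * sum(u^2 / uvar)
  }
  opt <- stats::nlminb(rep(0, 7), joint,
                       control = list(iter.max = 500, eval.max = 1000))
  polish <- stats::optim(opt$par, joint, method = "BFGS",
                         control = list(reltol = 1e-12, maxit = 500))
  if (polish$value < opt$objective) {
    opt <- list(par = polish$par, objective = polish$value)
  }
  H <- stats::optimHess(opt$par, joint)
  ofv_r <- 2 * opt$objective + sum(log(uvar)) +
    determinant(H, logarithm = TRUE)$modulus[1]
  expect_lt(abs(ofv_cpp - ofv_r), 0.5)
})

test_that("with negligible random-effect variances the OFV collapses to the fixed-effects likelihood", {
  ds0 <- simulate_trial(seed = 502, models = models_novar)
  pop <- models_novar$cpi
  ofv <- marginal_neg2ll(ds0, pop, rif_ebes = rif_true_params(
    default_design(), models_novar, 502))
  # direct Gaussian likelihood at the typical-value predictions
  manual <- 0
  sig <- pop$err
  rifprof <- simulate_rif(models_novar$rif$fixed, seq(0, 24, 1 / 32),
                          engine = "grid")
  for (id in 1:12) {
    for (k in 1:3) {
      rif_on <- k %in% c(1, 3)
      p <- individual_params(pop, rif_present = rif_on)
      pk <- ds0[ds0$ID == id & ds0$OCC == k & ds0$STREAM %in% "cpi_plasma", ]
      uk <- ds0[ds0$ID == id & ds0$OCC == k & ds0$STREAM %in% "cpi_urine", ]
      sim <- simulate_cpi(p, if (rif_on) rifprof,
                          ddi_scenario(r = as.numeric(rif_on)),
                          times = pk$TIME,
                          urine_intervals = lapply(seq_len(nrow(uk)),
                                                   function(i) c(uk$TSTART[i], uk$TIME[i])),
                          rif_present = FALSE, engine = "grid", dt = 1 / 16)
      fp <- sim$plasma$conc
      vp <- sig$plasma[["prop"]]^2 * fp^2 + sig$plasma[["add"]]^2
      fu <- sim$urine$amount
      vu <- sig$urine[["prop"]]^2 * fu^2 + sig$urine[["add"]]^2
      manual <- manual + sum(log(2 * pi * vp) + (pk$DV - fp)^2 / vp) +
        sum(log(2 * pi * vu) + (uk$DV - fu)^2 / vu)
    }
  }
  expect_equal(ofv, manual, tolerance = 1e-4)
})

test_that("empirical Bayes estimates recover known random effects from rich data", {
  pop <- models_tab1$cpi
  eta_true <- c(ksyn = 0.05, CLb = 0.2, CLR = -0.1, V = 0.3, Ki = -0.15)
  p <- individual_params(pop, eta_true, rif_present = TRUE)
  rifprof <- simulate_rif(models_tab1$rif$fixed, seq(0, 24, 1 / 16),
                          engine = "grid")
  tt <- seq(-7, 24, 0.25)
  sim <- simulate_cpi(p, rifprof, times = tt, rif_present = FALSE,
                      engine = "grid", dt = 1 / 16)
  # nearly noise-free observations on a dense grid
  err_small <- 1e-5
  ds1 <- data.frame(ID = 1L, OCC = 1L, TIME = c(0, tt),
                    TSTART = c(NA, rep(NA, length(tt))),
                    AMT = c(600, rep(NA, length(tt))),
                    CMT = c(1L, rep(3L, length(tt))),
                    EVID = c(1L, rep(0L, length(tt))),
                    DV = c(NA, sim$plasma$conc),
                    MDV = c(1L, rep(0L, length(tt))),
                    STREAM = c(NA, rep("cpi_plasma", length(tt))))
  ur <- data.frame(ID = 1L, OCC = 1L, TIME = sim$urine$end,
                   TSTART = sim$urine$start, AMT = NA, CMT = 4L, EVID = 0L,
                   DV = sim$urine$amount, MDV = 0L, STREAM = "cpi_urine")
  ds1 <- rbind(ds1, ur)
  class(ds1) <- c("pk_dataset", "data.frame")
  pop_small <- pop
  pop_small$err <- residual_error_spec(plasma = c(prop = err_small, add = 1e-7),
                                       urine = c(prop = err_small, add = 1e-7))
  rif1 <- data.frame(ID = 1L, OCC = 1L,
                     ka = models_tab1$rif$fixed$ka,
                     CL = models_tab1$rif$fixed$CL,
                     V = models_tab1$rif$fixed$V,
                     MTT = models_tab1$rif$fixed$MTT,
                     n = models_tab1$rif$fixed$n,
                     famt = dose_umol(models_tab1$rif$fixed))
  eb <- empirical_bayes(ds1, pop_small, rif_ebes = rif1)
  u_hat <- eb$u[[1]]
  # with a single occasion only eta + kappa is identified for ksyn and CLb;
  # the remaining effects are subject-level only
  expect_equal(u_hat[1] + u_hat[6], eta_true[["ksyn"]], tolerance = 2e-3)
  expect_equal(u_hat[2] + u_hat[7], eta_true[["CLb"]], tolerance = 2e-3)
  expect_equal(unname(u_hat[3:5]), unname(eta_true[c("CLR", "V", "Ki")]),
               tolerance = 2e-3)
  # shrinkage limit: negligible prior variance forces the estimates to 0
  pop_shrunk <- pop
  pop_shrunk$re$omega2[] <- 1e-8
  pop_shrunk$re$pi2[] <- 1e-8
  eb0 <- empirical_bayes(ds1, pop_shrunk, rif_ebes = rif1)
  expect_lt(max(abs(eb0$u[[1]])), 1e-3)
})

test_that("OFV increases when a parameter is perturbed away from the truth", {
  ofv0 <- marginal_neg2ll(ds_est, models_tab1$cpi, rif_ebes = rif_truth)
  for (par in c("ksyn", "CLb", "CLR", "Ki")) {
    for (fac in c(0.6, 1.6)) {
      pop2 <- models_tab1$cpi
      pop2$fixed[[par]] <- pop2$fixed[[par]] * fac
      expect_gt(marginal_neg2ll(ds_est, pop2, rif_ebes = rif_truth), ofv0)
    }
  }
})

test_that("fitting lowers the OFV from perturbed starting values", {
  m0 <- perturbed_models()
  ofv_init <- marginal_neg2ll(ds_est, m0$cpi, rif_ebes = rif_truth)
  ft <- fit_nlme(ds_est, m0$cpi, rif_ebes = rif_truth)
  expect_lt(ft$ofv, ofv_init)
  ratios <- ft$theta[c("ksyn", "CLb", "CLR", "Ki")] /
    unlist(unclass(models_tab1$cpi$fixed))[c("ksyn", "CLb", "CLR", "Ki")]
  # single-trial smoke check; the 20-trial recovery study asserts the
  # tighter median-bias property
  expect_true(all(abs(ratios - 1) < 0.5))
  expect_lt(stats::median(abs(ratios - 1)), 0.25)
})

test_that("visual predictive check bands behave as expected", {
  ds0 <- simulate_trial(seed = 601, models = models_novar, noise = FALSE)
  v0 <- vpc(ds0, models_novar, default_design(), n_replicates = 5, seed = 602,
            noise = FALSE)
  # zero-variance model: bands collapse onto the typical curve
  expect_equal(v0$sim_lo, v0$sim_hi, tolerance = 1e-10)
  expect_equal(v0$sim_med, v0$obs_med, tolerance = 1e-10)
  # band widths grow with the proportional residual error
  m_lo <- models_novar
  m_lo$cpi$err$plasma[["prop"]] <- 0.05
  m_hi <- models_novar
  m_hi$cpi$err$plasma[["prop"]] <- 0.3
  ds1 <- simulate_trial(seed = 603, models = m_lo)
  v_lo <- vpc(ds1, m_lo, default_design(), n_replicates = 30, seed = 604)
  v_hi <- vpc(ds1, m_hi, default_design(), n_replicates = 30, seed = 604)
  sel <- v_lo$STREAM == "cpi_plasma"
  width_lo <- mean(v_lo$sim_hi[sel] - v_lo$sim_lo[sel])
  width_hi <- mean(v_hi$sim_hi[sel] - v_hi$sim_lo[sel])
  expect_gt(width_hi, width_lo)
})

test_that("VPC of a correctly specified model covers the observed medians", {
  v <- vpc(ds_est, models_tab1, default_design(), n_replicates = 100,
           seed = 605)
  sel <- v$STREAM %in% c("cpi_plasma", "rif_plasma")
  cover <- mean(v$obs_med[sel] >= v$med_lo[sel] &
                  v$obs_med[sel] <= v$med_hi[sel])
  expect_gt(cover, 0.8)
})

test_that("goodness-of-fit residuals are standardised for the generating model", {
  ft <- structure(list(compound = "cpi",
                       theta = unlist(unclass(models_tab1$cpi$fixed)),
                       omega2 = copropk:::pop_re_vectors(models_tab1$cpi)$omega2,
                       pi2 = copropk:::pop_re_vectors(models_tab1$cpi)$pi2,
                       sigma = copropk:::sigma_matrix(models_tab1$cpi),
                       ebes = empirical_bayes(ds_est, models_tab1$cpi,
                                              rif_ebes = rif_truth)$u,
                       rif_ebes = rif_truth, vshift = TRUE),
                  class = "fit_result")
  g <- gof_table(ft, ds_est)
  expect_equal(nrow(g), 420 + 108)
  expect_lt(abs(mean(g$IWRES)), 0.15)
  expect_lt(abs(stats::sd(g$IWRES) - 1), 0.3)
  expect_lt(abs(stats::sd(g$CWRES_L) - 1), 0.35)
  expect_true(all(g$IPRED > 0))
})

test_that("likelihood-ratio test retains the rifampicin-condition distribution covariate", {
  # the rosuvastatin distribution parameters change drastically under
  # rifampicin; dropping that covariate must be rejected decisively
  thn <- c("ka", "CLR", "CLb", "V1", "V1_rif", "Q", "Q_rif", "V2",
           "V2_rif", "Ki")
  fixed <- setdiff(thn, "CLb")
  pop_red <- models_tab1$rsv
  pop_red$fixed$V1_rif <- pop_red$fixed$V1
  pop_red$fixed$V2_rif <- pop_red$fixed$V2
  pop_red$fixed$Q_rif <- pop_red$fixed$Q
  fit_red <- fit_nlme(ds_est, pop_red, rif_ebes = rif_truth,
                      fixed_params = fixed)
  fit_full <- fit_nlme(ds_est, models_tab1$rsv, rif_ebes = rif_truth,
                       fixed_params = fixed)
  lrt <- likelihood_ratio_test(fit_red, fit_full, df = 3)
  expect_gt(lrt$dofv, stats::qchisq(0.95, 3))
  expect_lt(lrt$p, 1e-6)
})
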