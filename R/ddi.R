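#' Options for the forward DDI / power simulations
#'
#' Controls the statistical structure of the simulated two-period
#' crossover: whether residual error is added to the sampled
#' concentrations before computing AUCs, whether the rifampicin-condition
#' volume shift of CPI is applied in hypothetical-inhibitor scenarios,
#' whether interoccasion variability is redrawn per period, and whether
#' the interindividual effects are shared between the two periods of a
#' subject (crossover) or drawn independently.
#'
#' @param noise add residual error to sampled concentrations (default
#'   FALSE: AUCs are computed from the noise-free sampled profiles, so the
#'   spread of the AUC ratios reflects the between-period and
#'   between-subject random effects only)
#' @param vshift apply the rifampicin-condition `V_rif` in the inhibited
#'   period (default TRUE)
#' @param iov redraw interoccasion effects per period (default TRUE)
#' @param share_eta share interindividual effects across the two periods
#'   (default TRUE, a true crossover)
#' @param obs_times plasma sampling grid used for the trapezoid AUC (h)
#' @param dt internal simulation grid resolution (h)
#' @return list of options
#' @export
ddi_options <- function(noise = FALSE, vshift = TRUE, iov = TRUE,
                        share_eta = TRUE,
                        obs_times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24),
                        dt = 1 / 16) {
  list(noise = noise, vshift = vshift, iov = iov, share_eta = share_eta,
       obs_times = obs_times, dt = dt)
}

# trapezoid quadrature weights on a fixed grid
trapezoid_weights <- function(tt) {
  n <- length(tt)
  w <- numeric(n)
  d <- diff(tt)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

# Simulate per-subject two-period crossover CPI AUCs under a hypothetical
# inhibitor.  RNG must be seeded by the caller.  Returns a data.frame of
# per-subject AUCs; when keep_profiles = TRUE also the full concentration
# matrices on the internal grid.
sim_crossover_auc <- function(n_subjects, scenario, models, opts,
                              keep_profiles = FALSE, chunk = 20000L) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  pr <- models$rif
  pc <- models$cpi
  grid <- seq(0, 24, by = opts$dt)
  oidx <- match(opts$obs_times, grid)
  if (anyNA(oidx)) stop("obs_times must lie on the simulation grid")
  w <- trapezoid_weights(opts$obs_times)
  errc <- pc$err$plasma
  out_ctrl <- numeric(n_subjects)
  out_inh <- numeric(n_subjects)
  profs <- if (keep_profiles) list() else NULL
  done <- 0L
  while (done < n_subjects) {
    ns <- min(chunk, n_subjects - done)
    # rifampicin individual parameters (inhibited period only)
    er <- draw_random_effects(pr, ns, 1)
    fr <- pr$fixed
    ka <- fr$ka * exp(er$eta[, "ka"] + er$kappa[, "ka", 1])
    CL <- fr$CL * exp(er$eta[, "CL"])
    V <- fr$V * exp(er$eta[, "V"] + er$kappa[, "V", 1])
    MTT <- fr$MTT * exp(er$eta[, "MTT"] + er$kappa[, "MTT", 1])
    nn <- fr$n * exp(er$eta[, "n"])
    if (!opts$iov) {
      ka <- fr$ka * exp(er$eta[, "ka"])
      V <- fr$V * exp(er$eta[, "V"])
      MTT <- fr$MTT * exp(er$eta[, "MTT"])
    }
    Prif <- cbind(ka, CL, V, MTT, nn, dose_umol(fr))
    Crif <- cpp_rif_grid_pop(grid, Prif, 0)
    # CPI individual parameters per period
    ec <- draw_random_effects(pc, ns, 2)
    eta2 <- if (opts$share_eta) ec$eta else {
      e2 <- draw_random_effects(pc, ns, 1)
      e2$eta
    }
    fc <- pc$fixed
    kap <- function(par, per) {
      if (opts$iov) ec$kappa[, par, per] else 0
    }
    ksynA <- fc$ksyn * exp(ec$eta[, "ksyn"] + kap("ksyn", 1))
    CLbA <- fc$CLb * exp(ec$eta[, "CLb"] + kap("CLb", 1))
    ksynB <- fc$ksyn * exp(eta2[, "ksyn"] + kap("ksyn", 2))
    CLbB <- fc$CLb * exp(eta2[, "CLb"] + kap("CLb", 2))
    CLRA <- fc$CLR * exp(ec$eta[, "CLR"])
    CLRB <- fc$CLR * exp(eta2[, "CLR"])
    Vbase <- if (opts$vshift) fc$V_rif else fc$V
    VB <- Vbase * exp(eta2[, "V"])
    KiB <- fc$Ki * exp(eta2[, "Ki"])
    cssA <- ksynA / (CLbA + CLRA)
    cssB <- ksynB / (CLbB + CLRB)
    Pcpi <- cbind(ksynB, CLbB, CLRB, VB, KiB)
    sol <- cpp_cpi_grid_pop(grid, Crif, Pcpi, scenario$r, scenario$rho, cssB)
    Finh <- sol$conc[, oidx, drop = FALSE]
    Fctrl <- matrix(cssA, nrow = ns, ncol = length(oidx))
    if (opts$noise) {
      nobs <- length(Finh)
      Yinh <- Finh * (1 + matrix(stats::rnorm(nobs, 0, errc[["prop"]]), ns)) +
        matrix(stats::rnorm(nobs, 0, errc[["add"]]), ns)
      Yctrl <- Fctrl * (1 + matrix(stats::rnorm(nobs, 0, errc[["prop"]]), ns)) +
        matrix(stats::rnorm(nobs, 0, errc[["add"]]), ns)
    } else {
      Yinh <- Finh
      Yctrl <- Fctrl
    }
    idx <- (done + 1L):(done + ns)
    out_inh[idx] <- as.numeric(Yinh %*% w)
    out_ctrl[idx] <- as.numeric(Yctrl %*% w)
    if (keep_profiles) profs[[length(profs) + 1L]] <- sol$conc
    done <- done + ns
  }
  res <- data.frame(subject = seq_len(n_subjects), auc_control = out_ctrl,
                    auc_inhibited = out_inh,
                    aucr = out_inh / out_ctrl)
  if (keep_profiles) {
    attr(res, "grid") <- grid
    attr(res, "profiles") <- do.call(rbind, profs)
  }
  res
}

#' Simulate a virtual DDI population for a hypothetical inhibitor
#'
#' Two-period crossover per subject: a control period at the individual
#' CPI baseline and an inhibited period in which a single 600-mg oral
#' rifampicin-like dose drives the competitive inhibition term, scaled by
#' the scenario multiplier `r`.  CPI AUC(0-24 h) is computed by trapezoid
#' on the plasma sampling grid in each period.
#'
#' @param scenario a [ddi_scenario()]
#' @param models list with population models `rif` and `cpi`
#' @param n_subjects number of virtual subjects
#' @param seed integer seed
#' @param opts a [ddi_options()] list
#' @return object of class `ddi_sim`: list with `subjects` (per-subject
#'   AUCs and ratios), `mean_aucr`, `median_aucr`, `median_profile`
#'   (data.frame time, conc of the inhibited-period median), `scenario`,
#'   `n_subjects`
#' @export
simulate_ddi_population <- function(scenario, models = default_models(),
                                    n_subjects = 1000, seed,
                                    opts = ddi_options()) {
  stopifnot(n_subjects >= 1, !missing(seed))
  set.seed(as.integer(seed))
  res <- sim_crossover_auc(n_subjects, scenario, models, opts,
                           keep_profiles = n_subjects <= 5000)
  med <- NULL
  if (!is.null(attr(res, "profiles"))) {
    med <- data.frame(time = attr(res, "grid"),
                      conc = apply(attr(res, "profiles"), 2, stats::median))
  }
  structure(list(subjects = res[, c("subject", "auc_control",
                                    "auc_inhibited", "aucr")],
                 mean_aucr = mean(res$aucr),
                 median_aucr = stats::median(res$aucr),
                 median_profile = med,
                 scenario = scenario, n_subjects = n_subjects),
            class = "ddi_sim")
}

#' @export
print.ddi_sim <- function(x, ...) {
  cat(sprintf(
    "DDI simulation: r = %g, rho = %g, %d subjects\n  mean AUCR = %.3f, median AUCR = %.3f\n",
    x$scenario$r, x$scenario$rho, x$n_subjects, x$mean_aucr, x$median_aucr))
  invisible(x)
}

#' Median CPI profiles under hypothetical synthesis inhibition
#'
#' Simulates the rifampicin-reference scenario (`r = 1`) with the
#' inhibitor additionally suppressing CPI synthesis with strength `rho`
#' relative to its effect on biliary clearance.  `rho = 0` reproduces the
#' transporter-only simulation exactly (same seed, same draws).
#'
#' @param rho_values synthesis-inhibition ratios (default 0, 0.1, 10)
#' @param models list with population models `rif` and `cpi`
#' @param n_subjects virtual subjects per scenario
#' @param seed integer seed (reused for every `rho` so scenarios differ
#'   only through `rho`)
#' @param opts a [ddi_options()] list
#' @return list of `ddi_sim` objects, one per `rho`, named by `rho`
#' @export
ksyn_scenario_profiles <- function(rho_values = c(0, 0.1, 10),
                                   models = default_models(),
                                   n_subjects = 1000, seed,
                                   opts = ddi_options()) {
  stopifnot(!missing(seed), all(rho_values >= 0))
  out <- lapply(rho_values, function(rho) {
    simulate_ddi_population(ddi_scenario(r = 1, rho = rho), models,
                            n_subjects, seed = seed, opts = opts)
  })
  names(out) <- as.character(rho_values)
  out
}

#' Simulation-based power curve for a crossover biomarker DDI study
#'
#' For each sample size `n`, simulates `n_reps` crossover trials of `n`
#' subjects under the scenario, applies a two-sided one-sample t-test to
#' the per-subject log AUC ratios (null: mean log AUCR = 0) at level
#' `alpha`, and estimates power as the rejection fraction.  Reports the
#' smallest `n` reaching the target power.
#'
#' @param scenario a [ddi_scenario()]
#' @param alpha significance level (default 0.01)
#' @param n_grid sample sizes to evaluate (default 2:30)
#' @param n_reps simulated trials per sample size (>= 500 recommended)
#' @param seed integer seed
#' @param models list with population models `rif` and `cpi`
#' @param target_power power target for the minimal sample size
#' @param opts a [ddi_options()] list
#' @return object of class `power_result`: list with `alpha`, `n_grid`,
#'   `power` (per `n`), `minimal_n`, `n_reps`, `scenario`
#' @export
power_curve <- function(scenario, alpha = 0.01, n_grid = 2:30, n_reps = 1000,
                        seed, models = default_models(), target_power = 0.8,
                        opts = ddi_options()) {
  stopifnot(!missing(seed), all(n_grid >= 2), n_reps >= 1,
            alpha > 0, alpha < 1)
  set.seed(as.integer(seed))
  power <- numeric(length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    la <- log(sim_crossover_auc(n_reps * n, scenario, models, opts)$aucr)
    X <- matrix(la, nrow = n_reps, ncol = n, byrow = TRUE)
    m <- rowMeans(X)
    s2 <- (rowSums(X^2) - n * m^2) / (n - 1)
    tstat <- m / sqrt(s2 / n)
    power[i] <- mean(abs(tstat) > stats::qt(1 - alpha / 2, df = n - 1))
  }
  hit <- n_grid[power >= target_power]
  structure(list(alpha = alpha, n_grid = n_grid, power = power,
                 minimal_n = if (length(hit)) min(hit) else NA_integer_,
                 n_reps = n_reps, target_power = target_power,
                 scenario = scenario),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power curve: r = %g, alpha = %g, %d reps per n\n",
              x$scenario$r, x$alpha, x$n_reps))
  print(data.frame(n = x$n_grid, power = round(x$power, 3)))
  cat(sprintf("smallest n with power >= %.2f: %s\n", x$target_power,
              ifelse(is.na(x$minimal_n), "not reached", x$minimal_n)))
  invisible(x)
}
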