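#' @useDynLib copropk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils head tail
NULL

# estimation grid resolution (h); 1/16 keeps all design times exactly on
# the grid (they are all multiples of 1/16 h)
.est_dt <- 1 / 16

est_grid <- function(compound) {
  t0 <- if (compound == "cpi") -7 else 0
  seq(t0, 24, by = .est_dt)
}

grid_index <- function(times, grid) {
  idx <- round((times - grid[1]) / .est_dt) + 1L
  bad <- idx < 1 | idx > length(grid) |
    abs(grid[pmin(pmax(idx, 1), length(grid))] - times) > 1e-9
  if (any(bad)) stop("observation times off the estimation grid: ",
                     paste(times[bad], collapse = ", "))
  idx
}

obs_rows <- function(dataset, stream) {
  dataset[dataset$EVID == 0 & !is.na(dataset$STREAM) &
            dataset$STREAM == stream & dataset$MDV == 0, , drop = FALSE]
}

# occasions on which a compound was dosed, from the dose rows
dosed_occasions <- function(dataset, depot_cmt) {
  unique(dataset$OCC[dataset$EVID == 1 & dataset$CMT == depot_cmt])
}

# rifampicin concentration curves on `grid` for each subject-occasion in
# `rif_ebes` (data.frame ID, OCC, ka, CL, V, MTT, n, famt)
rif_curve_lookup <- function(rif_ebes, grid) {
  if (is.null(rif_ebes)) return(NULL)
  curves <- vector("list", nrow(rif_ebes))
  for (i in seq_len(nrow(rif_ebes))) {
    r <- rif_ebes[i, ]
    curves[[i]] <- as.numeric(cpp_rif_grid(grid, r$ka, r$CL, r$V, r$MTT,
                                           r$n, r$famt, 0))
  }
  names(curves) <- paste(rif_ebes$ID, rif_ebes$OCC)
  curves
}

build_cpi_data <- function(dataset, rif_ebes = NULL) {
  grid <- est_grid("cpi")
  rif_occ <- dosed_occasions(dataset, .cmt_codes[["rif_depot"]])
  curves <- rif_curve_lookup(rif_ebes, grid)
  pl <- obs_rows(dataset, "cpi_plasma")
  ur <- obs_rows(dataset, "cpi_urine")
  ids <- sort(unique(c(pl$ID, ur$ID)))
  subjects <- vector("list", length(ids))
  occ_map <- list()
  for (si in seq_along(ids)) {
    id <- ids[si]
    occs <- sort(unique(c(pl$OCC[pl$ID == id], ur$OCC[ur$ID == id])))
    occ_map[[si]] <- occs
    sl <- vector("list", length(occs))
    for (ki in seq_along(occs)) {
      k <- occs[ki]
      has_rif <- k %in% rif_occ
      key <- paste(id, k)
      crif <- if (has_rif && !is.null(curves) && key %in% names(curves))
        curves[[key]] else rep(0, length(grid))
      pk <- pl[pl$ID == id & pl$OCC == k, ]
      uk <- ur[ur$ID == id & ur$OCC == k, ]
      sl[[ki]] <- list(crif = crif,
                       pidx = grid_index(pk$TIME, grid), pdv = pk$DV,
                       ulo = grid_index(uk$TSTART, grid),
                       uhi = grid_index(uk$TIME, grid), udv = uk$DV,
                       rif = has_rif)
    }
    subjects[[si]] <- sl
  }
  list(grid = grid, subjects = subjects, ids = ids, occ_map = occ_map)
}

build_rif_data <- function(dataset) {
  grid <- est_grid("rif")
  pl <- obs_rows(dataset, "rif_plasma")
  ids <- sort(unique(pl$ID))
  subjects <- vector("list", length(ids))
  occ_map <- list()
  for (si in seq_along(ids)) {
    id <- ids[si]
    occs <- sort(unique(pl$OCC[pl$ID == id]))
    occ_map[[si]] <- occs
    subjects[[si]] <- lapply(occs, function(k) {
      pk <- pl[pl$ID == id & pl$OCC == k, ]
      list(pidx = grid_index(pk$TIME, grid), pdv = pk$DV)
    })
  }
  list(grid = grid, subjects = subjects, ids = ids, occ_map = occ_map)
}

build_rsv_data <- function(dataset, rif_ebes = NULL) {
  grid <- est_grid("rsv")
  rif_occ <- dosed_occasions(dataset, .cmt_codes[["rif_depot"]])
  curves <- rif_curve_lookup(rif_ebes, grid)
  pl <- obs_rows(dataset, "rsv_plasma")
  ur <- obs_rows(dataset, "rsv_urine")
  ids <- sort(unique(c(pl$ID, ur$ID)))
  subjects <- vector("list", length(ids))
  occ_map <- list()
  for (si in seq_along(ids)) {
    id <- ids[si]
    occs <- sort(unique(c(pl$OCC[pl$ID == id], ur$OCC[ur$ID == id])))
    occ_map[[si]] <- occs
    subjects[[si]] <- lapply(occs, function(k) {
      has_rif <- k %in% rif_occ
      key <- paste(id, k)
      crif <- if (has_rif && !is.null(curves) && key %in% names(curves))
        curves[[key]] else rep(0, length(grid))
      pk <- pl[pl$ID == id & pl$OCC == k, ]
      uk <- ur[ur$ID == id & ur$OCC == k, ]
      list(crif = crif, pidx = grid_index(pk$TIME, grid), pdv = pk$DV,
           ulo = grid_index(uk$TSTART, grid),
           uhi = grid_index(uk$TIME, grid), udv = uk$DV, rif = has_rif)
    })
  }
  list(grid = grid, subjects = subjects, ids = ids, occ_map = occ_map)
}

theta_names <- function(compound) {
  switch(compound,
         rif = c("ka", "CL", "V", "MTT", "n"),
         cpi = c("ksyn", "CLb", "CLR", "V", "V_rif", "Ki"),
         rsv = c("ka", "CLR", "CLb", "V1", "V1_rif", "Q", "Q_rif", "V2",
                 "V2_rif", "Ki"))
}

sigma_matrix <- function(pop) {
  streams <- if (pop$compound == "rif") "plasma" else c("plasma", "urine")
  t(vapply(streams, function(s) pop$err[[s]][c("prop", "add")],
           numeric(2)))
}

pop_re_vectors <- function(pop) {
  nm <- re_param_names(pop$compound)
  omega2 <- vapply(nm$eta, function(p) {
    if (p %in% names(pop$re$omega2)) pop$re$omega2[[p]] else 0
  }, numeric(1))
  pi2 <- vapply(nm$kappa, function(p) {
    if (p %in% names(pop$re$pi2)) pop$re$pi2[[p]] else 0
  }, numeric(1))
  # the Laplace engine needs strictly positive prior variances; a
  # negligible floor stands in for "no random effect"
  list(omega2 = pmax(omega2, 1e-8), pi2 = pmax(pi2, 1e-8))
}

neg2ll_engine <- function(compound, dat, theta, omega2, pi2, sig, famt,
                          uinit, scenario = ddi_scenario(r = 1),
                          vshift = TRUE) {
  switch(compound,
         cpi = cpp_cpi_neg2ll(dat$grid, dat$subjects, theta, omega2, pi2,
                              sig, scenario$r, scenario$rho, vshift, uinit),
         rif = cpp_rif_neg2ll(dat$grid, dat$subjects, theta, omega2, pi2,
                              sig, famt, uinit),
         rsv = cpp_rsv_neg2ll(dat$grid, dat$subjects, theta, omega2, pi2,
                              sig, famt, uinit))
}

u_dim <- function(compound, nocc) {
  switch(compound, cpi = 5 + 2 * nocc, rif = 5 + 3 * nocc, rsv = 6 + nocc)
}

#' Approximate marginal -2 log-likelihood (OFV) of a population model
#'
#' Laplace approximation: for each subject the joint density of the data
#' and the random effects is maximised over the random effects by damped
#' Gauss-Newton, and the curvature correction uses the Gauss-Newton
#' (FOCE-like) Hessian.  For CPI and rosuvastatin the subject-specific
#' rifampicin concentration curves (empirical Bayes profiles from the
#' rifampicin fit) enter the inhibition term; without them the inhibitor
#' concentration is zero.
#'
#' @param dataset a `pk_dataset`
#' @param pop a [population_model()]
#' @param rif_ebes optional data.frame of per-subject-occasion rifampicin
#'   parameters (`ID`, `OCC`, `ka`, `CL`, `V`, `MTT`, `n`, `famt`), as
#'   returned by [rif_ebe_params()]
#' @param vshift apply the rifampicin-condition covariate shifts on the
#'   inhibited occasions (CPI volume; rosuvastatin distribution)?
#' @param scenario a [ddi_scenario()] scaling the inhibition driving term
#'   (the rifampicin reference by default)
#' @return the objective function value (-2 log marginal likelihood)
#' @export
marginal_neg2ll <- function(dataset, pop, rif_ebes = NULL, vshift = TRUE,
                            scenario = ddi_scenario(r = 1)) {
  compound <- pop$compound
  dat <- switch(compound,
                cpi = build_cpi_data(dataset, rif_ebes),
                rif = build_rif_data(dataset),
                rsv = build_rsv_data(dataset, rif_ebes))
  re <- pop_re_vectors(pop)
  theta <- unlist(unclass(pop$fixed)[theta_names(compound)])
  famt <- if (compound == "cpi") 0 else dose_umol(pop$fixed)
  uinit <- lapply(seq_along(dat$subjects), function(i)
    rep(0, u_dim(compound, length(dat$subjects[[i]]))))
  res <- neg2ll_engine(compound, dat, theta, re$omega2, re$pi2,
                       sigma_matrix(pop), famt, uinit, scenario = scenario,
                       vshift = vshift)
  res$neg2ll
}

#' Fit a population PK model by Laplace approximate maximum likelihood
#'
#' Optimises the fixed effects (and optionally the random-effect variances
#' and proportional residual errors) on the log scale with `nlminb`,
#' re-solving the per-subject random-effect modes at every objective
#' evaluation (warm-started across evaluations).
#'
#' @param dataset a `pk_dataset`
#' @param pop a [population_model()] holding the initial values
#' @param rif_ebes see [marginal_neg2ll()]; required to describe the
#'   inhibited occasions of CPI/rosuvastatin data
#' @param estimate character subset of `c("theta", "omega", "sigma")`;
#'   components not listed stay fixed at their initial values
#' @param fixed_params names of fixed-effect parameters to hold at their
#'   initial values (used by [profile_likelihood()])
#' @param vshift,scenario see [marginal_neg2ll()]
#' @param control passed to [stats::nlminb()]
#' @return object of class `fit_result`
#' @export
fit_nlme <- function(dataset, pop, rif_ebes = NULL, estimate = "theta",
                     fixed_params = character(), vshift = TRUE,
                     scenario = ddi_scenario(r = 1),
                     control = list(rel.tol = 1e-6, iter.max = 300,
                                    eval.max = 600)) {
  compound <- pop$compound
  dat <- switch(compound,
                cpi = build_cpi_data(dataset, rif_ebes),
                rif = build_rif_data(dataset),
                rsv = build_rsv_data(dataset, rif_ebes))
  re <- pop_re_vectors(pop)
  tn <- theta_names(compound)
  theta0 <- unlist(unclass(pop$fixed)[tn])
  sig0 <- sigma_matrix(pop)
  famt <- if (compound == "cpi") 0 else dose_umol(pop$fixed)
  free_th <- setdiff(tn, fixed_params)
  est_om <- "omega" %in% estimate
  est_sg <- "sigma" %in% estimate
  par0 <- log(theta0[free_th])
  if (est_om) par0 <- c(par0, log(re$omega2), log(re$pi2))
  if (est_sg) par0 <- c(par0, log(sig0[, "prop"]))
  n_om <- length(re$omega2) + length(re$pi2)
  env <- new.env()
  env$u <- lapply(seq_along(dat$subjects), function(i)
    rep(0, u_dim(compound, length(dat$subjects[[i]]))))
  unpack <- function(par) {
    i <- length(free_th)
    theta <- theta0
    theta[free_th] <- exp(par[seq_len(i)])
    omega2 <- re$omega2
    pi2 <- re$pi2
    if (est_om) {
      v <- exp(par[i + seq_len(n_om)])
      omega2 <- v[seq_along(re$omega2)]
      pi2 <- v[length(re$omega2) + seq_along(re$pi2)]
      i <- i + n_om
    }
    sig <- sig0
    if (est_sg) sig[, "prop"] <- exp(par[i + seq_len(nrow(sig0))])
    list(theta = theta, omega2 = omega2, pi2 = pi2, sig = sig)
  }
  obj <- function(par) {
    p <- unpack(par)
    res <- neg2ll_engine(compound, dat, p$theta, p$omega2, p$pi2, p$sig,
                         famt, env$u, scenario = scenario, vshift = vshift)
    if (!res$failed) env$u <- res$u
    res$neg2ll
  }
  opt <- stats::nlminb(par0, obj, control = control)
  if (opt$convergence != 0) {
    # one restart from the current solution guards against premature
    # "false convergence" stops on flat likelihood directions
    opt2 <- stats::nlminb(opt$par, obj, control = control)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  p <- unpack(opt$par)
  final <- neg2ll_engine(compound, dat, p$theta, p$omega2, p$pi2, p$sig,
                         famt, env$u, scenario = scenario, vshift = vshift)
  names(p$omega2) <- names(re$omega2)
  names(p$pi2) <- names(re$pi2)
  structure(list(compound = compound, theta = p$theta, omega2 = p$omega2,
                 pi2 = p$pi2, sigma = p$sig, ofv = final$neg2ll,
                 ebes = final$u, ids = dat$ids, occ_map = dat$occ_map,
                 convergence = opt$convergence, message = opt$message,
                 iterations = opt$iterations, estimate = estimate,
                 fixed_params = fixed_params, init = pop,
                 vshift = vshift, rif_ebes = rif_ebes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Population PK fit (%s), OFV = %.3f\n", x$compound, x$ofv))
  tab <- data.frame(parameter = names(x$theta),
                    estimate = signif(unname(x$theta), 4))
  nm <- re_param_names(x$compound)
  tab$iiv_cv <- signif(ifelse(tab$parameter %in% nm$eta,
                              omega2_to_cv(x$omega2[match(tab$parameter,
                                                          nm$eta)]),
                              NA), 3)
  tab$iov_cv <- signif(ifelse(tab$parameter %in% nm$kappa,
                              omega2_to_cv(x$pi2[match(tab$parameter,
                                                       nm$kappa)]),
                              NA), 3)
  print(tab, row.names = FALSE)
  cat("residual error (prop, add) per stream:\n")
  print(signif(x$sigma, 3))
  invisible(x)
}

#' Export a fit report as JSON
#'
#' @param fit a `fit_result`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  rep <- list(compound = fit$compound, ofv = fit$ofv,
              theta = as.list(fit$theta),
              iiv_cv = as.list(omega2_to_cv(fit$omega2)),
              iov_cv = as.list(omega2_to_cv(fit$pi2)),
              sigma = list(prop = as.list(fit$sigma[, "prop"]),
                           add = as.list(fit$sigma[, "add"])),
              convergence = fit$convergence)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-subject-occasion rifampicin parameters at the empirical Bayes modes
#'
#' Used to inject the perpetrator concentration curves into the CPI and
#' rosuvastatin fits (sequential, individual-PK-parameters style).
#'
#' @param fit a rifampicin `fit_result`
#' @return data.frame with `ID`, `OCC`, `ka`, `CL`, `V`, `MTT`, `n`,
#'   `famt`
#' @export
rif_ebe_params <- function(fit) {
  stopifnot(inherits(fit, "fit_result"), fit$compound == "rif")
  th <- fit$theta
  famt <- dose_umol(fit$init$fixed)
  rows <- list()
  for (si in seq_along(fit$ids)) {
    u <- fit$ebes[[si]]
    occs <- fit$occ_map[[si]]
    for (ki in seq_along(occs)) {
      o <- 5 + 3 * (ki - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        ID = fit$ids[si], OCC = occs[ki],
        ka = th[["ka"]] * exp(u[1] + u[o + 1]),
        CL = th[["CL"]] * exp(u[2]),
        V = th[["V"]] * exp(u[3] + u[o + 2]),
        MTT = th[["MTT"]] * exp(u[4] + u[o + 3]),
        n = th[["n"]] * exp(u[5]),
        famt = famt)
    }
  }
  do.call(rbind, rows)
}

#' True per-subject-occasion rifampicin parameters of a simulated trial
#'
#' Convenience for simulation studies: rebuilds the individual rifampicin
#' parameters a [simulate_trial()] call generated, by replaying its random
#' draws, so the probe models can be fitted with the perpetrator exposure
#' known exactly.
#'
#' @param design the `trial_design` used
#' @param models the population models used
#' @param seed the seed passed to [simulate_trial()]
#' @return data.frame as in [rif_ebe_params()]
#' @export
rif_true_params <- function(design, models, seed) {
  set.seed(as.integer(seed))
  nocc <- length(design$occasions)
  ns <- design$n_subjects
  re <- draw_random_effects(models$rif, ns, nocc)
  famt <- models$rif$fixed$F * design$doses[["rif_mg"]] /
    models$rif$fixed$MW * 1000
  rows <- list()
  for (s in seq_len(ns)) {
    for (k in seq_len(nocc)) {
      if (!"RIF" %in% design$occasions[[k]]$treatments) next
      kap <- stats::setNames(re$kappa[s, , k], colnames(re$kappa))
      p <- individual_params(models$rif, re$eta[s, ], kap)
      rows[[length(rows) + 1L]] <- data.frame(
        ID = s, OCC = k, ka = p$ka, CL = p$CL, V = p$V, MTT = p$MTT,
        n = p$n, famt = famt)
    }
  }
  do.call(rbind, rows)
}

#' Empirical Bayes estimates of the random effects
#'
#' Maximises the joint density of each subject's data and random effects
#' at fixed population parameters (the MAP / empirical Bayes estimate that
#' underlies the conditional estimation step).  A subject with no
#' observations gets the prior mode 0.
#'
#' @param dataset a `pk_dataset`
#' @param pop a [population_model()]
#' @param rif_ebes see [marginal_neg2ll()]
#' @return list with per-subject random-effect vectors (`u`), subject ids
#'   and the occasion map
#' @export
empirical_bayes <- function(dataset, pop, rif_ebes = NULL) {
  compound <- pop$compound
  dat <- switch(compound,
                cpi = build_cpi_data(dataset, rif_ebes),
                rif = build_rif_data(dataset),
                rsv = build_rsv_data(dataset, rif_ebes))
  re <- pop_re_vectors(pop)
  theta <- unlist(unclass(pop$fixed)[theta_names(compound)])
  famt <- if (compound == "cpi") 0 else dose_umol(pop$fixed)
  uinit <- lapply(seq_along(dat$subjects), function(i)
    rep(0, u_dim(compound, length(dat$subjects[[i]]))))
  res <- neg2ll_engine(compound, dat, theta, re$omega2, re$pi2,
                       sigma_matrix(pop), famt, uinit)
  list(u = res$u, ids = dat$ids, occ_map = dat$occ_map)
}

#' Sequential population fit: perpetrator first, then the probes
#'
#' Fits the rifampicin model, freezes its subject-level empirical Bayes
#' concentration curves, and injects them as the inhibitor input into the
#' CPI fit (simultaneous plasma + urine, both conditions) and the
#' rosuvastatin fit.
#'
#' @param dataset a `pk_dataset` containing all streams
#' @param models initial population models (list `rif`, `cpi`, `rsv`)
#' @param estimate see [fit_nlme()]
#' @param compounds which fits to run (default all three)
#' @param control passed to [fit_nlme()]
#' @return list with elements `rif`, `cpi`, `rsv` (`fit_result` objects,
#'   present if requested)
#' @export
fit_sequential <- function(dataset, models = default_models(),
                           estimate = "theta",
                           compounds = c("rif", "cpi", "rsv"),
                           control = list(rel.tol = 1e-6, iter.max = 300,
                                          eval.max = 600)) {
  out <- list()
  rif_ebes <- NULL
  if ("rif" %in% compounds) {
    out$rif <- fit_nlme(dataset, models$rif, estimate = estimate,
                        control = control)
    rif_ebes <- rif_ebe_params(out$rif)
  }
  if ("cpi" %in% compounds)
    out$cpi <- fit_nlme(dataset, models$cpi, rif_ebes = rif_ebes,
                        estimate = estimate, control = control)
  if ("rsv" %in% compounds)
    out$rsv <- fit_nlme(dataset, models$rsv, rif_ebes = rif_ebes,
                        estimate = estimate, control = control)
  out
}

#' Profile likelihood of one fixed-effect parameter
#'
#' Re-optimises the remaining free parameters at each grid value of the
#' profiled parameter and returns the OFV profile.  A rise of at least
#' `qchisq(0.95, 1) = 3.84` units within the profiled range indicates the
#' parameter is practically identifiable from the data.
#'
#' @param dataset a `pk_dataset`
#' @param pop a [population_model()]
#' @param parameter fixed-effect name to profile (e.g. `"V"`)
#' @param grid parameter values to profile over
#' @param rif_ebes see [marginal_neg2ll()]
#' @param estimate see [fit_nlme()]
#' @param vshift apply the rifampicin-condition volume shift?  With
#'   `vshift = FALSE` and `parameter = "V"` a single volume is profiled in
#'   both conditions (the base turnover model, the form whose
#'   identifiability is of interest)
#' @param control passed to [fit_nlme()]
#' @return object of class `likelihood_profile`: data.frame with `value`,
#'   `ofv`, `dofv` (rise over the minimum)
#' @export
profile_likelihood <- function(dataset, pop, parameter, grid,
                               rif_ebes = NULL, estimate = "theta",
                               vshift = TRUE,
                               control = list(rel.tol = 1e-6,
                                              iter.max = 200,
                                              eval.max = 400)) {
  stopifnot(parameter %in% theta_names(pop$compound))
  ofv <- vapply(grid, function(v) {
    pop_v <- pop
    pop_v$fixed[[parameter]] <- v
    if (parameter == "V" && !vshift) pop_v$fixed$V_rif <- v
    ft <- fit_nlme(dataset, pop_v, rif_ebes = rif_ebes, estimate = estimate,
                   fixed_params = parameter, vshift = vshift,
                   control = control)
    ft$ofv
  }, numeric(1))
  out <- data.frame(value = grid, ofv = ofv, dofv = ofv - min(ofv))
  attr(out, "parameter") <- parameter
  class(out) <- c("likelihood_profile", "data.frame")
  out
}

#' Laplace marginal -2 log-likelihood for a single-random-effect model
#'
#' Reference implementation used for small nonlinear mixed-effects models
#' with one subject-level random effect: the inner problem is solved
#' exactly by one-dimensional optimisation and the curvature is the exact
#' numerical second derivative (not the Gauss-Newton approximation).
#'
#' @param y observations of one subject
#' @param predict_fn function of the scalar random effect returning the
#'   prediction vector for `y`
#' @param omega2 variance of the random effect
#' @param sigma `c(prop, add)` residual-error components
#' @return -2 log marginal likelihood (Laplace approximation)
#' @export
laplace_marginal_nll <- function(y, predict_fn, omega2, sigma) {
  stopifnot(omega2 > 0, length(sigma) == 2)
  joint <- function(eta) {
    f <- predict_fn(eta)
    v <- sigma[1]^2 * f^2 + sigma[2]^2
    0.5 * sum(log(2 * pi * v) + (y - f)^2 / v) + 0.5 * eta^2 / omega2
  }
  opt <- stats::optimize(joint, c(-10, 10) * sqrt(omega2) + c(-1, 1))
  eta_hat <- opt$minimum
  h <- 1e-4
  hess <- (joint(eta_hat + h) - 2 * opt$objective + joint(eta_hat - h)) / h^2
  2 * opt$objective + log(omega2) + log(hess)
}

#' Visual predictive check
#'
#' Simulates `n_replicates` trials from the population models under the
#' same design, and summarises per stream, rifampicin condition and
#' nominal time: the 2.5/50/97.5 percentiles of the pooled simulated
#' observations, the replicate-to-replicate 95% interval of the per-bin
#' median, and the observed percentiles.
#'
#' @param dataset observed (or reference simulated) `pk_dataset`
#' @param models population models (list `rif`, `cpi`, `rsv`)
#' @param design the `trial_design` to simulate under
#' @param n_replicates number of simulated replicate trials (>= 200)
#' @param seed integer seed
#' @param noise include residual error in the simulated replicates?
#' @return object of class `vpc_result`: data.frame with columns `STREAM`,
#'   `rif`, `TIME`, simulated band (`sim_lo`, `sim_med`, `sim_hi`), the
#'   median-band interval (`med_lo`, `med_hi`) and observed percentiles
#'   (`obs_lo`, `obs_med`, `obs_hi`)
#' @export
vpc <- function(dataset, models = default_models(),
                design = default_design(), n_replicates = 500, seed,
                noise = TRUE) {
  stopifnot(n_replicates >= 1, !missing(seed))
  rif_occ <- dosed_occasions(dataset, .cmt_codes[["rif_depot"]])
  key_of <- function(d) paste(d$STREAM, d$OCC %in% rif_occ, d$TIME)
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0 &
                   !is.na(dataset$STREAM), ]
  okey <- key_of(obs)
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  sims <- vector("list", n_replicates)
  meds <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    ds <- simulate_trial(design, models, seed = as.integer(seed) + i - 1L,
                         noise = noise)
    so <- ds[ds$EVID == 0 & ds$MDV == 0 & !is.na(ds$STREAM), ]
    k <- key_of(so)
    sims[[i]] <- data.frame(key = k, DV = so$DV)
    meds[[i]] <- tapply(so$DV, k, stats::median)
  }
  pool <- do.call(rbind, sims)
  bins <- sort(unique(okey))
  medmat <- do.call(rbind, lapply(meds, function(m) m[bins]))
  out <- do.call(rbind, lapply(bins, function(b) {
    sv <- pool$DV[pool$key == b]
    ov <- obs$DV[okey == b]
    sq <- qs(sv)
    oq <- qs(ov)
    mq <- stats::quantile(medmat[, b], c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
    parts <- strsplit(b, " ")[[1]]
    data.frame(STREAM = parts[1], rif = as.logical(parts[2]),
               TIME = as.numeric(parts[3]),
               sim_lo = sq[1], sim_med = sq[2], sim_hi = sq[3],
               med_lo = mq[1], med_hi = mq[2],
               obs_lo = oq[1], obs_med = oq[2], obs_hi = oq[3])
  }))
  out <- out[order(out$STREAM, out$rif, out$TIME), ]
  rownames(out) <- NULL
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Goodness-of-fit table for a fitted model
#'
#' Population predictions (`PRED`, random effects at zero), individual
#' predictions (`IPRED`, random effects at the empirical Bayes modes),
#' individual weighted residuals (`IWRES = (DV - IPRED)/sd(IPRED)`), and a
#' linearisation-based conditional weighted residual (`CWRES_L`), computed
#' by first-order expansion of the individual prediction around the
#' empirical Bayes mode (the FOCE-style diagnostic).
#'
#' @param fit a `fit_result` for the CPI model
#' @param dataset the dataset that was fitted
#' @return data.frame with `ID`, `OCC`, `TIME`, `STREAM`, `DV`, `PRED`,
#'   `IPRED`, `IWRES`, `CWRES_L`
#' @export
gof_table <- function(fit, dataset) {
  stopifnot(inherits(fit, "fit_result"), fit$compound == "cpi")
  dat <- build_cpi_data(dataset, fit$rif_ebes)
  sig <- fit$sigma
  re <- list(omega2 = fit$omega2, pi2 = fit$pi2)
  rows <- list()
  for (si in seq_along(dat$subjects)) {
    subj <- dat$subjects[[si]]
    u_hat <- fit$ebes[[si]]
    q <- length(u_hat)
    f_i <- as.numeric(cpp_cpi_predict(dat$grid, subj, fit$theta, 1, 0, TRUE,
                                      u_hat))
    f_0 <- as.numeric(cpp_cpi_predict(dat$grid, subj, fit$theta, 1, 0, TRUE,
                                      rep(0, q)))
    J <- matrix(0, length(f_i), q)
    h <- 1e-4
    for (k in seq_len(q)) {
      u2 <- u_hat
      u2[k] <- u2[k] + h
      J[, k] <- (as.numeric(cpp_cpi_predict(dat$grid, subj, fit$theta, 1, 0,
                                            TRUE, u2)) - f_i) / h
    }
    uvar <- c(re$omega2, rep(re$pi2, length(subj)))
    # observation bookkeeping mirroring the engine's row order
    meta <- do.call(rbind, lapply(seq_along(subj), function(ki) {
      oc <- subj[[ki]]
      occ <- dat$occ_map[[si]][ki]
      rbind(
        if (length(oc$pidx))
          data.frame(OCC = occ, TIME = dat$grid[oc$pidx],
                     STREAM = "cpi_plasma", DV = oc$pdv, sp = sig[1, "prop"],
                     sa = sig[1, "add"]),
        if (length(oc$ulo))
          data.frame(OCC = occ, TIME = dat$grid[oc$uhi],
                     STREAM = "cpi_urine", DV = oc$udv, sp = sig[2, "prop"],
                     sa = sig[2, "add"]))
    }))
    v_i <- meta$sp^2 * f_i^2 + meta$sa^2
    iwres <- (meta$DV - f_i) / sqrt(v_i)
    # FOCE-style linearisation around the EBE mode
    mu <- f_i - as.numeric(J %*% u_hat)
    Vm <- J %*% (uvar * t(J)) + diag(v_i, length(f_i))
    cw <- tryCatch(solve(t(chol(Vm)), meta$DV - mu),
                   error = function(e) rep(NA_real_, length(f_i)))
    rows[[length(rows) + 1L]] <- data.frame(
      ID = dat$ids[si], OCC = meta$OCC, TIME = meta$TIME,
      STREAM = meta$STREAM, DV = meta$DV, PRED = f_0, IPRED = f_i,
      IWRES = iwres, CWRES_L = as.numeric(cw))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test between nested population fits
#'
#' Compares the objective function values of a reduced and a full model
#' fit (e.g. with and without the rifampicin-condition covariate) against
#' the chi-squared distribution; the criterion used for covariate and
#' random-effect retention during model development.
#'
#' @param fit_reduced `fit_result` of the constrained model
#' @param fit_full `fit_result` of the richer model
#' @param df difference in the number of free parameters
#' @return list with `dofv` (OFV drop), `df` and `p`
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full, df = 1) {
  stopifnot(inherits(fit_reduced, "fit_result"),
            inherits(fit_full, "fit_result"), df >= 1)
  d <- fit_reduced$ofv - fit_full$ofv
  list(dofv = d, df = df,
       p = stats::pchisq(max(d, 0), df, lower.tail = FALSE))
}
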