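#' Default three-occasion crossover trial design
#'
#' Twelve healthy subjects studied on three occasions separated by 7-day
#' washouts: a single 600-mg oral rifampicin dose alone (OCC1), a single
#' 5-mg oral rosuvastatin dose alone (OCC2), and both together (OCC3).
#' Doses are given at `t = 0` of each occasion; pre-dose times are
#' negative.  CPI plasma is sampled on every occasion (including a pre-dose
#' baseline at `t = 0`); drug plasma sampling is post-dose only.  Urine is
#' collected over (-7, 0), (0, 7) and (7, 24) h for CPI and (0, 7),
#' (7, 24) h for rosuvastatin.  The per-occasion sample counts reproduce
#' the published totals (rifampicin 276, CPI 420, rosuvastatin 264 plasma
#' rows).
#'
#' @param n_subjects number of subjects (default 12)
#' @return an object of class `trial_design`
#' @export
default_design <- function(n_subjects = 12) {
  rif12 <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  rif11 <- setdiff(rif12, 16)
  cpi12 <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  cpi11 <- setdiff(cpi12, 16)
  cpi_urine <- list(c(-7, 0), c(0, 7), c(7, 24))
  rsv_urine <- list(c(0, 7), c(7, 24))
  occ <- function(label, treatments, rif_t, cpi_t, rsv_t) {
    list(label = label, treatments = treatments,
         plasma_times = list(rif = rif_t, cpi = cpi_t, rsv = rsv_t),
         urine_intervals = list(
           cpi = cpi_urine,
           rsv = if ("RSV" %in% treatments) rsv_urine else list()))
  }
  design <- list(
    n_subjects = n_subjects,
    washout_days = 7,
    doses = c(rif_mg = 600, rsv_mg = 5),
    occasions = list(
      occ("OCC1", "RIF", rif12, cpi12, numeric()),
      occ("OCC2", "RSV", numeric(), cpi12, rif11),
      occ("OCC3", c("RIF", "RSV"), rif11, cpi11, rif11)))
  structure(design, class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Crossover trial design: %d subjects, %d occasions\n",
              x$n_subjects, length(x$occasions)))
  for (o in x$occasions)
    cat(sprintf("  %s: %s (plasma samples rif/cpi/rsv = %d/%d/%d)\n",
                o$label, paste(o$treatments, collapse = "+"),
                length(o$plasma_times$rif), length(o$plasma_times$cpi),
                length(o$plasma_times$rsv)))
  invisible(x)
}

# compartment coding used in the NONMEM-like long format
.cmt_codes <- c(rif_depot = 1L, rif_plasma = 2L, cpi_plasma = 3L,
                cpi_urine = 4L, rsv_depot = 5L, rsv_plasma = 6L,
                rsv_peripheral = 7L, rsv_urine = 8L)

#' Simulate a complete synthetic crossover trial
#'
#' Draws interindividual random effects once per subject and interoccasion
#' effects per subject-occasion, simulates each subject's rifampicin
#' exposure, drives that subject's CPI and rosuvastatin kinetics with it
#' within the same occasion, and samples observations with the residual
#' error model.  The result replays deterministically under a fixed seed.
#'
#' @param design a [default_design()]-style `trial_design`
#' @param models list with population models `rif`, `cpi`, `rsv`
#'   (see [default_models()])
#' @param seed integer seed for all random draws
#' @param noise sample residual error? (`FALSE` gives noise-free
#'   observations)
#' @param urine_missingness probability that a urine record is flagged
#'   missing (`MDV = 1`), emulating incomplete collections; default 0
#'   (complete data)
#' @return a `data.frame` of class `pk_dataset` with columns `ID`, `OCC`,
#'   `TIME`, `TSTART`, `AMT`, `CMT`, `EVID`, `DV`, `MDV`, `STREAM`.
#'   Concentrations are uM (rifampicin, rosuvastatin) or nM (CPI); urine
#'   amounts nmol (CPI) or umol (rosuvastatin); doses mg.
#' @export
simulate_trial <- function(design = default_design(),
                           models = default_models(), seed,
                           noise = TRUE, urine_missingness = 0) {
  stopifnot(inherits(design, "trial_design"), !missing(seed))
  set.seed(as.integer(seed))
  nocc <- length(design$occasions)
  ns <- design$n_subjects
  re <- list(rif = draw_random_effects(models$rif, ns, nocc),
             cpi = draw_random_effects(models$cpi, ns, nocc),
             rsv = draw_random_effects(models$rsv, ns, nocc))
  kap <- function(cmp, s, k) {
    a <- re[[cmp]]$kappa
    if (dim(a)[2] == 0) return(numeric())
    stats::setNames(a[s, , k], colnames(a))
  }
  maybe_noise <- function(f, stream, err) {
    if (noise) sample_observation(f, stream, err) else f
  }
  rows <- list()
  add_row <- function(df) rows[[length(rows) + 1L]] <<- df
  dt <- 1 / 32
  for (s in seq_len(ns)) {
    for (k in seq_len(nocc)) {
      occ <- design$occasions[[k]]
      rif_on <- "RIF" %in% occ$treatments
      rsv_on <- "RSV" %in% occ$treatments
      rif_profile <- NULL
      if (rif_on) {
        p_rif <- individual_params(models$rif, re$rif$eta[s, ],
                                   kap("rif", s, k))
        p_rif$dose_mg <- unname(design$doses["rif_mg"])
        grid <- seq(0, 24, by = dt)
        rif_profile <- data.frame(
          time = grid,
          conc = as.numeric(cpp_rif_grid(grid, p_rif$ka, p_rif$CL, p_rif$V,
                                         p_rif$MTT, p_rif$n,
                                         dose_umol(p_rif), 0)))
        add_row(data.frame(ID = s, OCC = k, TIME = 0, TSTART = NA_real_,
                           AMT = p_rif$dose_mg, CMT = .cmt_codes[["rif_depot"]],
                           EVID = 1L, DV = NA_real_, MDV = 1L,
                           STREAM = NA_character_))
        tt <- occ$plasma_times$rif
        f <- rif_profile$conc[match(tt, rif_profile$time)]
        add_row(data.frame(ID = s, OCC = k, TIME = tt, TSTART = NA_real_,
                           AMT = NA_real_, CMT = .cmt_codes[["rif_plasma"]],
                           EVID = 0L,
                           DV = maybe_noise(f, "plasma", models$rif$err),
                           MDV = 0L, STREAM = "rif_plasma"))
      }
      # CPI observed on every occasion
      p_cpi <- individual_params(models$cpi, re$cpi$eta[s, ],
                                 kap("cpi", s, k), rif_present = rif_on)
      sim <- simulate_cpi(p_cpi, rif_profile = rif_profile,
                          scenario = ddi_scenario(r = if (rif_on) 1 else 0),
                          times = occ$plasma_times$cpi,
                          urine_intervals = occ$urine_intervals$cpi,
                          rif_present = FALSE,  # V already shifted above
                          engine = "grid", dt = dt)
      add_row(data.frame(ID = s, OCC = k, TIME = sim$plasma$time,
                         TSTART = NA_real_, AMT = NA_real_,
                         CMT = .cmt_codes[["cpi_plasma"]], EVID = 0L,
                         DV = maybe_noise(sim$plasma$conc, "plasma",
                                          models$cpi$err),
                         MDV = 0L, STREAM = "cpi_plasma"))
      umiss <- stats::runif(nrow(sim$urine)) < urine_missingness
      add_row(data.frame(ID = s, OCC = k, TIME = sim$urine$end,
                         TSTART = sim$urine$start, AMT = NA_real_,
                         CMT = .cmt_codes[["cpi_urine"]], EVID = 0L,
                         DV = maybe_noise(sim$urine$amount, "urine",
                                          models$cpi$err),
                         MDV = as.integer(umiss), STREAM = "cpi_urine"))
      if (rsv_on) {
        p_rsv <- individual_params(models$rsv, re$rsv$eta[s, ],
                                   kap("rsv", s, k), rif_present = rif_on)
        p_rsv$dose_mg <- unname(design$doses["rsv_mg"])
        simr <- simulate_rsv(p_rsv, rif_profile = rif_profile,
                             times = occ$plasma_times$rsv,
                             urine_intervals = occ$urine_intervals$rsv,
                             rif_present = FALSE,  # params already shifted
                             engine = "grid", dt = dt)
        add_row(data.frame(ID = s, OCC = k, TIME = 0, TSTART = NA_real_,
                           AMT = p_rsv$dose_mg, CMT = .cmt_codes[["rsv_depot"]],
                           EVID = 1L, DV = NA_real_, MDV = 1L,
                           STREAM = NA_character_))
        add_row(data.frame(ID = s, OCC = k, TIME = simr$plasma$time,
                           TSTART = NA_real_, AMT = NA_real_,
                           CMT = .cmt_codes[["rsv_plasma"]], EVID = 0L,
                           DV = maybe_noise(simr$plasma$conc, "plasma",
                                            models$rsv$err),
                           MDV = 0L, STREAM = "rsv_plasma"))
        umiss <- stats::runif(nrow(simr$urine)) < urine_missingness
        add_row(data.frame(ID = s, OCC = k, TIME = simr$urine$end,
                           TSTART = simr$urine$start, AMT = NA_real_,
                           CMT = .cmt_codes[["rsv_urine"]], EVID = 0L,
                           DV = maybe_noise(simr$urine$amount, "urine",
                                            models$rsv$err),
                           MDV = as.integer(umiss), STREAM = "rsv_urine"))
      }
    }
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  ds <- ds[order(ds$ID, ds$OCC, ds$TIME, ds$CMT, method = "radix"), ]
  rownames(ds) <- NULL
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' Per-subject, per-occasion pre-dose CPI baselines
#'
#' Extracts the pre-dose (`TIME <= 0`) CPI plasma observations from a
#' dataset, for between-occasion variability analysis (see
#' [baseline_stats()]).
#'
#' @param dataset a `pk_dataset`
#' @return data.frame with columns `ID`, `OCC`, `baseline` (nM)
#' @export
occasion_baseline_table <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & !is.na(dataset$STREAM) &
                   dataset$STREAM == "cpi_plasma" & dataset$TIME <= 0, ,
                 drop = FALSE]
  if (nrow(obs) == 0)
    stop("dataset contains no pre-dose CPI plasma rows")
  out <- data.frame(ID = obs$ID, OCC = obs$OCC, baseline = obs$DV)
  full <- expand.grid(ID = unique(dataset$ID),
                      OCC = unique(dataset$OCC[dataset$STREAM %in%
                                                 "cpi_plasma"]))
  miss <- !paste(full$ID, full$OCC) %in% paste(out$ID, out$OCC)
  if (any(miss))
    warning(sum(miss), " subject-occasion(s) lack a pre-dose CPI baseline")
  out[order(out$ID, out$OCC), ]
}
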