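#' Structural parameters for the rifampicin model
#'
#' One-compartment disposition with transit-compartment absorption for a
#' single oral rifampicin (RIF) dose.  Clearance and volume are apparent
#' oral parameters, so bioavailability `F` defaults to 1 and the dose is
#' converted to micromoles internally (plasma concentrations are in uM).
#'
#' @param ka first-order absorption rate constant (1/h)
#' @param CL apparent clearance (L/h)
#' @param V apparent central volume (L)
#' @param MTT mean transit time of the absorption delay (h)
#' @param n number of transit compartments (dimensionless, may be non-integer)
#' @param F bioavailability fraction
#' @param dose_mg oral dose (mg)
#' @param MW molar mass (g/mol) used for the mg to umol conversion
#' @return an object of class `rif_params`
#' @export
rif_params <- function(ka = 2.09, CL = 3.97, V = 24.7, MTT = 0.74, n = 8.63,
                       F = 1, dose_mg = 600, MW = 822.94) {
  stopifnot(ka > 0, CL > 0, V > 0, MTT > 0, n >= 0, F > 0, F <= 1,
            dose_mg >= 0, MW > 0)
  structure(list(ka = ka, CL = CL, V = V, MTT = MTT, n = n, F = F,
                 dose_mg = dose_mg, MW = MW),
            class = "rif_params")
}

#' Structural parameters for the coproporphyrin I turnover model
#'
#' CPI plasma concentration follows a turnover model: zero-order synthesis
#' `ksyn` and first-order loss through biliary (`CLb`, inhibitable by
#' rifampicin) and renal (`CLR`) clearances.  `V_rif` is the volume of
#' distribution when the inhibitor is co-administered (binary covariate);
#' `Ki` is the total (plasma) rifampicin inhibition constant against CPI
#' transport.
#'
#' @param ksyn zero-order synthesis rate (nM/h)
#' @param CLb biliary clearance (L/h)
#' @param CLR renal clearance (L/h)
#' @param V volume of distribution (L)
#' @param V_rif volume of distribution under rifampicin (L)
#' @param Ki total rifampicin inhibition constant (uM)
#' @return an object of class `cpi_params`
#' @export
cpi_params <- function(ksyn = 12.7, CLb = 12.3, CLR = 1.64, V = 6.59,
                       V_rif = 3.4, Ki = 1.15) {
  stopifnot(ksyn > 0, CLb > 0, CLR > 0, V > 0, V_rif > 0, Ki > 0)
  css <- ksyn / (CLb + CLR)
  stopifnot(is.finite(css), css > 0)
  structure(list(ksyn = ksyn, CLb = CLb, CLR = CLR, V = V, V_rif = V_rif,
                 Ki = Ki),
            class = "cpi_params")
}

#' Structural parameters for the rosuvastatin model
#'
#' Two-compartment disposition with first-order absorption; elimination from
#' the central compartment is split into a biliary component (`CLb`,
#' inhibitable by rifampicin) and a renal component (`CLR`).  Distribution
#' parameters take different values when rifampicin is co-administered
#' (`V1_rif`, `V2_rif`, `Q_rif`).
#'
#' @param ka absorption rate constant (1/h)
#' @param CLb biliary clearance (L/h)
#' @param CLR renal clearance (L/h)
#' @param V1,V2 central and peripheral volumes (L)
#' @param Q intercompartmental clearance (L/h)
#' @param V1_rif,V2_rif,Q_rif distribution parameters under rifampicin
#' @param Ki total rifampicin inhibition constant (uM)
#' @param F bioavailability fraction
#' @param dose_mg oral dose (mg)
#' @param MW molar mass (g/mol)
#' @return an object of class `rsv_params`
#' @export
rsv_params <- function(ka = 0.287, CLb = 124, CLR = 8.48, V1 = 430, V2 = 865,
                       Q = 45.3, V1_rif = 2.98, V2_rif = 128, Q_rif = 5.03,
                       Ki = 2.23, F = 1, dose_mg = 5, MW = 481.54) {
  stopifnot(ka > 0, CLb > 0, CLR > 0, V1 > 0, V2 > 0, Q > 0, V1_rif > 0,
            V2_rif > 0, Q_rif > 0, Ki > 0, F > 0, F <= 1, dose_mg >= 0,
            MW > 0)
  structure(list(ka = ka, CLb = CLb, CLR = CLR, V1 = V1, V2 = V2, Q = Q,
                 V1_rif = V1_rif, V2_rif = V2_rif, Q_rif = Q_rif, Ki = Ki,
                 F = F, dose_mg = dose_mg, MW = MW),
            class = "rsv_params")
}

#' Physiological constants
#'
#' @param fu_rif rifampicin unbound fraction in plasma
#' @return a list of constants
#' @export
pk_constants <- function(fu_rif = 0.11) {
  stopifnot(fu_rif > 0, fu_rif <= 1)
  list(fu_rif = fu_rif)
}

#' Dose amount in micromoles
#'
#' @param p a `rif_params` or `rsv_params` object
#' @return `F * dose_mg / MW * 1000` (umol)
#' @export
dose_umol <- function(p) p$F * p$dose_mg / p$MW * 1000

#' Hypothetical-inhibitor scenario
#'
#' `r` scales the inhibitor driving term `C_RIF / Ki` in the biliary
#' clearance of the probe, emulating perpetrators with different potency or
#' exposure relative to rifampicin (`r = 1` is the rifampicin reference,
#' `r = 0` no inhibition).  `rho` additionally applies the same driving
#' term, scaled by `rho`, to the CPI synthesis rate
#' (`ksyn / (1 + rho * C_RIF / Ki)`); `rho = 0` leaves synthesis untouched.
#'
#' @param r inhibition multiplier relative to rifampicin (>= 0)
#' @param rho synthesis-inhibition ratio relative to the biliary effect (>= 0)
#' @return an object of class `ddi_scenario`
#' @export
ddi_scenario <- function(r = 1, rho = 0) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 0,
            is.numeric(rho), length(rho) == 1, rho >= 0)
  structure(list(r = r, rho = rho), class = "ddi_scenario")
}

#' Convert a percent coefficient of variation to a log-normal variance
#'
#' Exponential random-effect models imply log-normally distributed
#' individual parameters; a reported %CV on the natural scale corresponds
#' to variance `log(1 + (cv/100)^2)` on the log scale.
#'
#' @param cv_pct coefficient of variation in percent
#' @return variance of the log-scale random effect
#' @export
cv_to_omega2 <- function(cv_pct) {
  stopifnot(all(cv_pct >= 0))
  log(1 + (cv_pct / 100)^2)
}

#' Convert a log-normal variance to a percent coefficient of variation
#'
#' @param omega2 log-scale variance
#' @return %CV on the natural scale, `100 * sqrt(exp(omega2) - 1)`
#' @export
omega2_to_cv <- function(omega2) {
  stopifnot(all(omega2 >= 0))
  100 * sqrt(exp(omega2) - 1)
}

#' @export
print.rif_params <- function(x, ...) {
  cat("Rifampicin structural parameters (1-cpt, transit absorption)\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.cpi_params <- function(x, ...) {
  cat("Coproporphyrin I turnover-model parameters\n")
  print(unlist(unclass(x)))
  cat(sprintf("baseline Css = %.4g nM\n", x$ksyn / (x$CLb + x$CLR)))
  invisible(x)
}

#' @export
print.rsv_params <- function(x, ...) {
  cat("Rosuvastatin structural parameters (2-cpt, 1st-order absorption)\n")
  print(unlist(unclass(x)))
  invisible(x)
}
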