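#' Random-effects specification
#'
#' Variances of the exponential (log-normal) interindividual (`eta`) and
#' interoccasion (`kappa`) random effects.  Parameters absent from a vector
#' carry no random effect of that kind.
#'
#' @param omega2 named numeric vector of IIV variances (log scale)
#' @param pi2 named numeric vector of IOV variances (log scale)
#' @return an object of class `random_effects_spec`
#' @export
random_effects_spec <- function(omega2 = numeric(), pi2 = numeric()) {
  stopifnot(all(omega2 >= 0), all(pi2 >= 0))
  if (length(omega2)) stopifnot(!is.null(names(omega2)))
  if (length(pi2)) stopifnot(!is.null(names(pi2)))
  structure(list(omega2 = omega2, pi2 = pi2), class = "random_effects_spec")
}

#' Residual-error specification
#'
#' Combined proportional + additive residual error per observation stream.
#' Each stream is a numeric vector `c(prop = ..., add = ...)`; the additive
#' standard deviation is in the units of the stream.
#'
#' @param ... named streams, e.g. `plasma = c(prop = 0.139, add = 0.001)`
#' @return an object of class `residual_error_spec`
#' @export
residual_error_spec <- function(...) {
  streams <- list(...)
  stopifnot(length(streams) > 0, !is.null(names(streams)))
  for (s in streams) {
    stopifnot(all(c("prop", "add") %in% names(s)), all(s >= 0), sum(s) > 0)
  }
  structure(streams, class = "residual_error_spec")
}

#' Population model
#'
#' Bundles the structural fixed effects, the random-effects specification
#' and the residual-error specification for one compound.  Covariate shifts
#' (rifampicin-condition volumes/clearances) live inside the structural
#' parameter object and are switched on by `rif_present` in
#' [individual_params()].
#'
#' @param fixed a `rif_params`, `cpi_params` or `rsv_params` object
#' @param re a [random_effects_spec()]
#' @param err a [residual_error_spec()]
#' @return an object of class `population_model`
#' @export
population_model <- function(fixed, re, err) {
  stopifnot(inherits(fixed, c("rif_params", "cpi_params", "rsv_params")),
            inherits(re, "random_effects_spec"),
            inherits(err, "residual_error_spec"))
  compound <- switch(class(fixed)[1],
                     rif_params = "rif", cpi_params = "cpi",
                     rsv_params = "rsv")
  structure(list(fixed = fixed, re = re, err = err, compound = compound),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population PK model: %s\n", x$compound))
  print(x$fixed)
  cat("IIV %CV:", paste(names(x$re$omega2),
                        sprintf("%.1f", omega2_to_cv(x$re$omega2)),
                        collapse = ", "), "\n")
  if (length(x$re$pi2))
    cat("IOV %CV:", paste(names(x$re$pi2),
                          sprintf("%.1f", omega2_to_cv(x$re$pi2)),
                          collapse = ", "), "\n")
  invisible(x)
}

# parameters of each compound that carry random effects, in canonical order
re_param_names <- function(compound) {
  switch(compound,
         rif = list(eta = c("ka", "CL", "V", "MTT", "n"),
                    kappa = c("ka", "V", "MTT")),
         cpi = list(eta = c("ksyn", "CLb", "CLR", "V", "Ki"),
                    kappa = c("ksyn", "CLb")),
         rsv = list(eta = c("ka", "CLR", "CLb", "V1", "Q", "Ki"),
                    kappa = "ka"))
}

#' Map population parameters and random effects to individual parameters
#'
#' Applies the exponential random-effect model `theta_ik = theta *
#' exp(eta_i + kappa_ik)` and then the binary rifampicin-condition covariate
#' (volume / distribution shifts) when `rif_present` is `TRUE`.
#'
#' @param pop a [population_model()]
#' @param eta named vector of interindividual random effects (log scale);
#'   missing names default to 0
#' @param kappa named vector of interoccasion random effects for the
#'   occasion being evaluated; missing names default to 0
#' @param rif_present logical; apply the rifampicin-condition covariate?
#' @return a structural parameter object of the same class as `pop$fixed`
#' @export
individual_params <- function(pop, eta = numeric(), kappa = numeric(),
                              rif_present = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  if (length(eta) && is.null(names(eta)))
    stop("eta must be a named vector")
  if (length(kappa) && is.null(names(kappa)))
    stop("kappa must be a named vector")
  known <- re_param_names(pop$compound)
  if (!all(names(eta) %in% known$eta))
    stop("unknown eta name(s): ",
         paste(setdiff(names(eta), known$eta), collapse = ", "))
  if (!all(names(kappa) %in% known$kappa))
    stop("unknown kappa name(s): ",
         paste(setdiff(names(kappa), known$kappa), collapse = ", "))
  p <- unclass(pop$fixed)
  fac <- function(nm) {
    e <- if (nm %in% names(eta)) eta[[nm]] else 0
    k <- if (nm %in% names(kappa)) kappa[[nm]] else 0
    exp(e + k)
  }
  out <- p
  for (nm in union(known$eta, known$kappa)) out[[nm]] <- p[[nm]] * fac(nm)
  if (pop$compound == "cpi") {
    if (rif_present) out$V <- p$V_rif * fac("V")
    out$V_rif <- p$V_rif * fac("V")
  } else if (pop$compound == "rsv") {
    if (rif_present) {
      out$V1 <- p$V1_rif * fac("V1")
      out$Q <- p$Q_rif * fac("Q")
      out$V2 <- p$V2_rif
    }
    out$V1_rif <- p$V1_rif * fac("V1")
    out$Q_rif <- p$Q_rif * fac("Q")
  }
  class(out) <- class(pop$fixed)
  out
}

#' Prediction and residual variance for an observation
#'
#' Under the combined error model the observation variance is
#' `sigma_prop^2 * f^2 + sigma_add^2` for model prediction `f`.
#'
#' @param f model prediction(s), non-negative
#' @param stream stream name in `err`
#' @param err a [residual_error_spec()]
#' @return list with `prediction` and `variance`
#' @export
predict_observation <- function(f, stream, err) {
  stopifnot(inherits(err, "residual_error_spec"), stream %in% names(err),
            all(f >= 0))
  s <- err[[stream]]
  list(prediction = f, variance = s[["prop"]]^2 * f^2 + s[["add"]]^2)
}

#' Sample noisy observations from the residual-error model
#'
#' `y = f * (1 + eps_prop) + eps_add` with independent centred Gaussian
#' errors.  Negative draws are retained by default (the additive component
#' permits them); an optional lower limit of quantification censors values
#' below `lloq` to `NA`.
#'
#' @param f model prediction(s)
#' @param stream stream name in `err`
#' @param err a [residual_error_spec()]
#' @param lloq optional lower limit of quantification; values below are `NA`
#' @return numeric vector of simulated observations
#' @export
sample_observation <- function(f, stream, err, lloq = NULL) {
  stopifnot(inherits(err, "residual_error_spec"), stream %in% names(err))
  s <- err[[stream]]
  n <- length(f)
  y <- f * (1 + stats::rnorm(n, 0, s[["prop"]])) + stats::rnorm(n, 0, s[["add"]])
  if (!is.null(lloq)) y[y < lloq] <- NA_real_
  y
}

#' Draw population random effects
#'
#' Interindividual effects `eta` are drawn once per subject; interoccasion
#' effects `kappa` independently per subject and occasion.
#'
#' @param pop a [population_model()]
#' @param n_subjects number of subjects
#' @param n_occasions number of occasions
#' @return list with `eta` (matrix subjects x parameters) and `kappa`
#'   (array subjects x parameters x occasions)
#' @export
draw_random_effects <- function(pop, n_subjects, n_occasions = 1) {
  stopifnot(inherits(pop, "population_model"), n_subjects >= 1,
            n_occasions >= 1)
  om <- pop$re$omega2
  pi2 <- pop$re$pi2
  eta <- matrix(stats::rnorm(n_subjects * length(om), 0,
                             rep(sqrt(om), each = n_subjects)),
                nrow = n_subjects, dimnames = list(NULL, names(om)))
  kappa <- array(stats::rnorm(n_subjects * length(pi2) * n_occasions, 0,
                              rep(sqrt(pi2), each = n_subjects)),
                 dim = c(n_subjects, length(pi2), n_occasions),
                 dimnames = list(NULL, names(pi2), NULL))
  list(eta = eta, kappa = kappa)
}

#' Load the packaged population-PK parameterisation
#'
#' Reads a YAML parameter file in the packaged layout (fixed effects,
#' IIV/IOV %CV, residual errors per stream) and builds the three
#' [population_model()] objects.  %CV values are converted to log-scale
#' variances with [cv_to_omega2()].
#'
#' @param path path to a YAML parameter file; default is the packaged
#'   estimate set
#' @return list with elements `rif`, `cpi`, `rsv` (population models) and
#'   `constants`
#' @export
load_parameters <- function(path = system.file("extdata",
                                               "poppk_parameters.yaml",
                                               package = "copropk")) {
  y <- yaml::read_yaml(path)
  req <- c("rifampicin", "cpi", "rosuvastatin")
  if (!all(req %in% names(y)))
    stop("parameter file must contain blocks: ", paste(req, collapse = ", "))
  as_named <- function(x) unlist(x)
  mk_re <- function(b) {
    random_effects_spec(omega2 = cv_to_omega2(as_named(b$iiv_cv)),
                        pi2 = cv_to_omega2(as_named(b$iov_cv)))
  }
  mk_err <- function(b) {
    do.call(residual_error_spec,
            lapply(b$error, function(s) c(prop = s$prop, add = s$add)))
  }
  rb <- y$rifampicin
  rif <- population_model(
    do.call(rif_params, c(rb$fixed, list(dose_mg = rb$dose_mg, MW = rb$MW))),
    mk_re(rb), mk_err(rb))
  cb <- y$cpi
  cpi <- population_model(do.call(cpi_params, cb$fixed), mk_re(cb), mk_err(cb))
  sb <- y$rosuvastatin
  rsv <- population_model(
    do.call(rsv_params, c(sb$fixed, list(dose_mg = sb$dose_mg, MW = sb$MW))),
    mk_re(sb), mk_err(sb))
  list(rif = rif, cpi = cpi, rsv = rsv,
       constants = pk_constants(fu_rif = y$constants$fu_rif))
}

#' Default population models at the packaged estimates
#'
#' @return list as in [load_parameters()]
#' @export
default_models <- function() load_parameters()
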