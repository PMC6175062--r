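#' Linear trapezoid area under the curve
#'
#' AUC on the observed grid over a requested window; no extrapolation
#' beyond the observed range is performed (the window must lie inside it).
#' Window bounds falling between grid points are handled by linear
#' interpolation.
#'
#' @param times strictly increasing sampling times (h)
#' @param values concentrations at `times`
#' @param window `c(start, end)` (h), a subset of the observed range
#' @return object of class `auc_result`: list with `auc`, `window`,
#'   `method`
#' @export
auc_trapezoid <- function(times, values, window = range(times)) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  stopifnot(length(times) == length(values), length(window) == 2,
            window[1] < window[2])
  if (window[1] < min(times) || window[2] > max(times))
    stop("window [", window[1], ", ", window[2],
         "] outside observed range [", min(times), ", ", max(times), "]")
  tt <- sort(unique(c(times, window)))
  vv <- stats::approx(times, values, xout = tt)$y
  keep <- tt >= window[1] & tt <= window[2]
  tt <- tt[keep]
  vv <- vv[keep]
  auc <- sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
  structure(list(auc = auc, window = window, method = "linear-trapezoid"),
            class = "auc_result")
}

#' Fraction of elimination attributable to the inhibited transporter
#'
#' `fT = 1 - AUC(control) / AUC(+inhibitor)`: the share of a probe's
#' elimination mediated by the pathway the inhibitor blocks.
#'
#' @param auc_control AUC without inhibitor (> 0)
#' @param auc_inhibited AUC with inhibitor (> 0)
#' @return fT (dimensionless, < 1)
#' @export
compute_ft <- function(auc_control, auc_inhibited) {
  if (is.list(auc_control)) auc_control <- auc_control$auc
  if (is.list(auc_inhibited)) auc_inhibited <- auc_inhibited$auc
  stopifnot(all(auc_control > 0), all(auc_inhibited > 0))
  1 - auc_control / auc_inhibited
}

#' Baseline variability statistics across occasions
#'
#' Between-subject %CV of the occasion-pooled per-subject mean baselines,
#' per-occasion means, and a one-way ANOVA of baseline against occasion.
#'
#' @param baseline_table data.frame with columns `ID`, `OCC`, `baseline`
#'   (see [occasion_baseline_table()])
#' @return list with `between_subject_cv` (%), `occasion_means`,
#'   `anova_F`, `anova_p`
#' @export
baseline_stats <- function(baseline_table) {
  stopifnot(all(c("ID", "OCC", "baseline") %in% names(baseline_table)))
  bt <- baseline_table[!is.na(baseline_table$baseline), ]
  if (length(unique(bt$OCC)) < 2 || length(unique(bt$ID)) < 2)
    stop("need at least 2 occasions and 2 subjects")
  subj_means <- tapply(bt$baseline, bt$ID, mean)
  cv <- stats::sd(subj_means) / mean(subj_means) * 100
  occ_means <- tapply(bt$baseline, bt$OCC, mean)
  if (stats::var(bt$baseline) <= .Machine$double.eps * mean(bt$baseline)^2) {
    # degenerate table: no variation at all, hence no occasion effect
    Fv <- 0
    pv <- 1
  } else {
    fit <- stats::lm(baseline ~ factor(OCC), data = bt)
    an <- stats::anova(fit)
    Fv <- an$`F value`[1]
    pv <- an$`Pr(>F)`[1]
    if (an$`Sum Sq`[1] <= .Machine$double.eps * sum(an$`Sum Sq`) ||
        !is.finite(Fv)) {
      Fv <- 0
      pv <- 1
    }
  }
  list(between_subject_cv = cv,
       occasion_means = occ_means,
       anova_F = Fv,
       anova_p = pv)
}
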