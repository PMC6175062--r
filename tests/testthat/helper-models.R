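# shared fixtures: the packaged population models and variants used in
# several files

models_tab1 <- default_models()

# zero-variability variant (typical-value simulation)
models_novar <- local({
  m <- models_tab1
  for (cmp in c("rif", "cpi", "rsv")) {
    m[[cmp]]$re$omega2[] <- 0
    m[[cmp]]$re$pi2[] <- 0
  }
  m
})

# generic perturbed starting values for parameter-recovery fits (well away
# from the generating values, same for every seed)
perturbed_models <- function(m = models_tab1) {
  m$rif$fixed$ka <- 1.5
  m$rif$fixed$CL <- 6
  m$rif$fixed$V <- 35
  m$rif$fixed$MTT <- 1.2
  m$rif$fixed$n <- 5
  m$cpi$fixed$ksyn <- 20
  m$cpi$fixed$CLb <- 8
  m$cpi$fixed$CLR <- 2.5
  m$cpi$fixed$V <- 10
  m$cpi$fixed$V_rif <- 6
  m$cpi$fixed$Ki <- 2.5
  m
}

# brute-force one-way ANOVA from sums of squares (independent oracle)
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 1))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  dfb <- length(g) - 1
  dfw <- length(values) - length(g)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# adaptive-quadrature marginal -2 log-likelihood oracle for a model with a
# single Gaussian random effect
quadrature_nll_1d <- function(y, predict_fn, omega2, sigma) {
  dens <- function(eta) {
    vapply(eta, function(e) {
      f <- predict_fn(e)
      v <- sigma[1]^2 * f^2 + sigma[2]^2
      exp(sum(stats::dnorm(y, f, sqrt(v), log = TRUE)) +
            stats::dnorm(e, 0, sqrt(omega2), log = TRUE))
    }, 1)
  }
  -2 * log(stats::integrate(dens, -8 * sqrt(omega2), 8 * sqrt(omega2),
                            rel.tol = 1e-10)$value)
}
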