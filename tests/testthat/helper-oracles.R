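## Independent oracles, deliberately written without reusing package internals.

## Exhaustive sign-flip reference for the single-point cluster test: enumerate
## all 2^n sign assignments of the paired differences, apply the same
## threshold-then-extremal-statistic rule, and count how often the extremal
## statistic is at least as extreme as the observed one.
oracle_exhaustive_signflip_p <- function(d, cluster_alpha = 0.05) {
  n <- length(d)
  stopifnot(n <= 12)
  tstat <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))
  t_crit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  t_obs <- tstat(d)
  e_obs <- if (is.finite(t_obs) && abs(t_obs) > t_crit) t_obs else 0
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ex <- apply(signs, 1, function(s) {
    t <- tstat(s * d)
    if (is.finite(t) && abs(t) > t_crit) t else 0
  })
  mean(abs(ex) >= abs(e_obs))
}

## Mean of the unit MMN Gaussian over the measurement window samples
## (quadrature on the sample grid; the injected window-mean ground truth).
oracle_gauss_window_mean <- function(time_ms, window = c(200, 240),
                                     lat = 220, sigma = 30) {
  win <- time_ms >= window[1] & time_ms <= window[2]
  mean(exp(-0.5 * ((time_ms[win] - lat) / sigma)^2))
}

## Independent JZS Bayes factor via the noncentral-t marginal likelihood:
## BF10 = integral over delta of dt(t; df, delta * sqrt(n)) Cauchy(delta)
##        divided by dt(t; df, 0).
oracle_bf_noncentral_t <- function(t, n, scale = 0.707) {
  ## R's noncentral-t density warns about its own precision (~1e-8), far
  ## below the tolerance this oracle backs
  num <- stats::integrate(function(delta) {
    suppressWarnings(stats::dt(t, df = n - 1, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, scale)
  }, lower = -Inf, upper = Inf, rel.tol = 1e-9)$value
  num / stats::dt(t, df = n - 1)
}
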