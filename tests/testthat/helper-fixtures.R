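# Shared fixtures, all built in code.

# Small cohort -> analysis frame, for tests that only need plumbing.
small_frame <- function(seed = 1, n_per_group = 12, ...) {
  analysis_frame(generate_cohort(cohort_config(
    n_per_group = n_per_group, seed = seed, ...)))
}

# A random single-focal moderation fit on synthetic raw data (not via the
# cohort generator), for the JN / sandwich / diagnostics oracles.
random_fit <- function(seed, n = 40, b1 = NULL, b3 = NULL, hetero = TRUE) {
  set.seed(seed)
  b1 <- b1 %||% stats::rnorm(1, 0, 0.3)
  b3 <- b3 %||% stats::rnorm(1, 0, 0.3)
  m <- stats::runif(n, 80, 300)             # age-like moderator, months
  x <- stats::rnorm(n)
  zm <- (m - mean(m)) / stats::sd(m)
  sdl <- if (hetero) 0.5 * (1 + 0.8 * abs(zm)) else 0.5
  y <- b1 * x + 0.4 * zm + b3 * x * zm + stats::rnorm(n, 0, sdl)
  d <- data.frame(y = y, x = x, m = m)
  fit_moderation(d, model_spec("y", "x", "m", label = paste0("random", seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force grid scan of the conditional-effect p-value over the observed
# moderator range; returns the months at which |t| crosses the critical
# value (midpoint of the bracketing step).
grid_jn_roots <- function(fit, alpha = 0.05, vcov = "HC0", step = 0.001) {
  rng <- fit$moderator_stats$range
  ms <- seq(rng[1], rng[2], by = step)
  ce <- conditional_effect(fit, ms, vcov = vcov)
  f <- abs(ce$t) - stats::qt(1 - alpha / 2, fit$df_residual)
  i <- which(f[-1] * f[-length(f)] < 0)
  (ms[i] + ms[i + 1]) / 2
}

# QC fixture: one age-group x region x metabolite cell of 20 records with a
# symmetric pair of planted concentration outliers (+/-35 around a mean of
# 100; single-pass 3-SD threshold is 3 * sqrt((2*35^2 + 18*0.2^2)/19) =
# 34.07 < 35, so exactly those two are beyond it) and one CRLB = 60 record.
qc_fixture <- function() {
  conc <- c(rep(c(99.8, 100.2), 9), 135, 65)
  data.frame(
    id = sprintf("Q%02d", 1:20),
    age_group = "10y", region = "IPS", metabolite = "Glutamate",
    timepoint = 1,
    absolute_concentration = conc,
    crlb_percent = c(60, rep(5, 19)),
    snr = rep(c(39, 41), 10),
    stringsAsFactors = FALSE
  )
}
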