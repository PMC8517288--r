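# Shared fixtures: in-memory series builders and small synthetic
# participants used across test files.

wrap_2pi <- function(theta) theta %% (2 * pi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# von Mises draws for building test data (not used as an oracle).
sample_von_mises_for_test <- function(n, mu, kappa) {
  hrcycles:::sample_von_mises(n, mu, kappa)
}

# Wrap a numeric vector as a standardised 5-minute hr_series.
series_from_values <- function(x, standardise = TRUE, id = "TEST") {
  if (standardise) x <- (x - mean(x)) / stats::sd(x)
  structure(list(
    participant_id = id,
    start_time = as.POSIXct("2020-01-01", tz = "UTC"),
    step_s = 300L,
    values = as.numeric(x),
    observed = rep(TRUE, length(x)),
    interp = rep("observed", length(x)),
    standardised = standardise
  ), class = "hr_series")
}

# Sinusoid (+ optional white noise) sampled on the 5-minute grid.
tone_series <- function(period_hours, days, amplitude = 1, noise_sd = 0,
                        seed = 1) {
  n <- days * 288
  t_h <- (0:(n - 1)) / 12
  x <- 0
  for (k in seq_along(period_hours)) {
    x <- x + amplitude[min(k, length(amplitude))] *
      sin(2 * pi * t_h / period_hours[k])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  series_from_values(x)
}

# Cheap raw stream already on the 5-minute grid (no 5-second generation).
coarse_config <- function(..., sample_interval_s = 300) {
  synthetic_config(..., sample_interval_s = sample_interval_s)
}

# TRUE if every target period has a detected peak within rel_tol.
all_periods_recovered <- function(cycle_set, target_hours, rel_tol = 0.10) {
  p <- cycle_set$peaks$period_hours
  all(vapply(target_hours,
             function(th) any(abs(p - th) / th <= rel_tol), logical(1)))
}

# Brute-force Hodges-Ajne statistic: rotate a closed half-circle over a
# fine direction grid plus all data angles and antipodes.
hodges_ajne_m_bruteforce <- function(phases, grid_n = 2048) {
  dirs <- c(seq(0, 2 * pi, length.out = grid_n), phases, phases - pi)
  counts <- vapply(dirs, function(a) {
    sum(((phases - a) %% (2 * pi)) <= pi + 1e-12)
  }, numeric(1))
  as.integer(length(phases) - max(counts))
}
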