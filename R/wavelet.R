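# Continuous Morlet wavelet analysis of the standardised 5-minute
# heart-rate series: global (time-averaged) wavelet power on log-spaced
# scales, a chi-square time-averaged significance test against a fitted
# AR(1) red-noise (or white-noise) background, cone-of-influence
# restriction of admissible periods, peak detection, the band-overlap
# sparsity criterion, and cycle-class labelling.

COI_MIN_HOURS <- 2.4
MORLET_GAMMA <- 2.32 # decorrelation factor for time-averaged dof (Morlet)

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Global Morlet wavelet power spectrum of a heart-rate series
#'
#' Computes the continuous wavelet transform (Morlet, centre frequency
#' `omega0 = 6`) on log-spaced scales spanning admissible periods from
#' 2.4 hours to one quarter of the recording length (so at least four full
#' cycles of every admissible period are observed), then averages squared
#' transform magnitude over time at each scale, excluding points inside
#' the cone of influence. A per-period 99% significance threshold against
#' the fitted noise background is attached (see
#' [significance_threshold()]).
#'
#' @param series A standardised, gap-filled `hr_series`.
#' @param voices_per_octave Scale resolution (default 16: period
#'   quantisation error about 2-4%, well inside the +/-10% recovery
#'   tolerance used in testing).
#' @param omega0 Morlet centre frequency (default 6).
#' @param background Noise model for the significance test:
#'   `"red-noise"` fits the series' lag-1 autocorrelation (heart rate is
#'   strongly autocorrelated); `"white"` forces a flat background.
#' @param sig_level Significance level for the attached threshold
#'   (default 0.99).
#' @return A `wavelet_spectrum` object: `period_hours`, `power`
#'   (global wavelet power per period), `signif` (threshold per period),
#'   `dof`, `n_outside_coi`, `lag1`, `background`, `sig_level`,
#'   `coi_min_hours`, `coi_max_hours`, `dt_hours`, `n`, `omega0`,
#'   `voices_per_octave`, `variance`.
#' @export
compute_global_wavelet_power <- function(series, voices_per_octave = 16,
                                         omega0 = 6,
                                         background = c("red-noise", "white"),
                                         sig_level = 0.99) {
  stopifnot(inherits(series, "hr_series"))
  background <- match.arg(background)
  x <- series$values
  if (anyNA(x)) stop("series must be gap-filled before wavelet analysis",
                     call. = FALSE)
  n <- length(x)
  dt <- series$step_s / 3600 # hours
  span_h <- n * dt
  coi_max <- span_h / 4
  if (coi_max <= COI_MIN_HOURS) {
    stop(sprintf(
      "recording too short: %.1f h cannot host any period in [%.1f h, span/4]",
      span_h, COI_MIN_HOURS), call. = FALSE)
  }
  xvar <- stats::var(x)
  x0 <- x - mean(x)

  ff <- morlet_fourier_factor(omega0)
  s0 <- COI_MIN_HOURS / ff
  smax <- coi_max / ff
  jj <- 0:floor(voices_per_octave * log2(smax / s0))
  scales <- s0 * 2^(jj / voices_per_octave)
  periods <- scales * ff

  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x0, rep(0, npad - n)))
  wk <- 2 * pi * seq(0, npad / 2) / (npad * dt)

  power_mean <- numeric(length(scales))
  n_out <- integer(length(scales))
  i_time <- seq_len(n)
  edge_dist <- pmin(i_time - 1, n - i_time) * dt
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    pos <- seq(2, npad / 2 + 1)
    psi[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * wk[pos] - omega0)^2) / 2)
    w <- stats::fft(xf * psi, inverse = TRUE)[i_time] / npad
    pw <- Re(w)^2 + Im(w)^2
    outside <- edge_dist >= sqrt(2) * s
    n_out[j] <- sum(outside)
    power_mean[j] <- if (n_out[j] > 0) mean(pw[outside]) else NA_real_
  }
  keep <- n_out > 0
  spec <- structure(list(
    period_hours = periods[keep],
    scale = scales[keep],
    power = power_mean[keep],
    n_outside_coi = n_out[keep],
    lag1 = if (background == "red-noise") {
      as.numeric(stats::acf(x0, lag.max = 1, plot = FALSE)$acf[2])
    } else {
      0
    },
    background = background,
    coi_min_hours = COI_MIN_HOURS,
    coi_max_hours = coi_max,
    dt_hours = dt,
    n = n,
    omega0 = omega0,
    voices_per_octave = voices_per_octave,
    variance = xvar,
    participant_id = series$participant_id
  ), class = "wavelet_spectrum")
  thr <- significance_threshold(spec, level = sig_level)
  spec$signif <- thr$threshold
  spec$dof <- thr$dof
  spec$sig_level <- sig_level
  spec
}

#' Time-averaged significance threshold for global wavelet power
#'
#' The null model is an AR(1) (red-noise) or white-noise process with the
#' series' variance; its theoretical Fourier spectrum at each scale's
#' equivalent period forms the background. Time-averaging over the points
#' outside the cone of influence multiplies the chi-square degrees of
#' freedom according to the standard global-spectrum correction
#' `dof = 2 * sqrt(1 + (n_a * dt / (gamma * scale))^2)` with
#' `gamma = 2.32` for the Morlet wavelet; the threshold at each period is
#' `variance * background * qchisq(level, dof) / dof`.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param level Significance level in (0, 1), default 0.99.
#' @return List: `threshold` (per period), `dof` (per period),
#'   `background_spectrum` (per period).
#' @export
significance_threshold <- function(spectrum, level = 0.99) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  if (!is_scalar_num(level) || level <= 0 || level >= 1) {
    stop("significance level must lie in (0, 1)", call. = FALSE)
  }
  a <- spectrum$lag1
  freq_rad <- 2 * pi * spectrum$dt_hours / spectrum$period_hours
  bg <- (1 - a^2) / (1 + a^2 - 2 * a * cos(freq_rad))
  na <- spectrum$n_outside_coi
  dof <- 2 * sqrt(1 + (na * spectrum$dt_hours /
                       (MORLET_GAMMA * spectrum$scale))^2)
  threshold <- spectrum$variance * bg * stats::qchisq(level, dof) / dof
  list(threshold = threshold, dof = dof, background_spectrum = bg)
}

#' Classify a cycle period
#'
#' Periods within 10% of 24 hours are labelled circadian, shorter periods
#' ultradian and longer periods multiday. Multiday periods of 5-9 days
#' carry the additional sub-label about-weekly; 28-32 days about-monthly.
#'
#' @param period_hours Numeric vector of periods in hours.
#' @param circadian_tol Half-width of the circadian band as a fraction of
#'   24 h (default 0.10, i.e. 21.6-26.4 h).
#' @return data.frame with columns `period_hours`, `class`
#'   (`ultradian` / `circadian` / `multiday`) and `subclass`
#'   (`about-weekly`, `about-monthly` or NA).
#' @export
classify_period <- function(period_hours, circadian_tol = 0.10) {
  lo <- 24 * (1 - circadian_tol)
  hi <- 24 * (1 + circadian_tol)
  cls <- ifelse(period_hours < lo, "ultradian",
                ifelse(period_hours <= hi, "circadian", "multiday"))
  sub <- rep(NA_character_, length(period_hours))
  days <- period_hours / 24
  sub[cls == "multiday" & days >= 5 & days <= 9] <- "about-weekly"
  sub[cls == "multiday" & days >= 28 & days <= 32] <- "about-monthly"
  data.frame(period_hours = period_hours, class = cls, subclass = sub,
             stringsAsFactors = FALSE)
}

#' Detect significant peaks in the global wavelet power
#'
#' Returns every strict local maximum of the global power that exceeds the
#' significance threshold and lies within the admissible period range
#' (cone of influence). Plateau ties are broken toward the longer period.
#' Peaks are annotated with their +/-33.3% pass band (see
#' [design_band()]) and cycle class; overlapping peaks are thinned later
#' by [apply_sparsity_criterion()].
#'
#' @param spectrum A `wavelet_spectrum` with a significance threshold.
#' @return data.frame (possibly empty): `period_hours`, `power`,
#'   `band_low_hours`, `band_high_hours`, `class`, `subclass`.
#' @export
detect_peaks <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  p <- spectrum$power
  m <- length(p)
  idx <- integer(0)
  if (m >= 3) {
    i <- 2L
    while (i <= m - 1) {
      if (p[i] > p[i - 1]) {
        j <- i
        while (j < m && p[j + 1] == p[j]) j <- j + 1L # plateau: take longest
        if (j < m && p[j + 1] < p[j]) idx <- c(idx, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  idx <- idx[p[idx] > spectrum$signif[idx]]
  periods <- spectrum$period_hours[idx]
  keep <- periods >= spectrum$coi_min_hours & periods <= spectrum$coi_max_hours
  idx <- idx[keep]
  periods <- periods[keep]
  cls <- classify_period(periods)
  data.frame(period_hours = periods,
             power = spectrum$power[idx],
             band_low_hours = 2 * periods / 3,
             band_high_hours = 4 * periods / 3,
             class = cls$class,
             subclass = cls$subclass,
             stringsAsFactors = FALSE)
}

#' Thin overlapping peaks with the band-sparsity criterion
#'
#' Physiological cycles drift, so one underlying rhythm can produce
#' several closely spaced spectral maxima. The criterion keeps only the
#' strongest peak within any retained cycle's pass band: greedily take the
#' highest-power remaining peak (ties broken toward the longer period) and
#' discard all remaining peaks whose period lies strictly inside its
#' +/-33.3% band.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param spectrum Optional `wavelet_spectrum` (carries participant id and
#'   recording length onto the result).
#' @return A `cycle_set` object: `participant_id`, `peaks` (data.frame
#'   sorted by period), `recording_days`.
#' @export
apply_sparsity_criterion <- function(peaks, spectrum = NULL) {
  kept <- peaks[0, , drop = FALSE]
  remaining <- peaks
  while (nrow(remaining) > 0) {
    ord <- order(-remaining$power, -remaining$period_hours)
    best <- remaining[ord[1], , drop = FALSE]
    kept <- rbind(kept, best)
    inside <- remaining$period_hours > best$band_low_hours &
      remaining$period_hours < best$band_high_hours
    inside[ord[1]] <- TRUE
    remaining <- remaining[!inside, , drop = FALSE]
  }
  kept <- kept[order(kept$period_hours), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(
    participant_id = spectrum$participant_id %||% NA_character_,
    peaks = kept,
    recording_days = if (!is.null(spectrum)) {
      spectrum$n * spectrum$dt_hours / 24
    } else {
      NA_real_
    }
  ), class = "cycle_set")
}

#' Detect significant heart-rate cycles in one step
#'
#' Convenience wrapper: global wavelet power, significance threshold,
#' peak detection and the sparsity criterion.
#'
#' @param series A standardised, gap-filled `hr_series`.
#' @inheritParams compute_global_wavelet_power
#' @return A `cycle_set` (see [apply_sparsity_criterion()]); the spectrum
#'   is attached as attribute `"spectrum"`.
#' @export
detect_cycles <- function(series, voices_per_octave = 16, omega0 = 6,
                          background = c("red-noise", "white"),
                          sig_level = 0.99) {
  spectrum <- compute_global_wavelet_power(
    series, voices_per_octave = voices_per_octave, omega0 = omega0,
    background = background, sig_level = sig_level)
  out <- apply_sparsity_criterion(detect_peaks(spectrum), spectrum)
  attr(out, "spectrum") <- spectrum
  out
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %s: %d significant cycle(s) in %.1f days\n",
              x$participant_id, nrow(x$peaks), x$recording_days))
  if (nrow(x$peaks) > 0) {
    print(transform(x$peaks, period_days = period_hours / 24))
  }
  invisible(x)
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrum> %s: %d periods in [%.1f h, %.1f d], background %s (lag1 %.3f)\n",
    x$participant_id, length(x$period_hours), min(x$period_hours),
    max(x$period_hours) / 24, x$background, x$lag1))
  invisible(x)
}
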