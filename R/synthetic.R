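# Synthetic wearable heart-rate generator: sinusoidal circadian/multiday
# cycles with optional phase drift, AR(1) measurement noise, device-like
# recording gaps, and seizure-like events phase-locked to a chosen cycle.
# Ground truth is returned alongside the stream so that every downstream
# stage (resampling, wavelet detection, band-pass phase, phase-locking)
# can be tested for parameter recovery without any external data.

#' Specify one implanted heart-rate cycle
#'
#' @param period_hours Cycle period in hours (> 0).
#' @param amplitude Peak amplitude in BPM (>= 0).
#' @param initial_phase Phase at the start of the recording, radians in
#'   `[0, 2*pi)`.
#' @param phase_drift_sd Standard deviation of the Gaussian random phase
#'   wander accumulated over one full cycle, in radians. 0 gives a pure
#'   sinusoid; small positive values emulate the period instability that
#'   motivates band-pass extraction with wide (+/- 33.3%) cut-offs.
#' @return A `cycle_spec` list.
#' @export
cycle_spec <- function(period_hours, amplitude, initial_phase = 0,
                       phase_drift_sd = 0) {
  if (!is_scalar_num(period_hours) || period_hours <= 0) {
    stop_config("period_hours", "must be a positive number")
  }
  if (!is_scalar_num(amplitude) || amplitude < 0) {
    stop_config("amplitude", "must be a non-negative number")
  }
  if (!is_scalar_num(initial_phase) || initial_phase < 0 ||
      initial_phase >= 2 * pi) {
    stop_config("initial_phase", "must lie in [0, 2*pi)")
  }
  if (!is_scalar_num(phase_drift_sd) || phase_drift_sd < 0) {
    stop_config("phase_drift_sd", "must be a non-negative number")
  }
  structure(list(period_hours = period_hours, amplitude = amplitude,
                 initial_phase = initial_phase,
                 phase_drift_sd = phase_drift_sd),
            class = "cycle_spec")
}

#' Specify device-like missing segments
#'
#' Gap lengths observed with consumer wearables span several orders of
#' magnitude (from minutes while charging to weeks of non-wear), so the
#' default length model is uniform on the log scale.
#'
#' @param n_gaps Number of gaps to remove.
#' @param min_hours,max_hours Gap-length bounds in hours.
#' @param distribution `"uniform-log"` draws lengths log-uniformly in
#'   `[min_hours, max_hours]`; `"fixed"` uses `max_hours` for every gap.
#' @return A `gap_spec` list.
#' @export
gap_spec <- function(n_gaps, min_hours = 0.1, max_hours = 48,
                     distribution = c("uniform-log", "fixed")) {
  distribution <- match.arg(distribution)
  if (!is_scalar_num(n_gaps) || n_gaps < 0 || n_gaps != round(n_gaps)) {
    stop_config("n_gaps", "must be a non-negative integer")
  }
  if (!is_scalar_num(min_hours) || !is_scalar_num(max_hours) ||
      min_hours < 0 || min_hours > max_hours) {
    stop_config("min_hours/max_hours", "need 0 <= min_hours <= max_hours")
  }
  structure(list(n_gaps = as.integer(n_gaps), min_hours = min_hours,
                 max_hours = max_hours, distribution = distribution),
            class = "gap_spec")
}

#' Configure a synthetic participant
#'
#' Defaults describe a realistic long-term wearable deployment: 180 days of
#' photoplethysmography-derived heart rate sampled every 5 seconds, a 75 BPM
#' baseline carrying circadian (24 h), about-weekly (7 d) and about-monthly
#' (30 d) cycles, and autocorrelated measurement noise. 180 days guarantees
#' at least four full periods of the 30-day cycle, the minimum required for
#' cycle detection.
#'
#' @param duration_days Recording length in days (>= 1).
#' @param sample_interval_s Sampling interval of the raw stream in seconds.
#' @param baseline_bpm Mean heart rate in BPM.
#' @param cycles List of [cycle_spec()] objects (may be empty).
#' @param noise_sd Stationary SD of the additive noise, BPM.
#' @param noise_ar1 Lag-1 coefficient of the AR(1) noise at the raw sampling
#'   interval, in `[0, 1)`. 0 gives white noise.
#' @param gaps Optional [gap_spec()] applied after generation.
#' @param seed Integer seed; identical configs and seeds reproduce the
#'   stream exactly.
#' @param start_time Timestamp of the first sample (POSIXct, UTC).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_days = 180, sample_interval_s = 5,
                             baseline_bpm = 75,
                             cycles = list(
                               cycle_spec(24, 3),
                               cycle_spec(7 * 24, 2.5),
                               cycle_spec(30 * 24, 2.5)
                             ),
                             noise_sd = 5, noise_ar1 = 0.9,
                             gaps = NULL, seed = 1L,
                             start_time = as.POSIXct("2020-01-01",
                                                     tz = "UTC")) {
  if (!is_scalar_num(duration_days) || duration_days < 1) {
    stop_config("duration_days", "must be >= 1 day")
  }
  if (!is_scalar_num(sample_interval_s) || sample_interval_s <= 0) {
    stop_config("sample_interval_s", "must be > 0")
  }
  if (!is_scalar_num(baseline_bpm)) stop_config("baseline_bpm", "must be numeric")
  if (!is.list(cycles) ||
      !all(vapply(cycles, inherits, logical(1), "cycle_spec"))) {
    stop_config("cycles", "must be a list of cycle_spec objects")
  }
  if (!is_scalar_num(noise_sd) || noise_sd < 0) {
    stop_config("noise_sd", "must be non-negative")
  }
  if (!is_scalar_num(noise_ar1) || noise_ar1 < 0 || noise_ar1 >= 1) {
    stop_config("noise_ar1", "must lie in [0, 1)")
  }
  if (!is.null(gaps) && !inherits(gaps, "gap_spec")) {
    stop_config("gaps", "must be NULL or a gap_spec")
  }
  structure(list(duration_days = duration_days,
                 sample_interval_s = sample_interval_s,
                 baseline_bpm = baseline_bpm, cycles = cycles,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1,
                 gaps = gaps, seed = as.integer(seed),
                 start_time = start_time),
            class = "synthetic_config")
}

#' Configure phase-locked synthetic events
#'
#' Event phases on the target cycle follow a von Mises law with mean
#' `preferred_phase` and concentration `kappa` (`kappa = 0` is circular
#' uniform). An optional diurnal reporting bias mixes in a clock-time
#' preference, emulating the tendency of self-reported diaries to favour
#' waking hours.
#'
#' @param n_events Number of events to draw.
#' @param target_cycle Index into the generating config's `cycles` list.
#' @param preferred_phase Mean event phase, radians in `[0, 2*pi)`.
#' @param kappa von Mises concentration (>= 0).
#' @param diurnal_bias_weight Mixing weight in `[0, 1]` for a clock-time
#'   preference applied by rejection sampling (0 disables it).
#' @param diurnal_peak_hour Local clock hour of maximal reporting
#'   likelihood when `diurnal_bias_weight > 0`.
#' @param seed Integer seed.
#' @return An `event_config` list.
#' @export
event_config <- function(n_events, target_cycle = 1, preferred_phase = pi / 2,
                         kappa = 3, diurnal_bias_weight = 0,
                         diurnal_peak_hour = 18, seed = 1L) {
  if (!is_scalar_num(n_events) || n_events < 0 || n_events != round(n_events)) {
    stop_config("n_events", "must be a non-negative integer")
  }
  if (!is_scalar_num(kappa) || kappa < 0) stop_config("kappa", "must be >= 0")
  if (!is_scalar_num(preferred_phase) || preferred_phase < 0 ||
      preferred_phase >= 2 * pi) {
    stop_config("preferred_phase", "must lie in [0, 2*pi)")
  }
  if (!is_scalar_num(diurnal_bias_weight) || diurnal_bias_weight < 0 ||
      diurnal_bias_weight > 1) {
    stop_config("diurnal_bias_weight", "must lie in [0, 1]")
  }
  structure(list(n_events = as.integer(n_events),
                 target_cycle = as.integer(target_cycle),
                 preferred_phase = preferred_phase, kappa = kappa,
                 diurnal_bias_weight = diurnal_bias_weight,
                 diurnal_peak_hour = diurnal_peak_hour,
                 seed = as.integer(seed)),
            class = "event_config")
}

#' Generate a synthetic heart-rate stream with known ground truth
#'
#' The stream value at time t is
#' `baseline + sum_k amplitude_k * sin(phi_k(t)) + AR(1) noise`, where each
#' cycle's phase `phi_k` advances at `2*pi / period_k` per hour plus an
#' optional Gaussian random walk (phase drift). Ground-truth phases are
#' recorded on the 5-minute analysis grid so parameter-recovery tests can
#' compare against them directly.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `stream` (data.frame: `timestamp`, `bpm`)
#'   and `truth` (a `synthetic_truth` list: `cycles`, `grid_hours`,
#'   `phase_series` — one column per cycle, radians in `[0, 2*pi)` —,
#'   `start_time`, `duration_days`, and the gap layout if gaps were
#'   injected).
#' @export
generate_heart_rate <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("config", "must be a synthetic_config")
  }
  dt_h <- config$sample_interval_s / 3600
  n <- floor(config$duration_days * 24 / dt_h)
  t_h <- (seq_len(n) - 1) * dt_h

  grid_step_h <- 1 / 12 # 5-minute analysis grid
  stride <- max(1L, round(grid_step_h / dt_h))
  grid_idx <- seq(1L, n, by = stride)

  with_seed(config$seed, {
    values <- rep(config$baseline_bpm, n)
    k <- length(config$cycles)
    phase_series <- matrix(NA_real_, nrow = length(grid_idx), ncol = k)
    for (j in seq_len(k)) {
      cyc <- config$cycles[[j]]
      phi <- cyc$initial_phase + 2 * pi * t_h / cyc$period_hours
      if (cyc$phase_drift_sd > 0) {
        step_sd <- cyc$phase_drift_sd * sqrt(dt_h / cyc$period_hours)
        phi <- phi + cumsum(stats::rnorm(n, 0, step_sd))
      }
      values <- values + cyc$amplitude * sin(phi)
      phase_series[, j] <- wrap_2pi(phi[grid_idx])
    }
    if (config$noise_sd > 0) {
      innov_sd <- config$noise_sd * sqrt(1 - config$noise_ar1^2)
      eps <- stats::rnorm(n, 0, innov_sd)
      noise <- if (config$noise_ar1 > 0) {
        as.numeric(stats::filter(eps, config$noise_ar1, method = "recursive"))
      } else {
        eps
      }
      values <- values + noise
    }

    stream <- data.frame(
      timestamp = config$start_time + t_h * 3600,
      bpm = values
    )
    truth <- structure(list(
      cycles = config$cycles,
      grid_hours = t_h[grid_idx],
      phase_series = phase_series,
      start_time = config$start_time,
      duration_days = config$duration_days,
      gaps = NULL
    ), class = "synthetic_truth")

    if (!is.null(config$gaps) && config$gaps$n_gaps > 0) {
      gapped <- inject_gaps(stream, config$gaps, seed = config$seed + 1L)
      stream <- gapped$stream
      truth$gaps <- gapped$gaps
    }
    list(stream = stream, truth = truth)
  })
}

#' Remove device-like missing segments from a stream
#'
#' Gap start times are drawn uniformly over the record and re-drawn until
#' the requested number of non-overlapping gaps fits; samples inside each
#' gap are dropped.
#'
#' @param stream data.frame with `timestamp` and `bpm` columns.
#' @param spec A [gap_spec()].
#' @param seed Integer seed.
#' @return List: `stream` (rows removed), `gaps` (data.frame of
#'   `start_hours`, `duration_hours` relative to the first sample), and
#'   `removed_fraction`.
#' @export
inject_gaps <- function(stream, spec, seed = 1L) {
  if (!inherits(spec, "gap_spec")) stop_config("spec", "must be a gap_spec")
  if (nrow(stream) == 0) stop("cannot inject gaps into an empty stream",
                              call. = FALSE)
  if (spec$n_gaps == 0) {
    return(list(stream = stream,
                gaps = data.frame(start_hours = numeric(0),
                                  duration_hours = numeric(0)),
                removed_fraction = 0))
  }
  t0 <- stream$timestamp[1]
  t_h <- as.numeric(difftime(stream$timestamp, t0, units = "hours"))
  span <- t_h[length(t_h)]

  with_seed(seed, {
    durations <- switch(spec$distribution,
      "uniform-log" = exp(stats::runif(spec$n_gaps,
                                       log(max(spec$min_hours, 1e-6)),
                                       log(max(spec$max_hours, 1e-6)))),
      "fixed" = rep(spec$max_hours, spec$n_gaps)
    )
    if (sum(durations) >= span) {
      stop("gap placement error: requested gaps cover the entire record",
           call. = FALSE)
    }
    starts <- numeric(0)
    placed <- numeric(0)
    for (d in sort(durations, decreasing = TRUE)) {
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        s <- stats::runif(1, 0, span - d)
        if (!any(s < starts + placed & s + d > starts)) {
          starts <- c(starts, s)
          placed <- c(placed, d)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("gap placement error: could not place gaps without overlap",
             call. = FALSE)
      }
    }
    ord <- order(starts)
    gaps <- data.frame(start_hours = starts[ord],
                       duration_hours = placed[ord])
    drop <- rep(FALSE, length(t_h))
    for (i in seq_len(nrow(gaps))) {
      drop <- drop | (t_h >= gaps$start_hours[i] &
                      t_h < gaps$start_hours[i] + gaps$duration_hours[i])
    }
    list(stream = stream[!drop, , drop = FALSE], gaps = gaps,
         removed_fraction = mean(drop))
  })
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution.
# kappa = 0 reduces to the circular uniform.
sample_von_mises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      out[i] <- wrap_2pi(sign(u3 - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

#' Generate event times phase-locked to an implanted cycle
#'
#' Draws event phases from a von Mises law on the target cycle and maps
#' each draw to a recording time by choosing uniformly among grid points
#' whose true cycle phase matches the draw within one phase-grid step
#' (`2*pi * 5min / period`). This guarantees the intended phase law even
#' when the cycle drifts. With `diurnal_bias_weight > 0`, candidate times
#' are additionally accepted with probability proportional to a clock-time
#' preference, emulating diary reporting bias.
#'
#' @param truth The `synthetic_truth` from [generate_heart_rate()].
#' @param config An [event_config()].
#' @return POSIXct vector of event times (strictly inside the recording),
#'   with the realised phases as attribute `"true_phase"`.
#' @export
generate_phase_locked_events <- function(truth, config) {
  if (!inherits(truth, "synthetic_truth")) {
    stop_config("truth", "must be a synthetic_truth")
  }
  if (!inherits(config, "event_config")) {
    stop_config("config", "must be an event_config")
  }
  if (config$n_events == 0) {
    out <- truth$start_time[0]
    attr(out, "true_phase") <- numeric(0)
    return(out)
  }
  k <- length(truth$cycles)
  if (config$target_cycle < 1 || config$target_cycle > k) {
    stop_config("target_cycle", sprintf("must index one of %d cycles", k))
  }
  if (length(truth$grid_hours) == 0) {
    stop("recording span is empty; cannot place events", call. = FALSE)
  }
  cyc <- truth$cycles[[config$target_cycle]]
  phases <- truth$phase_series[, config$target_cycle]
  tol <- 2 * pi * (1 / 12) / cyc$period_hours # one 5-min phase-grid step

  with_seed(config$seed, {
    draws <- sample_von_mises(config$n_events, config$preferred_phase,
                              config$kappa)
    times_h <- numeric(config$n_events)
    realised <- numeric(config$n_events)
    for (i in seq_len(config$n_events)) {
      cand <- which(abs(circ_diff(phases, draws[i])) <= tol)
      if (length(cand) == 0) {
        cand <- which.min(abs(circ_diff(phases, draws[i])))
      }
      if (config$diurnal_bias_weight > 0) {
        repeat {
          j <- cand[sample.int(length(cand), 1L)]
          clock_phase <- 2 * pi *
            ((truth$grid_hours[j] +
              as.numeric(format(truth$start_time, "%H", tz = "UTC"))) %% 24) / 24
          peak_phase <- 2 * pi * config$diurnal_peak_hour / 24
          pref <- (1 + cos(clock_phase - peak_phase)) / 2 # in [0, 1]
          accept <- (1 - config$diurnal_bias_weight) +
            config$diurnal_bias_weight * pref
          if (stats::runif(1) <= accept) break
        }
      } else {
        j <- cand[sample.int(length(cand), 1L)]
      }
      times_h[i] <- truth$grid_hours[j]
      realised[i] <- phases[j]
    }
    ord <- order(times_h)
    out <- truth$start_time + times_h[ord] * 3600
    attr(out, "true_phase") <- realised[ord]
    attr(out, "drawn_phase") <- draws[ord]
    out
  })
}

#' Write a heart-rate stream as delimited text
#'
#' One sample per row, columns `timestamp` (ISO-8601, UTC) and `bpm` —
#' the dialect [read_heart_rate_table()] reads.
#'
#' @param stream data.frame with `timestamp`, `bpm`.
#' @param path Output file path.
#' @export
write_heart_rate_table <- function(stream, path) {
  utils::write.csv(
    data.frame(timestamp = format_timestamp(stream$timestamp),
               bpm = stream$bpm),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an event diary as delimited text
#'
#' @param events POSIXct vector of event times.
#' @param path Output file path.
#' @param labels Optional data.frame of per-event label columns
#'   (e.g. `awareness`, `motor`).
#' @export
write_diary <- function(events, path, labels = NULL) {
  df <- data.frame(timestamp = format_timestamp(events))
  if (!is.null(labels)) df <- cbind(df, labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
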