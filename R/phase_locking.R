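# Circular statistics linking seizure events to heart-rate cycle phase:
# event-to-phase mapping, phase histograms (24 bins for circadian cycles,
# 18 otherwise), the synchronisation index (mean resultant length),
# the Hodges-Ajne omnibus test of circular uniformity, Bonferroni
# correction across a participant's cycles, and surrogate SI null
# distributions built from random event times.

#' Map event times to cycle phase
#'
#' Each event takes the phase of the nearest grid point, provided it lies
#' within half a grid step (2.5 minutes). Events outside the recording
#' span, beyond that tolerance, or falling on grid points flagged
#' unusable (record edges, mean-filled stretches) are excluded and
#' counted.
#'
#' @param events POSIXct event times (or a `seizure_diary`).
#' @param cycle A `filtered_cycle`.
#' @return An `event_phase_set`: `phases` (radians in `[0, 2*pi)`),
#'   `n_events`, `n_excluded`, plus the cycle's identity fields.
#' @export
map_events_to_phase <- function(events, cycle) {
  stopifnot(inherits(cycle, "filtered_cycle"))
  if (inherits(events, "seizure_diary")) events <- events$events
  n_grid <- length(cycle$phase)
  if (n_grid == 0) stop("empty phase series", call. = FALSE)
  offset_s <- as.numeric(difftime(events, cycle$start_time, units = "secs"))
  idx <- round(offset_s / cycle$step_s) + 1
  dist_s <- abs(offset_s - (idx - 1) * cycle$step_s)
  ok <- idx >= 1 & idx <= n_grid & dist_s <= cycle$step_s / 2
  ok[ok] <- cycle$usable[idx[ok]]
  structure(list(
    phases = cycle$phase[idx[ok]],
    n_events = sum(ok),
    n_excluded = sum(!ok),
    participant_id = cycle$participant_id,
    centre_period_hours = cycle$band$centre,
    class = cycle$class,
    subclass = cycle$subclass
  ), class = "event_phase_set")
}

#' Seizure-analysis eligibility gate
#'
#' Phase-locking analysis requires at least 20 reported events during the
#' wearable recording span.
#'
#' @param diary A `seizure_diary` or POSIXct vector.
#' @param series An `hr_series` defining the recording span.
#' @param min_events Minimum usable events (default 20).
#' @return Logical scalar; the usable event count is attached as
#'   attribute `"n_usable"`.
#' @export
eligibility_gate <- function(diary, series, min_events = 20) {
  events <- if (inherits(diary, "seizure_diary")) diary$events else diary
  span_end <- series$start_time + length(series$values) * series$step_s
  n <- sum(events >= series$start_time & events <= span_end)
  structure(n >= min_events, n_usable = n)
}

#' Bin event phases into a phase distribution
#'
#' Equal-width half-open bins `[k*2*pi/n, (k+1)*2*pi/n)` spanning
#' `[0, 2*pi)`; circadian cycles use 24 bins (1 hour each), all other
#' periods 18.
#'
#' @param phases An `event_phase_set` or numeric vector of phases.
#' @param n_bins Number of bins; if NULL, chosen from the cycle class
#'   (24 for circadian, 18 otherwise; 18 when the class is unknown).
#' @return A `phase_distribution`: `n_bins`, `edges`, `centres`,
#'   `counts`, `n_events`.
#' @export
bin_phases <- function(phases, n_bins = NULL) {
  cls <- NULL
  if (inherits(phases, "event_phase_set")) {
    cls <- phases$class
    phases <- phases$phases
  }
  if (is.null(n_bins)) {
    n_bins <- if (identical(cls, "circadian")) 24L else 18L
  }
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  idx <- floor(wrap_2pi(phases) / (2 * pi / n_bins)) + 1
  idx[idx > n_bins] <- n_bins # guard the phase == 2*pi roundoff edge
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(n_bins = as.integer(n_bins), edges = edges,
                 centres = edges[-length(edges)] + pi / n_bins,
                 counts = counts, n_events = length(phases)),
            class = "phase_distribution")
}

#' Synchronisation index and preferred phase
#'
#' The mean resultant vector of the binned phase distribution, computed
#' over bin centres: `R = |sum_k counts_k exp(i centre_k)| / n`. SI ranges
#' from 0 (uniform distribution) to 1 (perfect alignment); the resultant's
#' direction is the preferred phase of event occurrence.
#'
#' @param dist A `phase_distribution` from [bin_phases()].
#' @return List: `si` in `[0, 1]`; `preferred_phase` radians in
#'   `[0, 2*pi)` (NA when `si` is numerically 0, where the direction is
#'   undefined).
#' @export
synchronization_index <- function(dist) {
  stopifnot(inherits(dist, "phase_distribution"))
  n <- dist$n_events
  if (n == 0) stop("zero events: SI undefined", call. = FALSE)
  z <- sum(dist$counts * exp(1i * dist$centres)) / n
  si <- Mod(z)
  list(si = si,
       preferred_phase = if (si < 1e-12) NA_real_ else wrap_2pi(Arg(z)))
}

#' Unbinned synchronisation index
#'
#' Mean resultant vector computed directly from event phases, exposed for
#' sensitivity analysis against the binned estimate.
#'
#' @param phases Numeric vector of phases (or an `event_phase_set`).
#' @return As [synchronization_index()].
#' @export
si_unbinned <- function(phases) {
  if (inherits(phases, "event_phase_set")) phases <- phases$phases
  n <- length(phases)
  if (n == 0) stop("zero events: SI undefined", call. = FALSE)
  z <- mean(exp(1i * phases))
  si <- Mod(z)
  list(si = si,
       preferred_phase = if (si < 1e-12) NA_real_ else wrap_2pi(Arg(z)))
}

# Hodges-Ajne statistic: n minus the maximum number of points in any
# closed half-circle; boundaries need only be checked at the data angles
# and their antipodes.
hodges_ajne_m <- function(phases) {
  n <- length(phases)
  cand <- c(phases, phases - pi)
  counts <- vapply(cand, function(a) {
    d <- (phases - a) %% (2 * pi)
    sum(d <= pi + 1e-12)
  }, numeric(1))
  as.integer(n - max(counts))
}

#' Hodges-Ajne omnibus test of circular uniformity
#'
#' Tests whether event phases are uniformly distributed on the circle
#' using the statistic `m`, the minimum number of points in the
#' complement of any closed half-circle. For `n <= 50` the exact tail
#' probability `p = 2^(1-n) (n - 2m) choose(n, m)` is used (clipped to
#' 1); for larger samples the standard large-sample approximation.
#' Runs on unbinned phases.
#'
#' @param phases Numeric vector of phases (or an `event_phase_set`).
#' @return List: `p` in (0, 1], `m`, `n`.
#' @export
hodges_ajne_test <- function(phases) {
  if (inherits(phases, "event_phase_set")) phases <- phases$phases
  n <- length(phases)
  if (n < 4) stop("Hodges-Ajne test needs at least 4 events", call. = FALSE)
  m <- hodges_ajne_m(phases)
  if (n <= 50) {
    p <- 2^(1 - n) * (n - 2 * m) * choose(n, m)
  } else {
    a <- pi * sqrt(n) / (2 * (n - 2 * m))
    p <- sqrt(2 * pi) / a * exp(-pi^2 / (8 * a^2))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, m = m, n = n)
}

#' Bonferroni-corrected significance level
#'
#' Experiment-wise error is controlled per participant across that
#' participant's significant heart-rate cycles.
#'
#' @param n_tests Number of cycles tested (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is_scalar_num(n_tests) || n_tests < 1) {
    stop("n_tests must be >= 1", call. = FALSE)
  }
  alpha / n_tests
}

#' Surrogate SI null distribution for one cycle
#'
#' Each surrogate draws `n_events` times uniformly at random from the
#' cycle's usable grid points, maps them through the actual phase series
#' and computes the binned SI — preserving the event count and the
#' cycle's real phase occupancy under the null of no phase preference.
#'
#' @param cycle A `filtered_cycle`.
#' @param n_events Number of events per surrogate.
#' @param n_surrogates Number of surrogates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param observed_si Optional observed SI; when given, the fraction of
#'   surrogate SIs below it is returned as `quantile`.
#' @param n_bins Histogram bins (default: by cycle class).
#' @return List: `si` (surrogate SI values), `quantile` (or NA).
#' @export
surrogate_si_distribution <- function(cycle, n_events, n_surrogates = 1000,
                                      seed = 1L, observed_si = NULL,
                                      n_bins = NULL) {
  stopifnot(inherits(cycle, "filtered_cycle"))
  if (n_surrogates < 100) stop("need at least 100 surrogates", call. = FALSE)
  usable_phase <- cycle$phase[cycle$usable]
  if (length(usable_phase) == 0) stop("usable recording span is empty",
                                      call. = FALSE)
  if (is.null(n_bins)) n_bins <- if (cycle$class == "circadian") 24L else 18L
  step <- 2 * pi / n_bins
  centres_z <- exp(1i * (step * (seq_len(n_bins) - 0.5)))
  with_seed(seed, {
    si <- vapply(seq_len(n_surrogates), function(i) {
      ph <- usable_phase[sample.int(length(usable_phase), n_events,
                                    replace = TRUE)]
      idx <- floor(wrap_2pi(ph) / step) + 1
      idx[idx > n_bins] <- n_bins
      Mod(sum(centres_z[idx])) / n_events
    }, numeric(1))
    list(si = si,
         quantile = if (is.null(observed_si)) NA_real_ else mean(si < observed_si))
  })
}

#' Assess seizure phase-locking across a participant's cycles
#'
#' For each extracted cycle: maps events to phase, computes the binned SI
#' and preferred phase, runs the Hodges-Ajne omnibus test on the unbinned
#' phases, applies the per-participant Bonferroni correction
#' (`alpha / number of cycles tested`), and locates the observed SI in a
#' surrogate null distribution.
#'
#' @param diary A `seizure_diary` or POSIXct event times.
#' @param cycles List of `filtered_cycle` objects (one participant).
#' @param series The participant's `hr_series` (recording span for the
#'   eligibility gate).
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_surrogates Surrogates per cycle (default 1000).
#' @param surrogate_quantile Exceedance quantile for the surrogate flag
#'   (default 0.95).
#' @param seed Integer seed for the surrogates.
#' @param min_events Eligibility threshold (default 20).
#' @param require_eligible Error when the participant has fewer than
#'   `min_events` events (default TRUE); set FALSE to compute anyway.
#' @return data.frame, one row per cycle: `centre_period_hours`, `class`,
#'   `subclass`, `n_events`, `n_excluded`, `si`, `preferred_phase`,
#'   `omnibus_p`, `omnibus_m`, `n_tests`, `alpha_corrected`,
#'   `significant`, `surrogate_quantile`, `surrogate_exceeds`.
#' @export
assess_phase_locking <- function(diary, cycles, series, alpha = 0.05,
                                 n_surrogates = 1000,
                                 surrogate_quantile = 0.95, seed = 1L,
                                 min_events = 20, require_eligible = TRUE) {
  if (length(cycles) == 0) {
    return(data.frame(centre_period_hours = numeric(0), class = character(0),
                      subclass = character(0), n_events = integer(0),
                      n_excluded = integer(0), si = numeric(0),
                      preferred_phase = numeric(0), omnibus_p = numeric(0),
                      omnibus_m = integer(0), n_tests = integer(0),
                      alpha_corrected = numeric(0), significant = logical(0),
                      surrogate_quantile = numeric(0),
                      surrogate_exceeds = logical(0)))
  }
  gate <- eligibility_gate(diary, series, min_events = min_events)
  if (!gate && require_eligible) {
    stop(sprintf(
      "participant not eligible: %d usable events < %d required",
      attr(gate, "n_usable"), min_events), call. = FALSE)
  }
  n_tests <- length(cycles)
  alpha_c <- bonferroni_threshold(n_tests, alpha)
  rows <- lapply(seq_along(cycles), function(i) {
    cyc <- cycles[[i]]
    eps <- map_events_to_phase(diary, cyc)
    if (eps$n_events >= 1) {
      dist <- bin_phases(eps)
      siv <- synchronization_index(dist)
      ha <- if (eps$n_events >= 4) hodges_ajne_test(eps) else
        list(p = NA_real_, m = NA_integer_)
      surr <- surrogate_si_distribution(cyc, eps$n_events,
                                        n_surrogates = n_surrogates,
                                        seed = seed + i,
                                        observed_si = siv$si)
      sq <- surr$quantile
    } else {
      siv <- list(si = NA_real_, preferred_phase = NA_real_)
      ha <- list(p = NA_real_, m = NA_integer_)
      sq <- NA_real_
    }
    data.frame(
      centre_period_hours = cyc$band$centre,
      class = cyc$class, subclass = cyc$subclass,
      n_events = eps$n_events, n_excluded = eps$n_excluded,
      si = siv$si, preferred_phase = siv$preferred_phase,
      omnibus_p = ha$p, omnibus_m = ha$m,
      n_tests = n_tests, alpha_corrected = alpha_c,
      significant = !is.na(ha$p) & ha$p < alpha_c &
        eps$n_events >= min_events,
      surrogate_quantile = sq,
      surrogate_exceeds = !is.na(sq) & sq > surrogate_quantile,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
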