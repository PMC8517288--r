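# End-to-end per-participant pipeline: raw stream (+ optional diary) ->
# preprocessing -> cycle detection -> band-pass extraction -> phase
# locking. Also a one-call synthetic-participant helper used throughout
# the test-suite and examples.

#' Run the full analysis for one participant
#'
#' Resamples the raw stream to the 5-minute grid, interpolates gaps,
#' z-standardises, detects significant cycles by Morlet wavelet analysis,
#' extracts each cycle with its band-pass filter and Hilbert phase and,
#' when a diary with enough events is supplied, assesses seizure
#' phase-locking for every cycle.
#'
#' @param raw An `hr_raw` stream ([hr_raw()] or
#'   [read_heart_rate_table()]).
#' @param diary Optional `seizure_diary` or POSIXct event times.
#' @param group Optional group label (e.g. `"epilepsy"` / `"control"`).
#' @param sig_level Wavelet significance level (default 0.99).
#' @param voices_per_octave Wavelet scale resolution (default 16).
#' @param background Wavelet noise background (default red noise).
#' @param seed Seed for the surrogate distributions.
#' @param ... Passed to [assess_phase_locking()].
#' @return List: `participant_id`, `group`, `adherence`, `series`,
#'   `spectrum`, `cycles` (a `cycle_set`), `filtered` (list of
#'   `filtered_cycle`), `eligible_seizures`, `n_usable_events`,
#'   `phase_locking` (data.frame or NULL).
#' @export
analyze_participant <- function(raw, diary = NULL, group = NULL,
                                sig_level = 0.99, voices_per_octave = 16,
                                background = c("red-noise", "white"),
                                seed = 1L, ...) {
  background <- match.arg(background)
  pre <- preprocess_heart_rate(raw)
  cycles <- detect_cycles(pre$series, voices_per_octave = voices_per_octave,
                          background = background, sig_level = sig_level)
  filtered <- extract_cycles(pre$series, cycles)
  res <- list(participant_id = raw$participant_id, group = group,
              adherence = pre$adherence, series = pre$series,
              spectrum = attr(cycles, "spectrum"), cycles = cycles,
              filtered = filtered, eligible_seizures = FALSE,
              n_usable_events = 0L, phase_locking = NULL)
  if (!is.null(diary)) {
    gate <- eligibility_gate(diary, pre$series)
    res$eligible_seizures <- isTRUE(gate)
    res$n_usable_events <- attr(gate, "n_usable")
    if (res$eligible_seizures && length(filtered) > 0) {
      res$phase_locking <- assess_phase_locking(diary, filtered, pre$series,
                                                seed = seed, ...)
    }
  }
  res
}

#' Simulate a complete synthetic participant
#'
#' Generates a heart-rate stream with implanted cycles (optionally with
#' gaps), draws phase-locked events on a chosen cycle, and returns the
#' raw objects the analysis pipeline ingests together with the ground
#' truth.
#'
#' @param config A [synthetic_config()].
#' @param events An [event_config()] or NULL for no diary.
#' @param participant_id Identifier.
#' @return List: `raw` (`hr_raw`), `diary` (`seizure_diary` or NULL),
#'   `truth` (`synthetic_truth`).
#' @export
simulate_participant <- function(config = synthetic_config(),
                                 events = NULL, participant_id = "SIM1") {
  gen <- generate_heart_rate(config)
  raw <- hr_raw(gen$stream$timestamp, gen$stream$bpm,
                participant_id = participant_id)
  diary <- NULL
  if (!is.null(events)) {
    ev <- generate_phase_locked_events(gen$truth, events)
    diary <- seizure_diary(ev, participant_id = participant_id)
  }
  list(raw = raw, diary = diary, truth = gen$truth)
}
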