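# Ingest and preprocessing of wearable heart-rate streams and seizure
# diaries: plausibility filtering, 5-minute resampling, adherence
# computation, gap interpolation and z-standardisation.

BPM_MIN <- 25
BPM_MAX <- 250
GRID_STEP_S <- 300L # 5-minute analysis grid

#' Read a heart-rate table
#'
#' Expects delimited text with a header and columns `timestamp` (ISO-8601)
#' and `bpm`. Rows are sorted by time, duplicate timestamps are collapsed
#' to their mean, and BPM values outside the plausibility window
#' `[25, 250]` are dropped (wearable artefact hygiene); the number dropped
#' is reported via a message and stored on the result.
#'
#' @param path File path.
#' @param participant_id Identifier attached to the stream.
#' @param sep Field separator (default `","`).
#' @param tz Timezone used to interpret timestamps.
#' @return An `hr_raw` object: list with `participant_id`, `time`
#'   (POSIXct, strictly increasing), `bpm`, `n_dropped`.
#' @export
read_heart_rate_table <- function(path, participant_id = "P1", sep = ",",
                                  tz = "UTC") {
  if (!file.exists(path)) stop("ingest error: file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("ingest error: empty file: ", path, call. = FALSE)
  need <- c("timestamp", "bpm")
  if (!all(need %in% names(df))) {
    stop("ingest error: need columns `timestamp` and `bpm`", call. = FALSE)
  }
  tt <- parse_timestamp(df$timestamp, tz = tz)
  if (anyNA(tt)) {
    bad <- which(is.na(tt))
    stop(sprintf("ingest error: unparseable timestamp at data row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  hr_raw(tt, as.numeric(df$bpm), participant_id = participant_id)
}

#' Construct a raw heart-rate stream in memory
#'
#' Applies the same hygiene as [read_heart_rate_table()]: time sorting,
#' duplicate-timestamp collapse by mean, and the `[25, 250]` BPM
#' plausibility filter.
#'
#' @param time POSIXct sample times.
#' @param bpm Numeric heart-rate values.
#' @param participant_id Identifier.
#' @return An `hr_raw` object.
#' @export
hr_raw <- function(time, bpm, participant_id = "P1") {
  stopifnot(length(time) == length(bpm))
  keep <- !is.na(bpm) & bpm >= BPM_MIN & bpm <= BPM_MAX
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropped %d sample(s) outside [%g, %g] BPM",
                    n_dropped, BPM_MIN, BPM_MAX))
  }
  time <- time[keep]
  bpm <- bpm[keep]
  if (length(time) == 0) stop("ingest error: no usable samples", call. = FALSE)
  ord <- order(time)
  time <- time[ord]
  bpm <- bpm[ord]
  if (anyDuplicated(as.numeric(time))) {
    key <- as.numeric(time)
    bpm <- as.numeric(tapply(bpm, key, mean))
    time <- as.POSIXct(sort(unique(key)), origin = "1970-01-01", tz = "UTC")
  }
  structure(list(participant_id = participant_id, time = time, bpm = bpm,
                 n_dropped = n_dropped),
            class = "hr_raw")
}

#' Read a seizure diary
#'
#' Delimited text with a `timestamp` column and optional `awareness`
#' (`aware` / `impaired-awareness`) and `motor` (`motor` / `non-motor`)
#' label columns.
#'
#' @param path File path.
#' @param participant_id Identifier.
#' @param sep Field separator.
#' @param tz Timezone used to interpret timestamps.
#' @return A `seizure_diary` object: list with `participant_id`, `events`
#'   (POSIXct, non-decreasing) and `labels` (data.frame or NULL).
#' @export
read_seizure_diary <- function(path, participant_id = "P1", sep = ",",
                               tz = "UTC") {
  if (!file.exists(path)) stop("ingest error: file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) {
    stop("ingest error: diary needs a `timestamp` column", call. = FALSE)
  }
  tt <- parse_timestamp(df$timestamp, tz = tz)
  if (anyNA(tt)) {
    stop("ingest error: unparseable diary timestamp(s)", call. = FALSE)
  }
  seizure_diary(tt, participant_id = participant_id,
                labels = df[setdiff(names(df), "timestamp")])
}

#' Construct a seizure diary in memory
#'
#' @param events POSIXct event times.
#' @param participant_id Identifier.
#' @param labels Optional data.frame of per-event labels.
#' @return A `seizure_diary` object.
#' @export
seizure_diary <- function(events, participant_id = "P1", labels = NULL) {
  ord <- order(events)
  if (!is.null(labels) && ncol(as.data.frame(labels)) > 0) {
    labels <- as.data.frame(labels)[ord, , drop = FALSE]
  } else {
    labels <- NULL
  }
  structure(list(participant_id = participant_id, events = events[ord],
                 labels = labels),
            class = "seizure_diary")
}

#' Resample a raw stream to the regular 5-minute grid
#'
#' The grid is aligned to the 5-minute floor of the first sample; each bin
#' value is the arithmetic mean of the raw samples falling in
#' `[t, t + 5 min)`, and bins containing no sample are marked unobserved.
#'
#' @param raw An `hr_raw` stream.
#' @return An `hr_series` object: `participant_id`, `start_time`,
#'   `step_s` (300), `values` (NA where unobserved), `observed` (logical),
#'   `interp` (per-point label, `"observed"` where observed).
#' @export
resample_to_grid <- function(raw) {
  stopifnot(inherits(raw, "hr_raw"))
  t_num <- as.numeric(raw$time)
  grid0 <- floor(t_num[1] / GRID_STEP_S) * GRID_STEP_S
  idx <- floor((t_num - grid0) / GRID_STEP_S) + 1
  n_bins <- max(idx)
  sums <- rowsum(raw$bpm, idx)
  counts <- rowsum(rep(1, length(idx)), idx)
  values <- rep(NA_real_, n_bins)
  values[as.integer(rownames(sums))] <- sums / counts
  observed <- !is.na(values)
  structure(list(
    participant_id = raw$participant_id,
    start_time = as.POSIXct(grid0, origin = "1970-01-01", tz = "UTC"),
    step_s = GRID_STEP_S,
    values = values,
    observed = observed,
    interp = ifelse(observed, "observed", NA_character_),
    standardised = FALSE
  ), class = "hr_series")
}

#' Grid times of an `hr_series`, in hours since its start
#' @param series An `hr_series`.
#' @return Numeric vector of offsets in hours.
#' @export
series_hours <- function(series) {
  (seq_along(series$values) - 1) * series$step_s / 3600
}

#' Compute adherence and cycle-analysis eligibility
#'
#' Adherence is the fraction of whole clock hours spanned by the recording
#' that contain at least one raw sample. A participant is eligible for
#' cycle analysis with at least four months of recording (1 month =
#' 30.44 days) and adherence strictly above 80%; both computed from raw
#' coverage, independent of any interpolation.
#'
#' @param raw An `hr_raw` stream.
#' @return An `adherence_report` list: `total_hours`, `covered_hours`,
#'   `adherence`, `recording_months`, `eligible_cycles`, `reason`.
#' @export
compute_adherence <- function(raw) {
  stopifnot(inherits(raw, "hr_raw"))
  hrs <- floor(as.numeric(raw$time) / 3600)
  total <- hrs[length(hrs)] - hrs[1] + 1
  covered <- length(unique(hrs))
  adherence <- covered / total
  months <- as.numeric(difftime(raw$time[length(raw$time)], raw$time[1],
                                units = "days")) / 30.44
  eligible <- months >= 4 && adherence > 0.80
  reason <- if (eligible) {
    "eligible"
  } else if (months < 4) {
    sprintf("recording %.1f months < 4 months", months)
  } else {
    sprintf("adherence %.1f%% not > 80%%", 100 * adherence)
  }
  structure(list(total_hours = total, covered_hours = covered,
                 adherence = adherence, recording_months = months,
                 eligible_cycles = eligible, reason = reason),
            class = "adherence_report")
}

#' Interpolate unobserved grid bins
#'
#' Gaps of up to 2 hours (1 hour attributable to each flank) are linearly
#' interpolated between the flanking observed values. Longer gaps are
#' ramped linearly over the first and last hour from the flanking values to
#' the global mean of all observed data, with the interior held at that
#' mean; this honours mean-value filling of long outages while avoiding
#' step discontinuities that would inject spurious high-frequency power.
#' `interp` records the method per point (`"linear"` or `"mean-fill"`);
#' observed bins are never altered.
#'
#' @param series An `hr_series` from [resample_to_grid()].
#' @param max_linear_hours Longest gap fully bridged by linear
#'   interpolation (default 2).
#' @param ramp_hours Ramp length at each edge of longer gaps (default 1).
#' @return The series with no missing values and a complete `interp` mask;
#'   the pre-standardisation global mean is stored as `fill_mean`.
#' @export
fill_gaps <- function(series, max_linear_hours = 2, ramp_hours = 1) {
  stopifnot(inherits(series, "hr_series"))
  obs <- series$observed
  if (sum(obs) < 2) {
    stop("preprocessing error: need at least 2 observed grid points",
         call. = FALSE)
  }
  v <- series$values
  interp <- series$interp
  gmean <- mean(v[obs])
  step_h <- series$step_s / 3600
  max_linear <- round(max_linear_hours / step_h)
  ramp <- round(ramp_hours / step_h)

  r <- rle(obs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (g in which(!r$values)) {
    i0 <- starts[g]
    i1 <- ends[g]
    len <- i1 - i0 + 1
    left <- if (i0 > 1) v[i0 - 1] else gmean
    right <- if (i1 < length(v)) v[i1 + 1] else gmean
    if (len <= max_linear) {
      v[i0:i1] <- left + (right - left) * seq_len(len) / (len + 1)
      interp[i0:i1] <- "linear"
    } else {
      nr <- min(ramp, floor(len / 2))
      if (nr > 0) {
        v[i0:(i0 + nr - 1)] <- left + (gmean - left) * seq_len(nr) / (nr + 1)
        v[(i1 - nr + 1):i1] <- gmean + (right - gmean) *
          seq_len(nr) / (nr + 1)
        interp[i0:(i0 + nr - 1)] <- "linear"
        interp[(i1 - nr + 1):i1] <- "linear"
      }
      if (len > 2 * nr) {
        v[(i0 + nr):(i1 - nr)] <- gmean
        interp[(i0 + nr):(i1 - nr)] <- "mean-fill"
      }
    }
  }
  series$values <- v
  series$interp <- interp
  series$fill_mean <- gmean
  series
}

#' z-standardise a gap-filled series
#'
#' Subtracts the mean and divides by the standard deviation, computed over
#' all grid points (including interpolated ones). The original mean and SD
#' are retained on the object for reporting.
#'
#' @param series A gap-filled `hr_series`.
#' @return The standardised series (`standardised = TRUE`, mean 0, SD 1).
#' @export
zscore <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  if (anyNA(series$values)) {
    stop("preprocessing error: fill gaps before standardising", call. = FALSE)
  }
  s <- stats::sd(series$values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: constant series cannot be standardised",
         call. = FALSE)
  }
  series$mean_bpm <- mean(series$values)
  series$sd_bpm <- s
  series$values <- (series$values - series$mean_bpm) / s
  series$standardised <- TRUE
  series
}

#' Resample, interpolate and standardise in one step
#'
#' @param raw An `hr_raw` stream.
#' @param ... Passed to [fill_gaps()].
#' @return List: `series` (standardised `hr_series`), `adherence`
#'   (the [compute_adherence()] report).
#' @export
preprocess_heart_rate <- function(raw, ...) {
  list(series = zscore(fill_gaps(resample_to_grid(raw), ...)),
       adherence = compute_adherence(raw))
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %s: %d points @ %ds from %s%s\n",
              x$participant_id, length(x$values), x$step_s,
              format_timestamp(x$start_time),
              if (isTRUE(x$standardised)) " (z-scored)" else ""))
  invisible(x)
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf(
    "<adherence> %.1f%% over %d h (%.1f months); cycle-eligible: %s (%s)\n",
    100 * x$adherence, x$total_hours, x$recording_months,
    x$eligible_cycles, x$reason))
  invisible(x)
}
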