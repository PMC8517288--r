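# Cohort-level aggregation: normalised spectra and their cohort average,
# cycle-class prevalence counts, Kolmogorov-Smirnov comparison of period
# distributions, demographic aggregates, and result writing.

#' Normalise a power curve to [0, 1]
#'
#' Subtracts the minimum and divides by the range, per participant, so
#' spectra with very different absolute power can be overlaid and
#' averaged.
#'
#' @param power Numeric vector (or a `wavelet_spectrum`).
#' @return Numeric vector with min 0 and max 1.
#' @export
normalize_power <- function(power) {
  if (inherits(power, "wavelet_spectrum")) power <- power$power
  rng <- range(power)
  if (diff(rng) == 0) stop("constant power curve cannot be normalised",
                           call. = FALSE)
  (power - rng[1]) / diff(rng)
}

#' Cohort-average normalised wavelet power
#'
#' Interpolates each participant's normalised global power onto a common
#' log-period grid and averages pointwise. Periods outside a
#' participant's admissible range (beyond their cone-of-influence
#' maximum) are excluded from that participant's contribution, so the
#' per-period denominator is the number of participants who could have
#' observed that period.
#'
#' @param spectra List of `wavelet_spectrum` objects.
#' @param grid_periods Optional common period grid (hours); defaults to a
#'   log-spaced grid spanning the cohort's admissible periods at 16
#'   points per octave.
#' @return data.frame: `period_hours`, `mean_power`, `n_contributing`.
#' @export
cohort_spectrum_average <- function(spectra, grid_periods = NULL) {
  if (length(spectra) == 0) stop("empty cohort", call. = FALSE)
  if (is.null(grid_periods)) {
    lo <- min(vapply(spectra, function(s) min(s$period_hours), numeric(1)))
    hi <- max(vapply(spectra, function(s) max(s$period_hours), numeric(1)))
    grid_periods <- 2^seq(log2(lo), log2(hi), by = 1 / 16)
  }
  mat <- vapply(spectra, function(s) {
    np <- normalize_power(s)
    out <- stats::approx(log(s$period_hours), np, xout = log(grid_periods),
                         rule = 1)$y
    out[grid_periods > s$coi_max_hours | grid_periods < s$coi_min_hours] <- NA
    out
  }, numeric(length(grid_periods)))
  mat <- matrix(mat, nrow = length(grid_periods))
  data.frame(period_hours = grid_periods,
             mean_power = rowMeans(mat, na.rm = TRUE),
             n_contributing = rowSums(!is.na(mat)))
}

#' Cycle and phase-locking prevalence counts
#'
#' Counts, per participant group, how many participants have at least one
#' significant cycle of each class (ultradian, circadian, multiday, and
#' the multiday sub-classes about-weekly and about-monthly), and — among
#' participants eligible for seizure analysis — how many have at least
#' one cycle of that class with significantly phase-locked events.
#'
#' @param results List of participant result lists as returned by
#'   [analyze_participant()] (each with `group`, `cycles`, and optionally
#'   `phase_locking`, `eligible_seizures`).
#' @return data.frame: `group`, `n`, one column per cycle class, and
#'   `locked_*` columns restricted to eligible participants.
#' @export
prevalence_counts <- function(results) {
  classes <- c("ultradian", "circadian", "multiday")
  subs <- c("about-weekly", "about-monthly")
  groups <- unique(vapply(results, function(r) r$group %||% "all",
                          character(1)))
  has_class <- function(r, cl) {
    pk <- r$cycles$peaks
    if (is.null(pk) || nrow(pk) == 0) return(FALSE)
    cl %in% pk$class || cl %in% pk$subclass
  }
  locked_class <- function(r, cl) {
    pl <- r$phase_locking
    if (is.null(pl) || nrow(pl) == 0) return(FALSE)
    sig <- pl[pl$significant, , drop = FALSE]
    nrow(sig) > 0 && (cl %in% sig$class ||
                      cl %in% sig$subclass[!is.na(sig$subclass)])
  }
  if (length(results) == 0) {
    cols <- c("group", "n", "n_eligible",
              gsub("-", "_", c(classes, subs)),
              paste0("locked_", gsub("-", "_", c(classes, subs))))
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                             length(cols)), cols))
    out$group <- character(0)
    return(out)
  }
  rows <- lapply(groups, function(g) {
    rs <- Filter(function(r) identical(r$group %||% "all", g), results)
    eligible <- Filter(function(r) isTRUE(r$eligible_seizures), rs)
    row <- data.frame(group = g, n = length(rs),
                      n_eligible = length(eligible))
    for (cl in c(classes, subs)) {
      row[[gsub("-", "_", cl)]] <-
        sum(vapply(rs, has_class, logical(1), cl = cl))
      row[[paste0("locked_", gsub("-", "_", cl))]] <-
        sum(vapply(eligible, locked_class, logical(1), cl = cl))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of period distributions
#'
#' Compares the pooled per-participant cycle periods of two groups with
#' the two-sided asymptotic two-sample KS test.
#'
#' @param periods_a,periods_b Numeric vectors of cycle periods.
#' @return List: `statistic`, `p`.
#' @export
compare_distributions_ks <- function(periods_a, periods_b) {
  if (length(periods_a) == 0 || length(periods_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(periods_a, periods_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Mean and SD of demographic columns
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation per
#' numeric column, rounded to one decimal as conventionally reported in
#' cohort demographic tables.
#'
#' @param demographics data.frame of numeric per-participant columns.
#' @param digits Rounding digits (default 1; NA disables rounding).
#' @return data.frame: `column`, `mean`, `sd`, `n`.
#' @export
demographics_summary <- function(demographics, digits = 1) {
  demographics <- as.data.frame(demographics)
  num <- vapply(demographics, is.numeric, logical(1))
  if (nrow(demographics) == 0 || !any(num)) {
    stop("empty cohort or no numeric columns", call. = FALSE)
  }
  cols <- names(demographics)[num]
  out <- do.call(rbind, lapply(cols, function(cl) {
    x <- demographics[[cl]]
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else NA_real_
    if (!is.na(digits)) {
      m <- round(m, digits)
      s <- round(s, digits)
    }
    data.frame(column = cl, mean = m, sd = s, n = length(x))
  }))
  rownames(out) <- NULL
  out
}

#' Demographics of the motivating epilepsy cohort
#'
#' The published per-participant demographic table of the 31-adult
#' epilepsy arm of the wearable cohort this package's methods were
#' developed around: sex, age (years), recording length (months),
#' seizures reported during wearable monitoring, adherence (%), and mean
#' heart rate (BPM). Useful for checking aggregate summaries and as a
#' realistic reference for synthetic-cohort parameters.
#'
#' @return data.frame with 31 rows: `participant`, `sex`, `age_years`,
#'   `recording_months`, `n_seizures`, `adherence_pct`, `mean_bpm`.
#' @export
epilepsy_cohort_demographics <- function() {
  data.frame(
    participant = paste0("P", 1:31),
    sex = c("F", "F", "M", "M", "M", "F", "F", "F", "F", "M", "F", "F",
            "F", "M", "M", "M", "F", "F", "F", "F", "M", "F", "F", "F",
            "M", "F", "F", "F", "F", "F", "M"),
    age_years = c(83, 33, 55, 27, 27, 33, 30, 30, 48, 69, 55, 51, 29, 70,
                  60, 36, 30, 51, 20, 25, 31, 22, 40, 50, 26, 69, 27, 28,
                  26, 29, 36),
    recording_months = c(16.5, 12.7, 14.5, 5.6, 14.8, 4.0, 20.6, 4.1,
                         13.2, 13.4, 19.3, 5.2, 6.9, 20.2, 4.8, 6.9, 6.2,
                         10.8, 21.8, 21.3, 8.1, 9.3, 22.3, 14.7, 6.2,
                         4.2, 13.6, 10.8, 9.0, 15.8, 16.5),
    n_seizures = c(105, 3, 213, 65, 120, 37, 29, 2, 0, 67, 32, 0, 169,
                   24, 20, 29, 7, 5, 103, 7, 21, 0, 416, 4, 3, 14, 148,
                   6, 251, 58, 286),
    adherence_pct = c(100, 97, 88, 92, 94, 80, 100, 80, 99, 100, 99, 80,
                      80, 82, 80, 80, 80, 80, 82, 94, 93, 99, 99, 92, 80,
                      98, 80, 97, 89, 83, 92),
    mean_bpm = c(93, 70, 79, 80, 65, 89, 78, 70, 62, 70, 69, 77, 82, 75,
                 84, 76, 69, 74, 87, 77, 72, 85, 73, 62, 64, 70, 86, 79,
                 78, 88, 62),
    stringsAsFactors = FALSE
  )
}

#' Write per-participant and cohort results to disk
#'
#' Writes one JSON record per participant, delimited-text summary tables
#' (prevalence, cohort spectrum, demographics summary when available) and
#' a run manifest with configuration, seed and package version. Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param results List of participant result lists
#'   ([analyze_participant()] output).
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional list with precomputed cohort tables
#'   (`prevalence`, `spectrum_average`, `demographics_summary`).
#' @param manifest Named list merged into the run manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, cohort = NULL, manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- character(0)
  if (length(results) == 0) warning("empty cohort: writing manifest only")
  for (r in results) {
    id <- r$participant_id %||% "participant"
    rec <- list(
      participant_id = id,
      group = r$group %||% NA,
      adherence = if (!is.null(r$adherence)) {
        r$adherence[c("adherence", "recording_months", "eligible_cycles")]
      },
      cycles = if (!is.null(r$cycles)) r$cycles$peaks,
      eligible_seizures = r$eligible_seizures %||% NA,
      phase_locking = r$phase_locking
    )
    p <- file.path(out_dir, paste0(id, ".json"))
    jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if (length(results) > 0) {
    prev <- cohort$prevalence %||% prevalence_counts(results)
    p <- file.path(out_dir, "prevalence.csv")
    utils::write.csv(prev, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(cohort$spectrum_average)) {
    p <- file.path(out_dir, "cohort_spectrum.csv")
    utils::write.csv(cohort$spectrum_average, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(cohort$demographics_summary)) {
    p <- file.path(out_dir, "demographics.csv")
    utils::write.csv(cohort$demographics_summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mf <- c(list(package = "hrcycles",
               version = as.character(utils::packageVersion("hrcycles")),
               n_participants = length(results)),
          manifest)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(mf, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
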