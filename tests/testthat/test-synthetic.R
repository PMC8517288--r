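# Synthetic generator: construction rules, determinism, gap injection,
# and the von Mises phase law of generated events.

test_that("degenerate configs produce the forced streams", {
  cfg <- synthetic_config(duration_days = 2, cycles = list(), noise_sd = 0,
                          baseline_bpm = 70, seed = 1)
  gen <- generate_heart_rate(cfg)
  expect_true(all(gen$stream$bpm == 70))

  cfg <- synthetic_config(duration_days = 3, sample_interval_s = 5,
                          cycles = list(cycle_spec(24, 5)), noise_sd = 0,
                          baseline_bpm = 70, seed = 1)
  gen <- generate_heart_rate(cfg)
  expect_true(all(gen$stream$bpm >= 65 - 1e-9 & gen$stream$bpm <= 75 + 1e-9))
  # maxima of a drift-free 24 h sinusoid are exactly 24 h apart
  bpm <- gen$stream$bpm
  day <- 24 * 720 # samples per day at 5 s
  m1 <- which.max(bpm[1:day])
  m2 <- day + which.max(bpm[(day + 1):(2 * day)])
  expect_equal(as.numeric(difftime(gen$stream$timestamp[m2],
                                   gen$stream$timestamp[m1],
                                   units = "hours")), 24)
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(cycle_spec(-1, 1), "period_hours")
  expect_error(cycle_spec(24, -1), "amplitude")
  expect_error(cycle_spec(24, 1, initial_phase = 7), "initial_phase")
  expect_error(synthetic_config(duration_days = 0.5), "duration_days")
  expect_error(synthetic_config(noise_ar1 = 1), "noise_ar1")
  expect_error(gap_spec(2, min_hours = 5, max_hours = 1), "min_hours")
  expect_error(event_config(10, kappa = -1), "kappa")
})

test_that("identical configs and seeds reproduce streams byte-identically", {
  cfg <- synthetic_config(duration_days = 2, seed = 11,
                          cycles = list(cycle_spec(24, 3, phase_drift_sd = 0.2)))
  g1 <- generate_heart_rate(cfg)
  g2 <- generate_heart_rate(cfg)
  expect_identical(g1$stream, g2$stream)
  expect_identical(g1$truth$phase_series, g2$truth$phase_series)
})

test_that("true phase series lies in [0, 2*pi) on the analysis grid", {
  cfg <- synthetic_config(duration_days = 5, sample_interval_s = 300,
                          cycles = list(cycle_spec(24, 3, phase_drift_sd = 0.3)),
                          seed = 2)
  tr <- generate_heart_rate(cfg)$truth
  expect_true(all(tr$phase_series >= 0 & tr$phase_series < 2 * pi))
  expect_equal(nrow(tr$phase_series), length(tr$grid_hours))
})

test_that("gap injection removes the configured segments and nothing else", {
  cfg <- coarse_config(duration_days = 365, cycles = list(), noise_sd = 1,
                       seed = 3)
  stream <- generate_heart_rate(cfg)$stream

  out0 <- inject_gaps(stream, gap_spec(0, 1, 2), seed = 1)
  expect_identical(out0$stream, stream)
  expect_equal(out0$removed_fraction, 0)

  # stress case: a single 1354 h outage on a year-long record
  out1 <- inject_gaps(stream, gap_spec(1, 1354, 1354, "fixed"), seed = 4)
  expect_equal(nrow(out1$gaps), 1)
  expect_equal(out1$gaps$duration_hours, 1354)
  removed <- nrow(stream) - nrow(out1$stream)
  expect_equal(removed, 1354 * 12, tolerance = 1e-9)
  expect_true(all(out1$stream$bpm %in% stream$bpm))
  # remaining samples untouched
  kept <- stream$timestamp %in% out1$stream$timestamp
  expect_identical(stream$bpm[kept], out1$stream$bpm)

  outa <- inject_gaps(stream, gap_spec(10, 0.1, 48), seed = 5)
  outb <- inject_gaps(stream, gap_spec(10, 0.1, 48), seed = 5)
  expect_identical(outa$stream, outb$stream)
  expect_identical(outa$gaps, outb$gaps)

  expect_error(inject_gaps(stream[1:10, ], gap_spec(2, 1354, 1354, "fixed")),
               "gap placement")
})

test_that("gap accounting matches the configured missing fraction", {
  cfg <- coarse_config(duration_days = 100, cycles = list(), noise_sd = 1,
                       seed = 6)
  stream <- generate_heart_rate(cfg)$stream
  span_h <- as.numeric(difftime(max(stream$timestamp), min(stream$timestamp),
                                units = "hours"))
  out <- inject_gaps(stream, gap_spec(5, 24, 24, "fixed"), seed = 7)
  expect_equal(out$removed_fraction, 5 * 24 / span_h,
               tolerance = 5 * (300 / 3600) / span_h * 2)
})

test_that("generated events follow the requested von Mises phase law", {
  cfg <- coarse_config(duration_days = 60,
                       cycles = list(cycle_spec(7 * 24, 2)), noise_sd = 0,
                       seed = 8)
  truth <- generate_heart_rate(cfg)$truth

  # kappa -> infinity: all phases in a narrow arc at the preferred phase
  ev <- generate_phase_locked_events(
    truth, event_config(50, kappa = 500, preferred_phase = pi / 2, seed = 1))
  ph <- attr(ev, "true_phase")
  expect_true(all(abs(ph - pi / 2) < 0.3))
  expect_gt(si_unbinned(ph)$si, 0.99)

  # kappa = 0: SI shrinks toward 0 for large n
  ev0 <- generate_phase_locked_events(
    truth, event_config(400, kappa = 0, seed = 2))
  expect_lt(si_unbinned(attr(ev0, "true_phase"))$si, 0.15)

  # event times strictly inside the recording span
  expect_true(all(ev >= truth$start_time))
  expect_true(all(ev <= truth$start_time + truth$duration_days * 86400))

  # determinism
  ev2 <- generate_phase_locked_events(
    truth, event_config(50, kappa = 500, preferred_phase = pi / 2, seed = 1))
  expect_identical(as.numeric(ev), as.numeric(ev2))
})

test_that("mean SI of von Mises event draws matches the Bessel ratio", {
  # mean resultant length of a von Mises sample converges to I1(k)/I0(k)
  cfg <- coarse_config(duration_days = 30,
                       cycles = list(cycle_spec(24, 2)), noise_sd = 0,
                       seed = 9)
  truth <- generate_heart_rate(cfg)$truth
  n_rep <- 200
  n_ev <- 100
  for (kappa in c(0, 1, 2, 5)) {
    target <- besselI(kappa, 1) / besselI(kappa, 0)
    si <- vapply(seq_len(n_rep), function(r) {
      ev <- generate_phase_locked_events(
        truth, event_config(n_ev, kappa = kappa, preferred_phase = 1,
                            seed = 1000 * kappa + r))
      si_unbinned(attr(ev, "true_phase"))$si
    }, numeric(1))
    se <- stats::sd(si) / sqrt(n_rep)
    # R_bar is biased upward at kappa = 0 (E ~ 1/sqrt(n)); allow that term
    bias_allow <- if (kappa == 0) 1 / sqrt(n_ev) else 0
    expect_lt(abs(mean(si) - target), 3 * se + bias_allow + 0.01,
              label = sprintf("kappa %g: |%.4f - %.4f|", kappa, mean(si),
                              target))
  }
})

test_that("written streams and diaries round-trip through the readers", {
  cfg <- coarse_config(duration_days = 2, noise_sd = 2, seed = 10,
                       cycles = list(cycle_spec(24, 3)))
  gen <- generate_heart_rate(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_heart_rate_table(gen$stream, f)
  raw <- read_heart_rate_table(f, participant_id = "RT")
  expect_equal(length(raw$bpm), nrow(gen$stream))
  expect_equal(raw$bpm, gen$stream$bpm, tolerance = 1e-6)

  ev <- gen$stream$timestamp[c(10, 20, 30)]
  fd <- withr::local_tempfile(fileext = ".csv")
  write_diary(ev, fd, labels = data.frame(awareness = c("aware",
                                                        "impaired-awareness",
                                                        "aware")))
  diary <- read_seizure_diary(fd, participant_id = "RT")
  expect_equal(as.numeric(diary$events), as.numeric(ev))
  expect_equal(diary$labels$awareness[2], "impaired-awareness")
})
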