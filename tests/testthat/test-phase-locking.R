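# Circular phase-locking statistics: event-phase mapping, binning, SI,
# Hodges-Ajne omnibus test, Bonferroni correction and surrogates.

make_cycle <- function(phase, usable = NULL, class = "multiday",
                       centre = 168) {
  structure(list(
    participant_id = "T", band = design_band(centre), filtered = sin(phase),
    phase = phase, usable = usable %||% rep(TRUE, length(phase)),
    class = class, subclass = NA_character_,
    start_time = as.POSIXct("2020-01-01", tz = "UTC"), step_s = 300L
  ), class = "filtered_cycle")
}

test_that("events map to the phase of the nearest grid point", {
  phase <- wrap_2pi(seq(0, 8 * pi, length.out = 2000))
  cyc <- make_cycle(phase)
  t0 <- cyc$start_time
  # exactly on a grid point
  eps <- map_events_to_phase(t0 + 10 * 300, cyc)
  expect_equal(eps$phases, phase[11])
  # 2 minutes after a grid point -> nearest point's phase
  eps <- map_events_to_phase(t0 + 10 * 300 + 120, cyc)
  expect_equal(eps$phases, phase[11])
  # before the recording start -> excluded
  eps <- map_events_to_phase(t0 - 3600, cyc)
  expect_equal(eps$n_events, 0)
  expect_equal(eps$n_excluded, 1)
  # on an unusable grid point -> excluded
  usable <- rep(TRUE, 2000); usable[11] <- FALSE
  eps <- map_events_to_phase(t0 + 10 * 300, make_cycle(phase, usable))
  expect_equal(eps$n_excluded, 1)
})

test_that("the 20-event eligibility gate is strict", {
  s <- series_from_values(rnorm(288))
  t0 <- s$start_time
  expect_true(eligibility_gate(t0 + 60 * (1:20), s))
  expect_false(eligibility_gate(t0 + 60 * (1:19), s))
  expect_false(eligibility_gate(t0[0], s))
  # events outside the recording span do not count
  ev <- c(t0 + 60 * (1:19), t0 + 365 * 86400)
  expect_false(eligibility_gate(ev, s))
})

test_that("phase binning uses half-open equal bins over [0, 2*pi)", {
  d <- bin_phases(0, n_bins = 18)
  expect_equal(d$counts[1], 1) # phase 0 falls in bin 1
  d <- bin_phases(rep(pi / 2, 7), n_bins = 18)
  expect_equal(max(d$counts), 7)
  expect_equal(sum(d$counts), 7)
  d <- bin_phases(2 * pi / 18 * (0:17) + pi / 18, n_bins = 18)
  expect_true(all(d$counts == 1))
  expect_lt(max(diff(d$edges)) - min(diff(d$edges)), 1e-12)
  # circadian cycles default to 24 bins, others to 18
  phase <- wrap_2pi(seq(0, 20 * pi, length.out = 3000))
  eps24 <- map_events_to_phase(as.POSIXct("2020-01-01", tz = "UTC") + 300,
                               make_cycle(phase, class = "circadian",
                                          centre = 24))
  expect_equal(bin_phases(eps24)$n_bins, 24L)
  eps18 <- map_events_to_phase(as.POSIXct("2020-01-01", tz = "UTC") + 300,
                               make_cycle(phase))
  expect_equal(bin_phases(eps18)$n_bins, 18L)
})

test_that("SI matches direct complex-sum values", {
  # perfect alignment: all events in the bin centred at pi/2
  d <- bin_phases(rep(pi / 2, 10), n_bins = 18)
  r <- synchronization_index(d)
  expect_equal(r$si, 1)
  expect_equal(r$preferred_phase, d$centres[which.max(d$counts)])
  # uniform counts -> SI 0
  d <- structure(list(n_bins = 18L, edges = seq(0, 2 * pi, length.out = 19),
                      centres = seq(0, 2 * pi, length.out = 19)[-19] +
                        pi / 18, counts = rep(3L, 18), n_events = 54L),
                 class = "phase_distribution")
  expect_lt(synchronization_index(d)$si, 1e-12)
  # counts {2 at centre 0, 1 at centre pi/2} -> |2 + i| / 3
  d <- structure(list(n_bins = 4L, edges = seq(0, 2 * pi, length.out = 5),
                      centres = c(0, pi / 2, pi, 3 * pi / 2),
                      counts = c(2L, 1L, 0L, 0L), n_events = 3L),
                 class = "phase_distribution")
  r <- synchronization_index(d)
  expect_equal(r$si, sqrt(5) / 3, tolerance = 1e-12)
  expect_equal(r$preferred_phase, atan2(1, 2), tolerance = 1e-12)
  expect_error(synchronization_index(bin_phases(numeric(0), n_bins = 18)),
               "zero events")
})

test_that("binned SI differs from unbinned SI by at most the bin width", {
  set.seed(8)
  for (i in 1:50) {
    ph <- sample_von_mises_for_test(n = sample(20:200, 1),
                                    mu = runif(1, 0, 2 * pi),
                                    kappa = runif(1, 0, 4))
    for (nb in c(18, 24)) {
      b <- synchronization_index(bin_phases(ph, n_bins = nb))$si
      u <- si_unbinned(ph)$si
      expect_lte(abs(b - u), 2 * sin(pi / (2 * nb)) + 1e-12)
    }
  }
})

test_that("Hodges-Ajne exact p matches hand-computed cases", {
  # n = 10 all inside one half-circle: m = 0, p = 10/512
  ph <- seq(0.1, pi - 0.1, length.out = 10)
  r <- hodges_ajne_test(ph)
  expect_equal(r$m, 0L)
  expect_equal(r$p, 10 / 512)
  # n = 4 on the quadrants: m = 1, p = 1
  r <- hodges_ajne_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r$m, 1L)
  expect_equal(r$p, 1)
  expect_error(hodges_ajne_test(c(0, 1, 2)), "at least 4")
  # p always in (0, 1], including the large-sample branch
  set.seed(9)
  for (n in c(8, 40, 80, 300)) {
    p <- hodges_ajne_test(runif(n, 0, 2 * pi))$p
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Hodges-Ajne agrees with the rotating half-plane oracle", {
  set.seed(10)
  for (i in 1:120) {
    n <- sample(4:12, 1)
    ph <- runif(n, 0, 2 * pi)
    m_bf <- hodges_ajne_m_bruteforce(ph)
    r <- hodges_ajne_test(ph)
    expect_equal(r$m, m_bf)
    expect_equal(r$p, min(2^(1 - n) * (n - 2 * m_bf) * choose(n, m_bf), 1))
  }
})

test_that("the omnibus test has power against concentrated alternatives", {
  # kappa = 2, n = 50: rejection rate at alpha = 0.05 over 500 replicates
  set.seed(11)
  rej <- vapply(1:500, function(i) {
    hodges_ajne_test(sample_von_mises_for_test(50, pi, 2))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.80)
})

test_that("Bonferroni correction divides alpha by the test count", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(5), 0.01)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("surrogate SI distributions behave at the extremes", {
  phase <- wrap_2pi(seq(0, 40 * pi, length.out = 5000))
  cyc <- make_cycle(phase)
  s1 <- surrogate_si_distribution(cyc, n_events = 30, n_surrogates = 200,
                                  seed = 3, observed_si = 1)
  expect_equal(s1$quantile, 1) # perfectly locked events beat all surrogates
  s2 <- surrogate_si_distribution(cyc, n_events = 30, n_surrogates = 200,
                                  seed = 3)
  expect_identical(s1$si, s2$si) # fixed seed -> identical distribution
  expect_true(all(s1$si >= 0 & s1$si <= 1))
  expect_error(surrogate_si_distribution(cyc, 30, n_surrogates = 50),
               "100 surrogates")
  expect_error(
    surrogate_si_distribution(make_cycle(phase, usable = rep(FALSE, 5000)),
                              30),
    "empty")
})

test_that("surrogate quantiles of null events are roughly uniform", {
  phase <- wrap_2pi(seq(0, 40 * pi, length.out = 5000))
  cyc <- make_cycle(phase)
  set.seed(12)
  q <- vapply(1:200, function(i) {
    idx <- sample.int(5000, 30, replace = TRUE)
    obs <- synchronization_index(bin_phases(phase[idx], n_bins = 18))$si
    surrogate_si_distribution(cyc, 30, n_surrogates = 200, seed = 5000 + i,
                              observed_si = obs)$quantile
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(q, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("preferred phase recovers the implanted event concentration", {
  cfg <- coarse_config(duration_days = 30,
                       cycles = list(cycle_spec(7 * 24, 2)), noise_sd = 0,
                       seed = 13)
  truth <- generate_heart_rate(cfg)$truth
  # theoretical coverage of the 15-degree band for the circular mean at
  # n = 100: ~92% at kappa 1 (SE ~ 8.6 deg), >99% at kappa 2 and 5
  coverage_floor <- c("1" = 0.80, "2" = 0.95, "5" = 0.95)
  for (kappa in c(1, 2, 5)) {
    ok <- vapply(1:40, function(r) {
      ev <- generate_phase_locked_events(
        truth, event_config(100, kappa = kappa, preferred_phase = 2,
                            seed = 7000 * kappa + r))
      est <- synchronization_index(
        bin_phases(attr(ev, "true_phase"), n_bins = 18))$preferred_phase
      abs((est - 2 + pi) %% (2 * pi) - pi) <= 15 * pi / 180
    }, logical(1))
    expect_gte(mean(ok), coverage_floor[[as.character(kappa)]])
  }
})

test_that("assess_phase_locking assembles per-cycle results", {
  sim <- simulate_participant(
    coarse_config(duration_days = 120, seed = 14),
    events = event_config(60, target_cycle = 2, kappa = 3,
                          preferred_phase = pi / 2, seed = 15))
  pre <- preprocess_heart_rate(sim$raw)
  cs <- detect_cycles(pre$series)
  fc <- extract_cycles(pre$series, cs)
  res <- assess_phase_locking(sim$diary, fc, pre$series,
                              n_surrogates = 200, seed = 16)
  expect_equal(nrow(res), length(fc))
  expect_true(all(res$n_tests == length(fc)))
  expect_equal(res$alpha_corrected, rep(0.05 / length(fc), length(fc)))
  expect_true(all(res$si >= 0 & res$si <= 1, na.rm = TRUE))
  # the 7 d cycle row is the locked one
  i7 <- which.min(abs(res$centre_period_hours - 168))
  expect_true(res$significant[i7])

  # no cycles -> empty result frame
  empty <- assess_phase_locking(sim$diary, list(), pre$series)
  expect_equal(nrow(empty), 0)

  # ineligible diaries are refused unless overridden
  short <- seizure_diary(sim$diary$events[1:5])
  expect_error(assess_phase_locking(short, fc, pre$series), "not eligible")
  res5 <- assess_phase_locking(short, fc, pre$series,
                               require_eligible = FALSE,
                               n_surrogates = 100, seed = 1)
  expect_false(any(res5$significant))
})
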