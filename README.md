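# hrcycles

Detection of circadian and multiday cycles in long-term wearable
heart-rate recordings, and quantification of how tightly clinical
events — epileptic seizures reported in a mobile diary — lock to the
phase of those cycles.

## Who this is for

Researchers in chronobiology, epileptology and digital health working
with months-long streams of photoplethysmography heart rate from
consumer wearables (nominal ~5-second sampling, realistic device
outages) alongside timestamped event diaries. The package provides the
complete, tested analysis chain from raw samples to cohort tables, plus
a synthetic-data generator with ground truth so the whole pipeline can
be validated without access to any deployment.

## What it computes

**Cycle detection.** The heart-rate stream is averaged onto a regular
5-minute grid, device outages are interpolated (linear up to 2 h;
longer gaps mean-filled with 1-h edge ramps), and the series is
z-standardised. A continuous Morlet wavelet transform (ω₀ = 6,
log-spaced scales) yields the global (time-averaged) wavelet power per
period; periods whose power exceeds the 99% chi-square threshold
against a fitted AR(1) red-noise background, with degrees of freedom
ν = 2√(1 + (nₐΔt/γs)²), are significant cycles. Admissible periods run
from 2.4 h to a quarter of the recording length (≥4 observed cycles),
outside the cone of influence; a sparsity criterion keeps only the
strongest peak within any retained cycle's pass band.

**Cycle extraction.** Each significant period T is isolated with a
second-order zero-phase Butterworth band-pass with cut-off periods
2T/3 and 4T/3 (±33.3%: a 24-h cycle gets 16–32 h, a 9-d cycle 6–12 d, a
30-d cycle 20–40 d), and its instantaneous phase is the analytic-signal
angle shifted so cycle peaks sit at π/2 and troughs at 3π/2.

**Phase-locking.** Event times map to the phase of the nearest grid
point; phases are binned (24 bins for circadian cycles, 18 otherwise)
and summarised by the synchronisation index SI = |Σ cₖ e^{iθₖ}|/n
(mean resultant length: 0 = uniform, 1 = perfect alignment) with the
resultant direction as the preferred phase. Uniformity is tested with
the Hodges-Ajne omnibus test (exact p = 2^{1−n}(n−2m)·C(n,m) for
n ≤ 50), Bonferroni-corrected across each participant's cycles, and the
observed SI is located in a surrogate null distribution built from
uniform random event times mapped through the real phase series.
Participants need ≥20 events during the recording.

**Cohort summaries.** Min-max-normalised spectra averaged on a common
log-period grid, prevalence counts per cycle class (ultradian /
circadian / multiday, about-weekly 5–9 d, about-monthly 28–32 d),
two-sample Kolmogorov-Smirnov comparisons, and demographic aggregates.

## Worked example

Simulate a 180-day participant (5-second sampling, 75 BPM baseline,
cycles at 24 h / 7 d / 30 d, AR(1) noise) with 100 seizures von
Mises-locked (κ = 3) to the 7-day cycle, and run the full analysis:

```r
library(hrcycles)
sim <- simulate_participant(
  synthetic_config(seed = 42),
  events = event_config(100, target_cycle = 2, kappa = 3, seed = 7))
pre <- preprocess_heart_rate(sim$raw)
pre$adherence
#> <adherence> 100.0% over 4320 h (5.9 months); cycle-eligible: TRUE (eligible)

cycles <- detect_cycles(pre$series)
cycles
#> <cycle_set> SIM1: 3 significant cycle(s) in 180.0 days
#>   period_hours     power band_low_hours band_high_hours     class      subclass
#> 1     23.84367  129.1175       15.89578        31.79156 circadian          <NA>
#> 2    167.50199  602.2744      111.66799       223.33598  multiday  about-weekly
#> 3    730.64885 2473.9740      487.09923       974.19847  multiday about-monthly

filtered <- extract_cycles(pre$series, cycles)
locking <- assess_phase_locking(sim$diary, filtered, pre$series, seed = 3)
locking[c("centre_period_hours", "class", "si", "preferred_phase",
          "omnibus_p", "significant", "surrogate_quantile")]
#>   centre_period_hours     class    si preferred_phase omnibus_p significant
#> 1                23.8 circadian 0.141           2.012  1.41e-01       FALSE
#> 2               167.5  multiday 0.784           1.679  1.14e-18        TRUE
#> 3               730.6  multiday 0.101           0.281  3.93e-01       FALSE
#>   surrogate_quantile
#> 1              0.867
#> 2              1.000
#> 3              0.568
```

All three implanted periods are recovered within the scale resolution
(23.8 h, 6.98 d, 30.4 d). Only the 7-day cycle shows significant
phase-locking: SI = 0.78 with preferred phase 1.68 rad (truth: π/2 ≈
1.57, the cycle peak), omnibus p = 1.1×10⁻¹⁸ far below the Bonferroni
level 0.05/3, and an SI above all 1,000 surrogates. The circadian and
30-day cycles, to which the events were not locked, stay
non-significant.

A thin command-line front end over the same functions ships in
`inst/cli/hrcycles.R` with subcommands `simulate`, `preprocess`,
`detect`, `extract`, `phaselock` and `report`.

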