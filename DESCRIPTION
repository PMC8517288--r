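Package: hrcycles
Title: Multiday Heart-Rate Cycle Detection and Seizure Phase-Locking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting circadian and multiday cycles in
    long-term wearable heart-rate recordings and for quantifying the
    phase-locking of clinical events (epileptic seizures) to those
    cycles. Implements 5-minute resampling with interpolation and
    adherence rules for wearable photoplethysmography streams, a
    continuous Morlet wavelet transform with a time-averaged
    red-noise significance test and cone-of-influence restriction,
    zero-phase Butterworth band-pass extraction of significant cycles
    with Hilbert instantaneous phase, circular phase-locking
    statistics (synchronisation index, Hodges-Ajne omnibus test,
    Bonferroni correction, surrogate null distributions), cohort-level
    summaries, and a synthetic-data generator with implanted cycles,
    device-like gaps and phase-locked events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
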