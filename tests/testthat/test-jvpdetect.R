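# build a jvp_filtered record from a raw displacement trace
filtered_from <- function(values, fs = 250, spec = filter_spec()) {
  apply_filters(displacement_signal(values, fs), spec)
}

# synthetic JVP displacement at the frame rate (no radar in the loop)
jvp_displacement <- function(duration, rate = 250, cardiac_rate = 1.13,
                             noise_sd = 0, seed = 1) {
  spec <- jvp_waveform_spec(cardiac_rate = cardiac_rate,
                            respiratory_amplitude = 0, noise_sd = noise_sd)
  displacement_signal(synth_jvp_trajectory(spec, duration, rate, seed)$values,
                      rate)
}

test_that("filter designs meet the band specification (frequency-response oracle)", {
  spec <- filter_spec()
  bp <- design_bandpass(spec)
  bs <- design_bandstop(spec)
  expect_length(bp, 1021)
  expect_length(bs, 511)
  # linear phase: both symmetric
  expect_equal(bp, rev(bp))
  expect_equal(bs, rev(bs), tolerance = 1e-12)
  # 2 Hz preserved within passband ripple, 0.2 Hz attenuated >= 40 dB
  expect_gt(20 * log10(fir_gain(bp, 2, 250)), -1)
  expect_lt(20 * log10(fir_gain(bp, 0.2, 250)), -40)
  # bandstop: >= 30 dB at the 1.0 Hz notch centre, passband intact at 2-4 Hz
  expect_lt(20 * log10(fir_gain(bs, 1.0, 250)), -30)
  expect_lt(20 * log10(fir_gain(bs, 0.95, 250)), -29)
  expect_lt(20 * log10(fir_gain(bs, 1.1, 250)), -25)
  expect_gt(20 * log10(fir_gain(bs, 2, 250)), -1)
  expect_gt(20 * log10(fir_gain(bs, 4, 250)), -1)
})

test_that("steady-state tones confirm the cascade response", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  run <- function(f) {
    filt <- filtered_from(sin(2 * pi * f * t), fs)
    steady <- filt$signal$values[(filt$trim[1] + 1):filt$trim[2]]
    sqrt(2 * mean(steady^2))          # sine amplitude estimate
  }
  expect_equal(run(2), 1, tolerance = 0.1)
  expect_lt(run(1.0), 10^(-30 / 20))
  expect_lt(run(0.2), 10^(-40 / 20))
})

test_that("trim bounds equal the combined 765-sample group delay", {
  spec <- filter_spec()
  expect_identical(spec$group_delay, 765L)
  for (n in c(2000L, 5000L)) {
    filt <- filtered_from(stats::rnorm(n))
    expect_identical(filt$trim, c(765L, n - 765L))
  }
  expect_error(filtered_from(stats::rnorm(1530)), "1531")
})

test_that("the filter cascade is linear and time-invariant", {
  set.seed(3)
  a <- stats::rnorm(2000)
  b <- stats::rnorm(2000)
  fa <- filtered_from(a)$signal$values
  fb <- filtered_from(b)$signal$values
  fab <- filtered_from(a + b)
  expect_equal(fab$signal$values, fa + fb, tolerance = 1e-9)
})

test_that("the reference pulse is the most self-consistent cycle", {
  filt <- filtered_from(jvp_displacement(30)$values)
  tmpl <- select_reference_pulse(filt, cardiac_rate_hint = 1.13)
  expect_equal(tmpl$cycle_length, round(250 / 1.13), tolerance = 0)
  # spectral period estimation agrees without the hint (within 10%)
  tmpl2 <- select_reference_pulse(filt)
  expect_lt(abs(tmpl2$cycle_length - 250 / 1.13) / (250 / 1.13), 0.1)

  # a corrupted cycle is never selected
  x <- jvp_displacement(30)$values
  p <- round(250 / 1.13)
  corrupt_start <- 765 + 3 * p + 1
  x[corrupt_start:(corrupt_start + p - 1)] <-
    stats::rnorm(p, sd = stats::sd(x) * 3)
  tmpl3 <- select_reference_pulse(filtered_from(x), cardiac_rate_hint = 1.13)
  expect_false(tmpl3$origin == 765 + 3 * p + 1)

  # too few cycles inside the trim bounds
  short <- filtered_from(jvp_displacement(8)$values)
  expect_error(select_reference_pulse(short, cardiac_rate_hint = 1.13),
               "insufficient cycles")
})

test_that("a perfectly periodic recording returns the lowest-index cycle", {
  p <- 200L
  set.seed(6)
  cycle <- as.numeric(stats::filter(stats::rnorm(p), rep(1 / 21, 21),
                                    circular = TRUE))
  x <- rep(cycle, 20)
  filt <- structure(list(signal = displacement_signal(x, 250),
                         trim = c(0L, length(x)), spec = filter_spec()),
                    class = "jvp_filtered")
  tmpl <- select_reference_pulse(filt, cardiac_rate_hint = 250 / p)
  expect_identical(tmpl$origin, 1L)
})

test_that("template self-match finds every tile with unit correlation", {
  set.seed(9)
  tmpl_vals <- as.numeric(stats::filter(stats::rnorm(150), rep(1 / 11, 11),
                                        circular = TRUE))
  x <- rep(tmpl_vals, 10)
  filt <- structure(list(signal = displacement_signal(x, 250),
                         trim = c(0L, length(x)), spec = filter_spec()),
                    class = "jvp_filtered")
  tmpl <- structure(list(values = tmpl_vals - mean(tmpl_vals),
                         cycle_length = 150L, origin = 1L),
                    class = "pulse_template")
  det <- detect_pulses(filt, tmpl, threshold = 0.8)
  expect_identical(nrow(det$pulses), 10L)
  expect_equal(det$pulses$correlation, rep(1, 10), tolerance = 1e-9)
  expect_equal(det$pulses$start, seq(1, by = 150, length.out = 10))
  # unattainable threshold
  expect_identical(nrow(detect_pulses(filt, tmpl, threshold = 1.0001)$pulses), 0L)
})

test_that("noisy synthetic JVP cycles are detected inside the trim bounds", {
  d <- jvp_displacement(30, noise_sd = 0, seed = 5)
  sig_sd <- stats::sd(d$values)
  noisy <- jvp_displacement(30, noise_sd = sig_sd / sqrt(10), seed = 5)  # 10 dB
  filt <- apply_filters(noisy)
  tmpl <- select_reference_pulse(filt, cardiac_rate_hint = 1.13)
  det <- detect_pulses(filt, tmpl, threshold = 0.8)
  l <- det$pulses$start
  p <- tmpl$cycle_length
  # no accepted pulse overlaps the transient margins
  expect_true(all(l >= 766 & l + p - 1 <= 7500 - 765))
  # ground-truth cardiac lattice anchored at the template's own cycle,
  # restricted to cycles fully inside the usable region
  period <- 250 / 1.13
  truth <- tmpl$origin + (-40:40) * period
  truth <- truth[truth >= 766 & truth + p - 1 <= 7500 - 765]
  hit <- vapply(truth, function(s) any(abs(l - s) <= p / 8), logical(1))
  expect_gte(mean(hit), 0.9)
  # detection count is monotonically non-increasing in threshold
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.97),
                   function(th) nrow(detect_pulses(filt, tmpl, th)$pulses),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # marked peaks are the segment maxima
  seg_max <- vapply(seq_len(nrow(det$pulses)), function(i) {
    s <- det$pulses$start[i]
    max(filt$signal$values[s:(s + p - 1)])
  }, numeric(1))
  expect_equal(det$pulses$peak_value, seg_max)
})

test_that("an in-notch cardiac fundamental is suppressed while harmonics survive", {
  # cardiac rate inside the 0.9-1.1 Hz arterial notch
  x <- jvp_displacement(30, cardiac_rate = 1.0)$values
  fs <- 250
  spec <- filter_spec()
  bp_only <- as.numeric(signal::filter(design_bandpass(spec), 1, x))
  cascade <- as.numeric(signal::filter(design_bandstop(spec), 1, bp_only))
  steady <- 2000:7000
  bandpower <- function(v, lo, hi) {
    sp <- mag_spectrum(v[steady], fs)
    sum(sp$amp[sp$freq >= lo & sp$freq <= hi]^2)
  }
  # fundamental power collapses after the bandstop ...
  expect_lt(bandpower(cascade, 0.9, 1.1) / bandpower(bp_only, 0.9, 1.1), 0.01)
  # ... but the 1.8-4 Hz harmonic content is preserved
  expect_gt(bandpower(cascade, 1.8, 4) / bandpower(bp_only, 1.8, 4), 0.8)
})

test_that("common-frequency synchronization recovers the shared cardiac line", {
  for (cr in c(1.13, 1.5)) {
    jvp <- jvp_displacement(30, cardiac_rate = cr, noise_sd = 20e-6, seed = 2)
    ppg <- synth_ppg(cr, 30, seed = 3)
    est <- common_frequency(jvp, ppg)
    expect_lt(abs(est$frequency - cr), 0.05)
    expect_true(est$confident)
  }
  # uncorrelated white noise: no common line, flagged low-confidence
  set.seed(14)
  wn_jvp <- displacement_signal(stats::rnorm(7500), 250)
  wn_ppg <- displacement_trajectory(273.1, stats::rnorm(8193))
  est_wn <- common_frequency(wn_jvp, wn_ppg)
  expect_false(est_wn$confident)
  # records too short for 0.05 Hz discrimination
  expect_error(common_frequency(displacement_signal(stats::rnorm(2500), 250),
                                synth_ppg(1.13, 30)),
               "too short")
})

test_that("normalized dB spectra peak at exactly 0 dB and are scale invariant", {
  set.seed(21)
  x <- stats::rnorm(1000)
  sp <- normalized_db_spectrum(x, sample_rate = 250)
  expect_equal(max(sp$amp_db), 0)
  sp_scaled <- normalized_db_spectrum(37.5 * x, sample_rate = 250)
  # compare above a -120 dB floor; lower bins are pure numerical residue
  expect_equal(pmax(sp$amp_db, -120), pmax(sp_scaled$amp_db, -120),
               tolerance = 1e-9)
  # integer-periodic tone: a single 0 dB line, everything else far below
  t <- (0:999) / 250
  tone <- normalized_db_spectrum(sin(2 * pi * 5 * t), sample_rate = 250)
  expect_equal(tone$freq_hz[which.max(tone$amp_db)], 5)
  expect_lt(max(tone$amp_db[tone$freq_hz != 5]), -40)
})
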