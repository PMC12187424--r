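# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written without touching the package's
# own implementation paths.

# plain algebraic (Kasa) least-squares circle fit: the reference the Taubin
# fit must beat on noisy data
kasa_fit <- function(x, y) {
  s <- qr.solve(cbind(2 * x, 2 * y, 1), x^2 + y^2)
  list(center = s[1:2], radius = sqrt(s[3] + s[1]^2 + s[2]^2))
}

# amplitude envelope via the analytic signal (frequency-domain Hilbert)
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# one-sided magnitude spectrum with its frequency grid
mag_spectrum <- function(x, fs, nfft = length(x)) {
  s <- Mod(stats::fft(c(x - mean(x), numeric(nfft - length(x)))))
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1) * fs / nfft, amp = s[half])
}

# frequency of the largest spectral line
peak_frequency <- function(x, fs, nfft = length(x)) {
  sp <- mag_spectrum(x, fs, nfft)
  sp$freq[which.max(sp$amp)]
}

# steady-state gain of an FIR filter at frequency f (direct DTFT evaluation)
fir_gain <- function(h, f, fs) {
  Mod(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs)))
}

# closed-form expected 0-based range bin for a target at range r:
# f_b = 2 r B / (c T_c) mapped onto the Ns-point fast-time grid
oracle_range_bin <- function(config, r) {
  c0 <- 299792458
  fb <- 2 * r * config$bandwidth / (c0 * config$chirp_duration)
  round(fb * config$n_samples_per_chirp / config$adc_rate)
}

# small fast config for Monte-Carlo style tests (valid per the frame/chirp
# timing invariants)
small_config <- function(n_rx = 2L) {
  radar_config(n_rx = n_rx, n_chirps_per_frame = 8L, n_samples_per_chirp = 32L)
}

# run the measurement chain (range FFT -> first-peak bin -> I/Q -> pair
# covariance -> eigen-beamforming -> blockwise circle correction -> phase ->
# displacement) on a cube; returns the displacement signal
measure_displacement <- function(cube, pair = c(1L, 2L)) {
  prof <- range_fft(cube)
  bin <- select_target_bin(prof)
  iq <- extract_iq(prof, bin)
  pair_iq <- structure(list(values = iq$values[, pair, drop = FALSE],
                            sample_rate = iq$sample_rate,
                            source_bin = bin),
                       class = "iq_series")
  rhat <- covariance(pair_iq, window = 256L, hop = 128L)
  state <- dominant_eigendecomposition(rhat)
  combined <- beamform_series(pair_iq, state)
  ph <- instantaneous_phase(recenter_iq_blocked(combined))
  phase_to_displacement(ph, wavelength(cube$config))
}
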