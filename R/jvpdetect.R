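# JVP band filtering, transient trimming, template-correlation pulse
# detection, and PPG synchronization.

#' JVP filter specification
#'
#' The displacement signal is band-limited to 0.75-4 Hz (where JVP component
#' visibility lies) with a 1021-tap linear-phase FIR bandpass, then notched
#' at 0.9-1.1 Hz with a 511-tap linear-phase FIR bandstop to suppress
#' arterial pulsation.  Odd tap counts give integer group delays
#' (`(1021-1)/2 + (511-1)/2 = 765` samples), which is the unusable transient
#' length at each record end.
#'
#' @param sample_rate signal rate (Hz).
#' @param bandpass passband edges (Hz).
#' @param bandpass_taps bandpass length (odd).
#' @param bandstop stopband edges (Hz).
#' @param bandstop_taps bandstop length (odd).
#' @return Object of class `filter_spec` including the combined `group_delay`
#'   in samples.
#' @export
filter_spec <- function(sample_rate = 250,
                        bandpass = c(0.75, 4), bandpass_taps = 1021L,
                        bandstop = c(0.9, 1.1), bandstop_taps = 511L) {
  bandpass_taps <- as.integer(bandpass_taps)
  bandstop_taps <- as.integer(bandstop_taps)
  if (bandpass_taps %% 2L == 0L || bandstop_taps %% 2L == 0L)
    stop("tap counts must be odd for an integer group delay", call. = FALSE)
  if (bandpass[1] <= 0 || bandpass[2] <= bandpass[1] ||
      bandpass[2] >= sample_rate / 2)
    stop("invalid bandpass edges", call. = FALSE)
  if (bandstop[1] <= 0 || bandstop[2] <= bandstop[1] ||
      bandstop[2] >= sample_rate / 2)
    stop("invalid bandstop edges", call. = FALSE)
  structure(list(sample_rate = sample_rate,
                 bandpass = bandpass, bandpass_taps = bandpass_taps,
                 bandstop = bandstop, bandstop_taps = bandstop_taps,
                 group_delay = (bandpass_taps - 1L) %/% 2L +
                   (bandstop_taps - 1L) %/% 2L),
            class = "filter_spec")
}

#' Design the JVP bandpass filter
#'
#' Hamming-window linear-phase FIR of `bandpass_taps` coefficients.
#'
#' @param spec a [filter_spec()].
#' @return Numeric coefficient vector.
#' @export
design_bandpass <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  as.numeric(signal::fir1(spec$bandpass_taps - 1L,
                          spec$bandpass / (spec$sample_rate / 2),
                          type = "pass"))
}

#' Design the arterial-notch bandstop filter
#'
#' Equality-constrained weighted least-squares design of a type-I
#' linear-phase FIR: the symmetric amplitude response is fitted to unity
#' outside the notch (with a transition band left unconstrained on each
#' side) and to zero inside it, subject to exact spectral zeros placed at
#' one-quarter and three-quarters of the notch width.  A window-method
#' design of the same length cannot realize a 0.2 Hz notch at a 250 Hz
#' rate; the constrained design attenuates the whole 0.9-1.1 Hz band by
#' more than 29 dB while leaving the 1.8-4 Hz JVP harmonics within about
#' 0.5 dB.
#'
#' @param spec a [filter_spec()].
#' @param notch_weight least-squares weight on the notch band.
#' @param transition_hz unconstrained transition width on each side (Hz).
#' @return Numeric coefficient vector (length `bandstop_taps`, symmetric).
#' @export
design_bandstop <- function(spec, notch_weight = 5, transition_hz = 0.45) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- spec$sample_rate
  lo <- spec$bandstop[1]
  hi <- spec$bandstop[2]
  m <- (spec$bandstop_taps - 1L) %/% 2L
  fgrid <- seq(0, fs / 2, by = 0.01)
  des <- ifelse(fgrid >= lo & fgrid <= hi, 0, 1)
  w <- rep(1, length(fgrid))
  w[fgrid >= lo & fgrid <= hi] <- notch_weight
  w[(fgrid > lo - transition_hz & fgrid < lo) |
      (fgrid > hi & fgrid < hi + transition_hz)] <- 0
  om <- 2 * pi * fgrid / fs
  cmat <- cbind(1, sapply(seq_len(m), function(k) cos(k * om)))
  width <- hi - lo
  omz <- 2 * pi * c(lo + width / 4, hi - width / 4) / fs
  emat <- cbind(1, t(sapply(omz, function(o) cos(seq_len(m) * o))))
  sw <- sqrt(w)
  gram <- crossprod(cmat * sw)
  rhs <- crossprod(cmat * sw, des * sw)
  kkt <- rbind(cbind(2 * gram, t(emat)),
               cbind(emat, matrix(0, nrow(emat), nrow(emat))))
  sol <- solve(kkt, c(2 * rhs, numeric(nrow(emat))))
  a <- sol[seq_len(m + 1L)]
  c(rev(a[-1]) / 2, a[1], a[-1] / 2)
}

#' Apply the JVP filter cascade with transient trimming
#'
#' Filters causally (bandpass then bandstop) so the filter delay line's
#' loading transient appears explicitly, and marks the combined group delay
#' (765 samples for the default designs) at each end as unusable.
#' Downstream detection operates only inside the trim bounds.
#'
#' @param sig a `displacement_signal` (or numeric vector with `sample_rate`
#'   taken from `spec`).
#' @param spec a [filter_spec()].
#' @return Object of class `jvp_filtered`: the filtered `signal`, the
#'   `trim` bounds `c(g, N - g)` (valid samples are `(g+1):(N-g)`, 1-based)
#'   and the `spec`.
#' @export
apply_filters <- function(sig, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- if (inherits(sig, "displacement_signal")) sig$values else as.numeric(sig)
  fs <- if (inherits(sig, "displacement_signal")) sig$sample_rate else spec$sample_rate
  g <- spec$group_delay
  n <- length(x)
  if (n <= 2L * g)
    stop(sprintf("signal too short: %d samples; at least %d (2 x %d + 1) required",
                 n, 2L * g + 1L, g), call. = FALSE)
  y <- as.numeric(signal::filter(design_bandpass(spec), 1, x))
  y <- as.numeric(signal::filter(design_bandstop(spec), 1, y))
  out <- structure(list(values = y, sample_rate = fs,
                        wavelength = if (inherits(sig, "displacement_signal"))
                          sig$wavelength else NA_real_),
                   class = "displacement_signal")
  structure(list(signal = out, trim = c(g, n - g), spec = spec),
            class = "jvp_filtered")
}

# 1-based indices of the usable (non-transient) region
valid_range <- function(filtered) {
  (filtered$trim[1] + 1L):filtered$trim[2]
}

# cardiac period (samples) from the autocorrelation peak at physiological
# lags; robust to a notch-attenuated fundamental, where a spectral argmax
# would lock onto a harmonic
estimate_cycle_length <- function(x, fs, band = c(0.75, 4)) {
  lags <- floor(fs / band[2]):ceiling(fs / band[1])
  ac <- stats::acf(x, lag.max = max(lags), plot = FALSE)$acf[-1]
  lags <- lags[lags <= length(ac)]
  lags[which.max(ac[lags])]
}

#' Select the reference JVP pulse
#'
#' Segments the usable part of the filtered recording into consecutive
#' candidate cycles at the cardiac period (estimated from the
#' autocorrelation peak at lags corresponding to 0.75-4 Hz unless a rate
#' hint is given - the arterial notch can attenuate the spectral
#' fundamental, which would mislead a plain spectral argmax) and returns the
#' candidate with the highest mean Pearson correlation against all others -
#' the "best pulse" that then serves as the detection template.
#'
#' @param filtered a [apply_filters()] result.
#' @param cardiac_rate_hint known cardiac fundamental (Hz), or `NULL` to
#'   estimate it spectrally.
#' @return Object of class `pulse_template`: `values`, `cycle_length`
#'   (samples) and `origin` (1-based start index in the full recording).
#' @export
select_reference_pulse <- function(filtered, cardiac_rate_hint = NULL) {
  stopifnot(inherits(filtered, "jvp_filtered"))
  fs <- filtered$signal$sample_rate
  idx <- valid_range(filtered)
  x <- filtered$signal$values[idx]
  p <- if (is.null(cardiac_rate_hint))
    as.integer(estimate_cycle_length(x, fs))
  else as.integer(round(fs / cardiac_rate_hint))
  n_cyc <- length(x) %/% p
  if (n_cyc < 5L)
    stop(sprintf("insufficient cycles: %d complete cycles inside the trim bounds, 5 required",
                 n_cyc), call. = FALSE)
  seg <- matrix(x[seq_len(n_cyc * p)], nrow = p)
  cors <- stats::cor(seg)
  mean_cor <- (colSums(cors) - 1) / (n_cyc - 1)
  best <- which.max(mean_cor)
  structure(list(values = seg[, best], cycle_length = p,
                 origin = idx[1] + (best - 1L) * p),
            class = "pulse_template")
}

#' Detect JVP pulses by template correlation
#'
#' Slides the reference pulse over the usable signal, computing the Pearson
#' correlation (mean-removed, unit-energy) at every start position.  Local
#' maxima at or above the threshold become accepted pulses; within each
#' accepted pulse the maximum sample is marked as its peak.  Candidates are
#' accepted greedily in decreasing correlation order subject to a minimum
#' start separation, so raising the threshold can never increase the pulse
#' count.  The separation defaults to 95% of the template length: detected
#' maxima jitter by a few samples around the true cardiac lattice, and a
#' strict full-length exclusion would suppress genuinely adjacent cycles
#' whenever the cardiac period is not an exact sample multiple.
#'
#' @param filtered a [apply_filters()] result.
#' @param template a [select_reference_pulse()] result.
#' @param threshold correlation acceptance threshold.
#' @param min_separation minimum spacing (samples) between accepted pulse
#'   starts; default `round(0.95 * length(template))`.
#' @return Object of class `jvp_pulse_set`: data frame `pulses` with
#'   `start`, `correlation`, `peak_index`, `peak_value` (indices 1-based in
#'   the full recording), plus `threshold` and `template_length`.
#' @export
detect_pulses <- function(filtered, template, threshold = 0.8,
                          min_separation = NULL) {
  stopifnot(inherits(filtered, "jvp_filtered"),
            inherits(template, "pulse_template"))
  x <- filtered$signal$values
  l <- length(template$values)
  n <- length(x)
  if (l >= n) stop("template must be shorter than the signal", call. = FALSE)
  if (is.null(min_separation)) min_separation <- round(0.95 * l)
  tc <- rev(template$values) - mean(template$values)
  tnorm <- sqrt(sum(tc^2))
  emb <- stats::embed(x, l)                     # row s = x[s .. s+l-1] reversed
  num <- as.vector(emb %*% tc)
  ss <- rowSums(emb^2) - rowSums(emb)^2 / l
  r <- num / (sqrt(pmax(ss, 0)) * tnorm)
  r[!is.finite(r)] <- -Inf
  # only windows fully inside the trim bounds are eligible
  starts <- seq_len(n - l + 1L)
  r[starts < filtered$trim[1] + 1L | starts + l - 1L > filtered$trim[2]] <- -Inf
  np <- length(r)
  is_max <- r >= threshold &
    r >= c(-Inf, r[-np]) & r >= c(r[-1], -Inf)
  cand <- which(is_max)
  acc <- integer(0)
  for (s in cand[order(-r[cand])]) {
    if (!any(abs(acc - s) < min_separation)) acc <- c(acc, s)
  }
  acc <- sort(acc)
  peaks <- vapply(acc, function(s) which.max(x[s:(s + l - 1L)]) + s - 1L,
                  integer(1))
  structure(list(pulses = data.frame(start = acc,
                                     correlation = r[acc],
                                     peak_index = peaks,
                                     peak_value = x[peaks]),
                 threshold = threshold, template_length = l),
            class = "jvp_pulse_set")
}

#' @export
print.jvp_pulse_set <- function(x, ...) {
  cat(sprintf("JVP pulses: %d accepted at threshold %.2f (template %d samples)\n",
              nrow(x$pulses), x$threshold, x$template_length))
  invisible(x)
}

# best small-denominator rational p/q with p/q = a/b
rational_ratio <- function(a, b, tol = 1e-9) {
  k <- 1
  while ((abs(a * k - round(a * k)) > tol || abs(b * k - round(b * k)) > tol) &&
         k < 1e6) k <- k * 10
  p <- round(a * k); q <- round(b * k)
  g <- function(u, v) if (v == 0) u else g(v, u %% v)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Common-frequency synchronization of radar JVP and PPG
#'
#' Both JVP and PPG are driven by the cardiac cycle, and their spectra
#' overlap most reliably between 0.8 and 2 Hz.  The PPG is resampled
#' (polyphase rational resampling) to the radar frame rate, both magnitude
#' spectra are evaluated on a shared zero-padded grid, and the returned
#' frequency is the argmax of their product over the band.  A peak whose
#' prominence over the in-band median falls below a floor is flagged
#' low-confidence (no common spectral line exists).
#'
#' @param jvp a `displacement_signal` (radar-derived JVP carrier).
#' @param ppg a [displacement_trajectory()] (e.g. at the 273.1 Hz device
#'   rate).
#' @param band search band (Hz).
#' @param resolution spectral grid resolution (Hz) after zero padding.
#' @param prominence_floor confidence floor on peak/median prominence.
#' @return Object of class `common_frequency_estimate`: `frequency` (Hz),
#'   `confident`, `prominence`.
#' @export
common_frequency <- function(jvp, ppg, band = c(0.8, 2), resolution = 0.02,
                             prominence_floor = 10) {
  stopifnot(inherits(jvp, "displacement_signal"),
            inherits(ppg, "displacement_trajectory"))
  fs <- jvp$sample_rate
  dur_jvp <- length(jvp$values) / fs
  dur_ppg <- length(ppg$values) / ppg$sample_rate
  if (dur_jvp < 20 || dur_ppg < 20)
    stop(sprintf(paste0("records too short for 0.05 Hz discrimination: ",
                        "%.1f s radar, %.1f s PPG; 20 s required"),
                 dur_jvp, dur_ppg), call. = FALSE)
  pq <- rational_ratio(fs, ppg$sample_rate)
  y <- as.numeric(signal::resample(ppg$values, pq[1], pq[2]))
  n <- min(length(jvp$values), length(y))
  x1 <- jvp$values[seq_len(n)]
  x2 <- y[seq_len(n)]
  nfft <- max(n, as.integer(ceiling(fs / resolution)))
  spec <- function(x) Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))
  s1 <- spec(x1); s2 <- spec(x2)
  fr <- (seq_len(nfft) - 1) * fs / nfft
  sel <- fr >= band[1] & fr <= band[2]
  prod_band <- s1[sel] * s2[sel]
  i <- which.max(prod_band)
  prominence <- prod_band[i] / stats::median(prod_band)
  structure(list(frequency = fr[sel][i],
                 confident = prominence >= prominence_floor,
                 prominence = prominence, band = band,
                 resolution = fs / nfft),
            class = "common_frequency_estimate")
}

#' @export
print.common_frequency_estimate <- function(x, ...) {
  cat(sprintf("common frequency: %.3f Hz (%s, prominence %.1f)\n",
              x$frequency, if (x$confident) "confident" else "LOW CONFIDENCE",
              x$prominence))
  invisible(x)
}

#' Normalized amplitude spectrum in dB
#'
#' One-sided magnitude spectrum of the demeaned signal divided by its
#' maximum and expressed as `20 log10`, so the maximum is exactly 0 dB -
#' the representation used to compare radar-derived JVP spectra against
#' reference waveforms.
#'
#' @param sig a `displacement_signal`, `displacement_trajectory` or numeric
#'   vector.
#' @param sample_rate sampling rate (Hz) for plain vectors.
#' @param nfft optional zero-padded transform length.
#' @return Data frame with `freq_hz` and `amp_db`.
#' @export
normalized_db_spectrum <- function(sig, sample_rate = NULL, nfft = NULL) {
  x <- if (inherits(sig, c("displacement_signal", "displacement_trajectory")))
    sig$values else as.numeric(sig)
  if (is.null(sample_rate) &&
      inherits(sig, c("displacement_signal", "displacement_trajectory")))
    sample_rate <- sig$sample_rate
  if (is.null(sample_rate)) stop("sample_rate required", call. = FALSE)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  n <- length(x)
  if (is.null(nfft)) nfft <- n
  s <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))
  half <- seq_len(nfft %/% 2 + 1L)
  s <- s[half]
  data.frame(freq_hz = (half - 1) * sample_rate / nfft,
             amp_db = 20 * log10(s / max(s)))
}
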