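# Synthetic displacement trajectories: JVP-like surface motion, the two-tone
# speaker plate, and a finger PPG surrogate.

#' Displacement trajectory container
#'
#' A uniformly sampled displacement time series in metres; the carrier of
#' surface motion fed to the FMCW echo simulator.
#'
#' @param sample_rate sampling rate (Hz).
#' @param values displacement samples (m).
#' @param description free-text provenance.
#' @return Object of class `displacement_trajectory`.
#' @export
displacement_trajectory <- function(sample_rate, values, description = "") {
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (!all(is.finite(values))) stop("trajectory values must be finite", call. = FALSE)
  structure(list(sample_rate = sample_rate, values = as.numeric(values),
                 description = description),
            class = "displacement_trajectory")
}

#' @export
print.displacement_trajectory <- function(x, ...) {
  cat(sprintf("displacement trajectory: %d samples at %g Hz (%.1f s)%s\n",
              length(x$values), x$sample_rate, length(x$values) / x$sample_rate,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

# evaluate a periodic train of Gaussian bumps at cycle phase u in [0,1);
# neighbouring-cycle tails (+-1) are summed so the train is exactly periodic
periodic_bumps <- function(u, amplitudes, centers, widths) {
  v <- numeric(length(u))
  for (i in seq_along(amplitudes)) {
    for (d in -1:1) {
      v <- v + amplitudes[i] * exp(-((u - centers[i] + d)^2) / (2 * widths[i]^2))
    }
  }
  v
}

#' JVP waveform specification
#'
#' Morphological parameters of the synthetic jugular venous pulse.  One
#' cardiac cycle is modelled as three positive Gaussian bumps (the a, c and v
#' waves) and two negative bumps (the x and y descents), expressed as surface
#' displacement in metres at fractions of the cycle; an arterial sinusoid at
#' the cardiac fundamental, a respiratory sinusoid and white Gaussian noise
#' are superimposed.  Venous amplitudes scale with `posture_factor` (JVP
#' visibility depends strongly on body position).
#'
#' Default bump widths (0.13-0.16 of the cycle) are chosen so that the venous
#' waveform's spectral content above 4 Hz stays below 1% of its dominant
#' line, matching the physiological observation that JVP component
#' visibility falls below 4 Hz.
#'
#' @param cardiac_rate cardiac fundamental (Hz); must lie below 4 Hz.
#' @param wave_amplitudes named numeric (a, c, v), metres.
#' @param wave_centers named numeric (a, c, v), cycle fraction in \[0,1);
#'   must be ordered a < c < v.
#' @param wave_widths named numeric (a, c, v), Gaussian sigma as cycle fraction.
#' @param descent_depths named numeric (x, y), metres (positive depths).
#' @param descent_centers named numeric (x, y), cycle fraction.
#' @param descent_widths named numeric (x, y), cycle fraction.
#' @param arterial_amplitude carotid coupling amplitude (m) at the cardiac
#'   fundamental.
#' @param respiratory_rate breathing rate (Hz).
#' @param respiratory_amplitude breathing displacement amplitude (m).
#' @param noise_sd white displacement noise s.d. (m).
#' @param posture_factor dimensionless scale on the venous bumps.
#' @return Object of class `jvp_waveform_spec`.
#' @export
jvp_waveform_spec <- function(cardiac_rate = 1.13,
                              wave_amplitudes = c(a = 150e-6, c = 60e-6, v = 120e-6),
                              wave_centers = c(a = 0.10, c = 0.25, v = 0.60),
                              wave_widths = c(a = 0.14, c = 0.13, v = 0.16),
                              descent_depths = c(x = 100e-6, y = 130e-6),
                              descent_centers = c(x = 0.18, y = 0.75),
                              descent_widths = c(x = 0.14, y = 0.16),
                              arterial_amplitude = 80e-6,
                              respiratory_rate = 0.25,
                              respiratory_amplitude = 200e-6,
                              noise_sd = 5e-6,
                              posture_factor = 1) {
  if (cardiac_rate <= 0 || cardiac_rate >= 4)
    stop("cardiac_rate must lie in (0, 4) Hz: JVP content must stay below 4 Hz",
         call. = FALSE)
  if (any(c(wave_amplitudes, descent_depths, arterial_amplitude,
            respiratory_amplitude, noise_sd) < 0))
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)
  if (!(wave_centers["a"] < wave_centers["c"] && wave_centers["c"] < wave_centers["v"]))
    stop("wave centers must be ordered a < c < v within the cycle", call. = FALSE)
  if (any(c(wave_widths, descent_widths) <= 0))
    stop("bump widths must be positive", call. = FALSE)
  structure(list(cardiac_rate = cardiac_rate,
                 wave_amplitudes = wave_amplitudes,
                 wave_centers = wave_centers,
                 wave_widths = wave_widths,
                 descent_depths = descent_depths,
                 descent_centers = descent_centers,
                 descent_widths = descent_widths,
                 arterial_amplitude = arterial_amplitude,
                 respiratory_rate = respiratory_rate,
                 respiratory_amplitude = respiratory_amplitude,
                 noise_sd = noise_sd,
                 posture_factor = posture_factor),
            class = "jvp_waveform_spec")
}

# run code under a temporary RNG state seeded with `seed`; NULL leaves the
# global stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a JVP-like displacement trajectory
#'
#' Builds the venous waveform per cycle from the Gaussian bumps of
#' [jvp_waveform_spec()] (scaled by `posture_factor`), then adds the arterial
#' sinusoid at the cardiac fundamental, the respiratory sinusoid and white
#' Gaussian noise.
#'
#' @param spec a [jvp_waveform_spec()].
#' @param duration record length (s).
#' @param rate sampling rate (Hz); must exceed twice the cardiac rate.
#' @param seed integer seed for the noise component, or `NULL`.
#' @return A [displacement_trajectory()].
#' @examples
#' traj <- synth_jvp_trajectory(jvp_waveform_spec(), duration = 10, rate = 250, seed = 1)
#' @export
synth_jvp_trajectory <- function(spec, duration, rate, seed = NULL) {
  stopifnot(inherits(spec, "jvp_waveform_spec"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate <= 2 * spec$cardiac_rate)
    stop("rate must exceed twice the cardiac rate", call. = FALSE)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  u <- (t * spec$cardiac_rate) %% 1
  venous <- spec$posture_factor * periodic_bumps(
    u,
    amplitudes = c(spec$wave_amplitudes, -spec$descent_depths),
    centers    = c(spec$wave_centers, spec$descent_centers),
    widths     = c(spec$wave_widths, spec$descent_widths))
  arterial <- spec$arterial_amplitude * sin(2 * pi * spec$cardiac_rate * t)
  resp <- spec$respiratory_amplitude * sin(2 * pi * spec$respiratory_rate * t)
  noise <- if (spec$noise_sd > 0)
    with_seed(seed, stats::rnorm(n, sd = spec$noise_sd)) else numeric(n)
  displacement_trajectory(rate, venous + arterial + resp + noise,
                          sprintf("synthetic JVP at %g Hz", spec$cardiac_rate))
}

#' Two-tone speaker-plate signal specification
#'
#' The plate used to validate system sensitivity vibrates with the sum of two
#' cosines, `a1 cos(2 pi f1 t) + a2 cos(2 pi f2 t)`, producing a beat at
#' `|f1 - f2|`.
#'
#' @param a1,a2 tone displacement amplitudes (m).
#' @param f1,f2 tone frequencies (Hz), distinct.
#' @return Object of class `speaker_signal_spec`.
#' @export
speaker_signal_spec <- function(a1 = 50e-6, a2 = 50e-6, f1 = 50, f2 = 54) {
  if (f1 == f2) stop("f1 and f2 must differ", call. = FALSE)
  if (a1 < 0 || a2 < 0) stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, f1 = f1, f2 = f2), class = "speaker_signal_spec")
}

#' Synthesize the two-tone speaker-plate trajectory
#'
#' @param spec a [speaker_signal_spec()].
#' @param duration record length (s).
#' @param rate sampling rate (Hz); must exceed twice the higher tone.
#' @return A [displacement_trajectory()].
#' @export
synth_speaker_trajectory <- function(spec, duration, rate) {
  stopifnot(inherits(spec, "speaker_signal_spec"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate <= 2 * max(spec$f1, spec$f2))
    stop("rate must exceed twice the higher tone frequency", call. = FALSE)
  t <- (seq_len(round(duration * rate)) - 1) / rate
  v <- spec$a1 * cos(2 * pi * spec$f1 * t) + spec$a2 * cos(2 * pi * spec$f2 * t)
  displacement_trajectory(rate, v,
                          sprintf("speaker plate %g + %g Hz", spec$f1, spec$f2))
}

#' Synthesize a finger-PPG surrogate
#'
#' Per cardiac cycle, a large systolic Gaussian peak followed by a smaller
#' dicrotic bump, phased so the systolic upstroke follows the JVP a wave and
#' the dicrotic notch sits near the v wave.  Output is in arbitrary optical
#' units but carried in the same trajectory container as the radar signals.
#'
#' @param cardiac_rate cardiac fundamental (Hz).
#' @param duration record length (s).
#' @param rate sampling rate (Hz); default 273.1 Hz, the finger-PPG device rate.
#' @param noise_sd additive white noise s.d. (a.u.).
#' @param seed integer seed for the noise, or `NULL`.
#' @return A [displacement_trajectory()].
#' @export
synth_ppg <- function(cardiac_rate, duration, rate = 273.1, noise_sd = 0.02,
                      seed = NULL) {
  if (cardiac_rate <= 0) stop("cardiac_rate must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (rate <= 2 * cardiac_rate)
    stop("rate must exceed twice the cardiac rate", call. = FALSE)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  u <- (t * cardiac_rate) %% 1
  v <- periodic_bumps(u,
                      amplitudes = c(1, 0.35),
                      centers = c(0.25, 0.62),
                      widths = c(0.10, 0.12))
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, sd = noise_sd))
           else numeric(n)
  displacement_trajectory(rate, v + noise,
                          sprintf("synthetic PPG at %g Hz", cardiac_rate))
}
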