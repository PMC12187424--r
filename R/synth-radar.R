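# FMCW echo simulator: skin surface at a configurable range and direction of
# arrival, observed through a real-valued (I-only) mixer across a
# half-wavelength receive pair plus an optional low-SNR auxiliary channel.

#' Scene specification for the echo simulator
#'
#' @param base_range radar-to-skin standoff (m).  The default 0.05 m places
#'   the echo cleanly away from the DC bin; the hardware's 2 mm standoff
#'   merges with DC at the device's ~28 mm bin width and is kept only as a
#'   documented degenerate case.
#' @param doa source angle (degrees) relative to the receive pair,
#'   in (-90, 90).
#' @param reflection_amplitude echo amplitude before ADC normalization.
#' @param noise_snr_db per-sample SNR (dB) of the additive white receiver
#'   noise on the half-wavelength pair; `Inf` for a noise-free scene.
#' @param aux_snr_db absolute SNR (dB) of antennas beyond the first pair (the
#'   deliberately degraded third channel used to exercise antenna selection);
#'   `Inf` disables the extra noise.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(base_range = 0.05, doa = 0, reflection_amplitude = 0.8,
                       noise_snr_db = 30, aux_snr_db = 0) {
  if (base_range <= 0) stop("base_range must be positive", call. = FALSE)
  if (doa <= -90 || doa >= 90) stop("doa must lie in (-90, 90) degrees", call. = FALSE)
  if (reflection_amplitude <= 0)
    stop("reflection_amplitude must be positive", call. = FALSE)
  structure(list(base_range = base_range, doa = doa,
                 reflection_amplitude = reflection_amplitude,
                 noise_snr_db = noise_snr_db, aux_snr_db = aux_snr_db),
            class = "scene_spec")
}

#' Radar data cube
#'
#' Real ADC samples indexed `(frame, antenna, chirp, sample)` together with
#' the radar configuration they were acquired under.
#'
#' @param values numeric array with dimensions
#'   `(frames, n_rx, n_chirps_per_frame, n_samples_per_chirp)`.
#' @param config the [radar_config()] describing the cube.
#' @return Object of class `radar_cube`.
#' @export
radar_cube <- function(values, config) {
  stopifnot(inherits(config, "radar_config"))
  d <- dim(values)
  if (length(d) != 4L)
    stop("cube values must be a 4-d array (frame, antenna, chirp, sample)",
         call. = FALSE)
  if (d[2] != config$n_rx || d[3] != config$n_chirps_per_frame ||
      d[4] != config$n_samples_per_chirp)
    stop(sprintf(paste0("cube dimensions (%d, %d, %d, %d) do not match config ",
                        "(*, %d, %d, %d)"),
                 d[1], d[2], d[3], d[4], config$n_rx, config$n_chirps_per_frame,
                 config$n_samples_per_chirp), call. = FALSE)
  if (!all(is.finite(values)))
    stop("cube values must be finite", call. = FALSE)
  if (max(abs(values)) > 1 + 1e-9)
    stop("cube values must lie within the normalized ADC range [-1, 1]",
         call. = FALSE)
  structure(list(values = values, config = config), class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("radar cube: %d frames x %d antennas x %d chirps x %d samples (%.1f s)\n",
              d[1], d[2], d[3], d[4], d[1] / x$config$frame_rate))
  invisible(x)
}

#' Simulate FMCW radar frames from a displacement trajectory
#'
#' For frame `t`, antenna `a` (1-based), chirp `c` and fast-time sample `n`
#' (0-based), the IF sample is
#' `A cos(2 pi f_b n / f_s + 4 pi R(t)/lambda + phi_a) + noise`, with
#' `R(t) = base_range + trajectory(t)`, beat frequency
#' `f_b = 2 R(t) B / (c T_c)` and inter-antenna phase
#' `phi_a = -2 pi d (a-1) sin(doa)` for element spacing `d` in wavelengths
#' (the sign matching the steering convention
#' `A(alpha) = [1, exp(-i pi sin alpha)]` of the half-wavelength pair).
#' The mixer is I-only: the cube holds the real IF signal, and complex data
#' arise only through the fast-time FFT, mirroring the hardware.  All chirps
#' within a frame see the same range (the surface moves at the frame rate).
#' The cube is scaled into the normalized ADC range \[-1, 1\].
#'
#' @param config a [radar_config()].
#' @param trajectory a [displacement_trajectory()] sampled at the frame rate.
#' @param scene a [scene_spec()].
#' @param seed integer seed for receiver noise, or `NULL`.
#' @param n_frames number of frames to simulate; defaults to the trajectory
#'   length.
#' @return A [radar_cube()].
#' @examples
#' cfg <- radar_config()
#' traj <- synth_jvp_trajectory(jvp_waveform_spec(), 2, cfg$frame_rate, seed = 1)
#' cube <- simulate_frames(cfg, traj, scene_spec(), seed = 1)
#' @export
simulate_frames <- function(config, trajectory, scene, seed = NULL,
                            n_frames = NULL) {
  stopifnot(inherits(config, "radar_config"),
            inherits(trajectory, "displacement_trajectory"),
            inherits(scene, "scene_spec"))
  if (abs(trajectory$sample_rate - config$frame_rate) >
      1e-6 * config$frame_rate)
    stop("trajectory sample_rate must equal the radar frame rate", call. = FALSE)
  if (is.null(n_frames)) n_frames <- length(trajectory$values)
  if (n_frames > length(trajectory$values))
    stop(sprintf("trajectory too short: %d samples for %d requested frames",
                 length(trajectory$values), n_frames), call. = FALSE)
  n_rx <- config$n_rx
  nc <- config$n_chirps_per_frame
  ns <- config$n_samples_per_chirp
  lam <- wavelength(config)

  rng <- scene$base_range + trajectory$values[seq_len(n_frames)]
  fb <- beat_frequency(config, rng)
  # fast-time argument, frames x samples; identical across chirps
  arg <- outer(fb, 0:(ns - 1)) * (2 * pi / config$adc_rate) + 4 * pi * rng / lam
  sin_doa <- sin(scene$doa * pi / 180)

  vals <- with_seed(seed, {
    v <- array(0, dim = c(n_frames, n_rx, nc, ns))
    for (a in seq_len(n_rx)) {
      phi_a <- -2 * pi * config$rx_spacing_wavelengths * (a - 1) * sin_doa
      m <- scene$reflection_amplitude * cos(arg + phi_a)
      for (ch in seq_len(nc)) v[, a, ch, ] <- m
    }
    if (is.finite(scene$noise_snr_db)) {
      sd_rx <- scene$reflection_amplitude / sqrt(2) /
        10^(scene$noise_snr_db / 20)
      v <- v + stats::rnorm(length(v), sd = sd_rx)
    }
    if (n_rx > 2L && is.finite(scene$aux_snr_db)) {
      sd_aux <- scene$reflection_amplitude / sqrt(2) /
        10^(scene$aux_snr_db / 20)
      n_aux <- n_frames * (n_rx - 2L) * nc * ns
      v[, 3:n_rx, , ] <- v[, 3:n_rx, , ] + stats::rnorm(n_aux, sd = sd_aux)
    }
    v
  })
  peak <- max(abs(vals))
  if (peak > 0) vals <- vals / peak
  radar_cube(vals, config)
}
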