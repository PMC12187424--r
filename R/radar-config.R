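# Radar configuration and index <-> physical-unit conversions.

# speed of light in vacuum (m/s)
.C0 <- 299792458

#' FMCW radar configuration
#'
#' Chirp/frame geometry, RF band and sampling rates of the radar front end.
#' Every index-to-physical-unit conversion in the package (range bins,
#' wavelength, beat frequency) is derived from this record.  Defaults are the
#' configuration found to give the best JVP visibility on the 58-63.5 GHz
#' device: 128 samples/chirp, 8 chirps/frame, 1 MHz ADC rate, 132.987 us
#' chirps, 250 Hz frame rate and the full 5.5 GHz sweep.
#'
#' @param n_rx number of receive antennas.
#' @param n_chirps_per_frame chirps per frame.
#' @param n_samples_per_chirp fast-time ADC samples per chirp.
#' @param adc_rate fast-time sampling rate (Hz).
#' @param chirp_duration chirp sweep duration (s).
#' @param frame_rate frame (slow-time) rate (Hz).
#' @param band_start sweep start frequency (Hz).
#' @param bandwidth sweep bandwidth (Hz).
#' @param rx_spacing_wavelengths receive-element spacing in carrier
#'   wavelengths (0.5 = half-wavelength pair).
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' wavelength(cfg) * 1e3   # carrier wavelength, mm
#' range_bin_width(cfg)    # range resolution, m
#' @export
radar_config <- function(n_rx = 3L,
                         n_chirps_per_frame = 8L,
                         n_samples_per_chirp = 128L,
                         adc_rate = 1e6,
                         chirp_duration = 132.987e-6,
                         frame_rate = 250,
                         band_start = 58e9,
                         bandwidth = 5.5e9,
                         rx_spacing_wavelengths = 0.5) {
  cfg <- list(
    n_rx = as.integer(n_rx),
    n_chirps_per_frame = as.integer(n_chirps_per_frame),
    n_samples_per_chirp = as.integer(n_samples_per_chirp),
    adc_rate = adc_rate,
    chirp_duration = chirp_duration,
    frame_rate = frame_rate,
    band_start = band_start,
    bandwidth = bandwidth,
    rx_spacing_wavelengths = rx_spacing_wavelengths
  )
  class(cfg) <- "radar_config"
  validate_radar_config(cfg)
  cfg
}

validate_radar_config <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  if (cfg$n_rx < 1L || cfg$n_chirps_per_frame < 1L || cfg$n_samples_per_chirp < 2L)
    stop("radar_config: antenna/chirp/sample counts must be positive", call. = FALSE)
  if (cfg$adc_rate <= 0 || cfg$chirp_duration <= 0 || cfg$frame_rate <= 0)
    stop("radar_config: rates and durations must be positive", call. = FALSE)
  if (cfg$n_samples_per_chirp / cfg$adc_rate > cfg$chirp_duration * (1 + 1e-9))
    stop("radar_config: sampling window exceeds chirp duration ",
         "(n_samples_per_chirp/adc_rate > chirp_duration)", call. = FALSE)
  if (cfg$n_chirps_per_frame * cfg$chirp_duration > 1 / cfg$frame_rate * (1 + 1e-9))
    stop("radar_config: chirps do not fit inside one frame period", call. = FALSE)
  if (cfg$bandwidth <= 0)
    stop("radar_config: bandwidth must be positive", call. = FALSE)
  if (cfg$band_start + cfg$bandwidth > 63.5e9 * (1 + 1e-12))
    stop("radar_config: sweep exceeds the 63.5 GHz device band edge", call. = FALSE)
  if (cfg$rx_spacing_wavelengths <= 0)
    stop("radar_config: rx_spacing_wavelengths must be positive", call. = FALSE)
  if (wavelength(cfg) <= 0)
    stop("radar_config: non-physical carrier wavelength", call. = FALSE)
  invisible(cfg)
}

#' @export
print.radar_config <- function(x, ...) {
  cat("FMCW radar configuration\n")
  cat(sprintf("  %d rx x %d chirps x %d samples, ADC %.3g MHz\n",
              x$n_rx, x$n_chirps_per_frame, x$n_samples_per_chirp, x$adc_rate / 1e6))
  cat(sprintf("  chirp %.3f us, frame rate %g Hz\n", x$chirp_duration * 1e6, x$frame_rate))
  cat(sprintf("  band %.2f-%.2f GHz (lambda %.3f mm, bin width %.1f mm)\n",
              x$band_start / 1e9, (x$band_start + x$bandwidth) / 1e9,
              wavelength(x) * 1e3, range_bin_width(x) * 1e3))
  invisible(x)
}

#' Carrier wavelength at band centre
#'
#' The wavelength used for all phase-to-displacement conversions, evaluated at
#' the centre of the sweep (`band_start + bandwidth/2`).
#'
#' @param config a [radar_config()].
#' @return Wavelength in metres.
#' @export
wavelength <- function(config) {
  .C0 / (config$band_start + config$bandwidth / 2)
}

#' Range-bin width
#'
#' Nominal range resolution `c/(2B)` of the sweep, in metres.
#'
#' @param config a [radar_config()].
#' @export
range_bin_width <- function(config) {
  .C0 / (2 * config$bandwidth)
}

#' Beat frequency of a target
#'
#' IF beat frequency `f_b = 2 R B / (c T_c)` for a target at range `R`.
#'
#' @param config a [radar_config()].
#' @param range target range (m).
#' @return Beat frequency in Hz.
#' @export
beat_frequency <- function(config, range) {
  2 * range * config$bandwidth / (.C0 * config$chirp_duration)
}

#' Fractional range-FFT bin of a target
#'
#' Converts a physical range to its (possibly fractional, 0-based) position on
#' the fast-time FFT grid, accounting for the sampled fraction of the sweep.
#'
#' @param config a [radar_config()].
#' @param range target range (m).
#' @export
range_to_bin <- function(config, range) {
  beat_frequency(config, range) * config$n_samples_per_chirp / config$adc_rate
}

#' Range placing a target exactly on an FFT bin
#'
#' Inverse of [range_to_bin()] at integer `bin`: the standoff at which the
#' beat tone is bin-centred (zero spectral leakage, including from the
#' negative-frequency image of the real-valued mixer).
#'
#' @param config a [radar_config()].
#' @param bin 0-based bin index.
#' @export
bin_centred_range <- function(config, bin) {
  bin * .C0 * config$chirp_duration * config$adc_rate /
    (2 * config$bandwidth * config$n_samples_per_chirp)
}
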