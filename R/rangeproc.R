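# Range processing: reshape raw samples, fast-time FFT, first-peak bin
# selection, slow-time I/Q extraction and SNR-based antenna selection.

#' Reshape a flat raw-sample vector into a data cube
#'
#' The flat vector is expected frame-major: for each frame, for each antenna,
#' for each chirp, the fast-time samples are contiguous.  No value is
#' altered; [flatten_cube()] is the exact inverse.
#'
#' @param flat_samples numeric vector of normalized ADC samples.
#' @param config a [radar_config()].
#' @return A [radar_cube()].
#' @export
reshape_raw <- function(flat_samples, config) {
  stopifnot(inherits(config, "radar_config"))
  per_frame <- config$n_rx * config$n_chirps_per_frame * config$n_samples_per_chirp
  if (length(flat_samples) %% per_frame != 0L)
    stop(sprintf(paste0("raw vector length %d is not divisible by ",
                        "n_rx (%d) x n_chirps_per_frame (%d) x ",
                        "n_samples_per_chirp (%d) = %d"),
                 length(flat_samples), config$n_rx, config$n_chirps_per_frame,
                 config$n_samples_per_chirp, per_frame), call. = FALSE)
  n_frames <- length(flat_samples) %/% per_frame
  v <- array(flat_samples,
             dim = c(config$n_samples_per_chirp, config$n_chirps_per_frame,
                     config$n_rx, n_frames))
  radar_cube(aperm(v, c(4, 3, 2, 1)), config)
}

#' Flatten a data cube back to the raw-sample vector
#'
#' Inverse of [reshape_raw()].
#'
#' @param cube a [radar_cube()].
#' @return Numeric vector.
#' @export
flatten_cube <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  as.numeric(aperm(cube$values, c(4, 3, 2, 1)))
}

#' Fast-time range FFT
#'
#' Removes each chirp's mean (suppressing the DC spike that masks close
#' targets), applies an optional window, and transforms the fast-time
#' samples of every chirp to a complex range profile.  With
#' `average_chirps = TRUE` the spectra are averaged (complex mean) across the
#' frame's chirps to reduce noise; with the default `FALSE` the first chirp's
#' spectrum is kept, which preserves fine slow-time detail of the JVP.
#'
#' @param cube a [radar_cube()].
#' @param window `"none"` or `"hann"`.
#' @param average_chirps average spectra across chirps within each frame.
#' @return Object of class `range_profile`: complex array
#'   `(frame, antenna, bin)` with `Ns/2 + 1` non-negative-frequency bins,
#'   plus the config and processing flags.
#' @export
range_fft <- function(cube, window = "none", average_chirps = FALSE) {
  stopifnot(inherits(cube, "radar_cube"))
  if (!window %in% c("none", "hann"))
    stop(sprintf("unknown window '%s'; available: none, hann", window),
         call. = FALSE)
  cfg <- cube$config
  ns <- cfg$n_samples_per_chirp
  nb <- ns %/% 2 + 1L
  v <- cube$values
  if (!average_chirps) v <- v[, , 1L, , drop = FALSE]
  d <- dim(v)                                   # frames, n_rx, chirps', ns
  x <- aperm(v, c(4, 3, 2, 1))                  # ns, chirps', n_rx, frames
  dim(x) <- c(ns, prod(d[1:3]))
  x <- sweep(x, 2L, colMeans(x))                # per-chirp mean removal
  if (window == "hann") x <- x * as.numeric(signal::hanning(ns))
  X <- stats::mvfft(x)[seq_len(nb), , drop = FALSE]
  dim(X) <- c(nb, d[3], d[2], d[1])             # bin, chirps', n_rx, frames
  if (average_chirps && d[3] > 1L) {
    X <- apply(X, c(1, 3, 4), mean)             # complex mean over chirps
  } else {
    X <- X[, 1L, , , drop = FALSE]
  }
  dim(X) <- c(nb, d[2], d[1])                   # bin, n_rx, frames
  prof <- aperm(X, c(3, 2, 1))
  structure(list(values = prof, config = cfg, window = window,
                 chirp_averaged = average_chirps),
            class = "range_profile")
}

#' Select the skin's range bin (first spike)
#'
#' Averages the magnitude spectrum over frames and antennas and returns the
#' lowest-index bin >= 1 that is a local maximum exceeding a prominence
#' floor (`prominence_factor` times the median magnitude of bins >= 1).  The
#' first qualifying peak - not the strongest - is taken, because the closest
#' obstacle is the skin; the DC bin is never returned.
#'
#' @param profile a `range_profile` from [range_fft()].
#' @param prominence_factor multiple of the median bin magnitude a peak must
#'   exceed.
#' @return Integer 0-based bin index.
#' @export
select_target_bin <- function(profile, prominence_factor = 3) {
  stopifnot(inherits(profile, "range_profile"))
  nb <- dim(profile$values)[3]
  if (nb < 3L) stop("range profile needs at least 3 bins", call. = FALSE)
  mag <- apply(Mod(profile$values), 3, mean)
  floor_mag <- prominence_factor * stats::median(mag[-1])
  for (k in 2:nb) {                             # 1-based index; bin k-1
    left_ok <- mag[k] > mag[k - 1]
    right_ok <- if (k < nb) mag[k] >= mag[k + 1] else TRUE
    if (left_ok && right_ok && mag[k] > floor_mag) return(k - 1L)
  }
  stop("no range peak found above the prominence floor; ",
       "check receiver gain and target range", call. = FALSE)
}

#' Extract slow-time I/Q streams at a range bin
#'
#' The selected bin's complex value per frame and antenna is the slow-time
#' I/Q sample (equivalent, up to a constant scale and fixed fast-time phase,
#' to inverse-transforming a one-bin-masked spectrum and reading it at a
#' fixed fast-time index).
#'
#' @param profile a `range_profile` covering all frames.
#' @param bin 0-based range bin (>= 1; the DC bin carries no target phase).
#' @return Object of class `iq_series`: complex matrix `(frame, antenna)`
#'   with `sample_rate` (the frame rate) and `source_bin`.
#' @export
extract_iq <- function(profile, bin) {
  stopifnot(inherits(profile, "range_profile"))
  nb <- dim(profile$values)[3]
  if (bin < 1L || bin > nb - 1L)
    stop(sprintf("bin must lie in [1, %d]", nb - 1L), call. = FALSE)
  vals <- profile$values[, , bin + 1L, drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = dim(profile$values)[2])
  structure(list(values = vals, sample_rate = profile$config$frame_rate,
                 source_bin = as.integer(bin)),
            class = "iq_series")
}

#' Select the best antenna pair by SNR
#'
#' Per antenna, the phase-difference signal (successive differences of the
#' unwrapped I/Q phase) is scored as the ratio of displacement-band power
#' (0.75-4 Hz by default) to out-of-band power, in dB.  The two highest-SNR
#' antennas are returned (ties broken towards lower indices).  A low-SNR
#' channel degrades the beamformer badly, so it must never enter the pair.
#'
#' @param iq an `iq_series` with at least two antennas.
#' @param band displacement band (Hz) treated as signal.
#' @return Object of class `antenna_selection`: `pair` (two 1-based antenna
#'   indices, ascending) and `snr_db` per antenna.
#' @export
select_antennas <- function(iq, band = c(0.75, 4)) {
  stopifnot(inherits(iq, "iq_series"))
  n_ant <- ncol(iq$values)
  if (n_ant < 2L) stop("antenna selection needs at least 2 antennas", call. = FALSE)
  fs <- iq$sample_rate
  snr_db <- vapply(seq_len(n_ant), function(a) {
    ph <- signal::unwrap(Arg(iq$values[, a]))
    d <- diff(ph)
    d <- d - mean(d)
    p <- Mod(stats::fft(d))^2
    n <- length(d)
    fr <- (seq_len(n) - 1) * fs / n
    keep <- fr > 0 & fr <= fs / 2
    inb <- keep & fr >= band[1] & fr <= band[2]
    outb <- keep & !inb
    10 * log10(sum(p[inb]) / sum(p[outb]))
  }, numeric(1))
  ord <- order(-snr_db)                          # stable: ties by lower index
  structure(list(pair = sort(ord[1:2]), snr_db = snr_db),
            class = "antenna_selection")
}

#' @export
print.antenna_selection <- function(x, ...) {
  cat(sprintf("selected antennas: (%d, %d); per-antenna SNR [dB]: %s\n",
              x$pair[1], x$pair[2],
              paste(sprintf("%.1f", x$snr_db), collapse = ", ")))
  invisible(x)
}
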