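# Eigen-beamforming of the selected two-antenna pair.  The one-bin I/Q
# streams are nearly noise-free, so their covariance is rank one and
# ill-conditioned; inverse-based beamformers fail on it.  Everything here is
# built on the dominant eigenvector alone - no matrix inversion anywhere.

#' Sample covariance of a two-antenna I/Q block
#'
#' `R = X X^H / N` over the block's `N` snapshots, with Hermitian symmetry
#' enforced by averaging with the conjugate transpose.  When `window` is
#' given and the block is longer, per-window covariances (hop `hop`) are
#' averaged, tracking the record without ever inverting anything.
#'
#' @param x complex matrix of snapshots: antennas in rows (`2 x N`), or an
#'   `iq_series` with exactly two antennas.
#' @param window optional sliding-window length in snapshots.
#' @param hop window hop (snapshots); defaults to `window/2`.
#' @return Object of class `covariance_matrix`: the 2x2 complex matrix `R`
#'   and the snapshot count.
#' @export
covariance <- function(x, window = NULL, hop = NULL) {
  if (inherits(x, "iq_series")) {
    if (ncol(x$values) != 2L)
      stop("covariance of an iq_series requires exactly two antennas",
           call. = FALSE)
    x <- t(x$values)
  }
  if (!is.matrix(x) || nrow(x) != 2L)
    stop("x must be a 2 x N complex snapshot matrix", call. = FALSE)
  n <- ncol(x)
  if (n < 1L) stop("at least one snapshot required", call. = FALSE)
  one_block <- function(xb) {
    r <- xb %*% Conj(t(xb)) / ncol(xb)
    (r + Conj(t(r))) / 2
  }
  if (is.null(window) || n <= window) {
    r <- one_block(x)
  } else {
    if (is.null(hop)) hop <- window %/% 2L
    starts <- seq(1L, n - window + 1L, by = hop)
    r <- matrix(0 + 0i, 2, 2)
    for (s in starts) r <- r + one_block(x[, s:(s + window - 1L), drop = FALSE])
    r <- r / length(starts)
  }
  structure(list(R = r, n_snapshots = n), class = "covariance_matrix")
}

#' Steering vector of the half-wavelength pair
#'
#' `A(alpha) = [1, exp(-2 pi i d sin(alpha))]` for element spacing `d` in
#' wavelengths (`d = 0.5` gives the canonical
#' `[1, exp(-i pi sin alpha)]`).
#'
#' @param alpha direction of arrival (radians), `|alpha| <= pi/2`.
#' @param spacing element spacing in wavelengths.
#' @return Complex length-2 vector; first component exactly 1.
#' @export
steering_vector <- function(alpha, spacing = 0.5) {
  if (abs(alpha) > pi / 2 + 1e-12)
    stop("alpha must lie within [-pi/2, pi/2]", call. = FALSE)
  c(1 + 0i, exp(-2i * pi * spacing * sin(alpha)))
}

#' Dominant eigendecomposition of the covariance
#'
#' Returns the unit eigenvector of the largest eigenvalue, with the global
#' phase fixed so its first non-zero component is real-positive (the
#' eigendecomposition phase is otherwise arbitrary, and a fixed convention
#' makes the beamformer deterministic).  The eigenvalue ratio is the
#' ill-conditioning indicator: for a coherent noise-free source it blows up.
#'
#' @param rhat a [covariance()].
#' @return Object of class `beamformer_state`: `e1`, `eigenvalue`,
#'   `eigenvalue_ratio`.
#' @export
dominant_eigendecomposition <- function(rhat) {
  stopifnot(inherits(rhat, "covariance_matrix"))
  r <- rhat$R
  if (all(Mod(r) == 0))
    stop("degenerate input: zero covariance matrix", call. = FALSE)
  e <- eigen(r, symmetric = TRUE)
  lam <- e$values
  e1 <- e$vectors[, 1]
  j <- which(Mod(e1) > 1e-12)[1]
  e1 <- e1 * Conj(e1[j]) / Mod(e1[j])
  e1 <- e1 / sqrt(sum(Mod(e1)^2))
  ratio <- if (lam[2] <= 1e-14 * lam[1]) Inf else lam[1] / lam[2]
  structure(list(e1 = e1, eigenvalue = lam[1], eigenvalue_ratio = ratio),
            class = "beamformer_state")
}

#' Project a steering vector onto the signal subspace
#'
#' `A_proj = e1 (e1^H A(alpha))`: the projection of the steering vector onto
#' the span of the dominant eigenvector, which suppresses noise and
#' reflections outside the principal signal direction.
#'
#' @param a complex steering vector (length 2).
#' @param state a [dominant_eigendecomposition()].
#' @return Complex length-2 projected vector.
#' @export
project_steering <- function(a, state) {
  stopifnot(inherits(state, "beamformer_state"))
  state$e1 * sum(Conj(state$e1) * a)
}

#' Direction-of-arrival power scan
#'
#' Evaluates `PSD(alpha) = A_proj^H R A_proj` per grid angle, with
#' `A_proj` the steering vector projected on the dominant eigenvector.  The
#' quadratic form is real and non-negative for Hermitian positive
#' semi-definite `R`; the peak angle is the argmax (lowest angle on ties).
#'
#' @param rhat a [covariance()].
#' @param grid_deg angle grid in degrees within `[-90, 90]`.
#' @return Object of class `doa_spectrum`: `angle_deg`, `psd`, `peak_deg`,
#'   and the beamformer's `eigenvalue_ratio`.
#' @export
psd_scan <- function(rhat, grid_deg = seq(-90, 90, by = 1)) {
  stopifnot(inherits(rhat, "covariance_matrix"))
  if (length(grid_deg) == 0L) stop("angle grid must be non-empty", call. = FALSE)
  if (any(grid_deg < -90 | grid_deg > 90))
    stop("angle grid must lie within [-90, 90] degrees", call. = FALSE)
  state <- dominant_eigendecomposition(rhat)
  psd <- vapply(grid_deg, function(ang) {
    ap <- project_steering(steering_vector(ang * pi / 180), state)
    Re(sum(Conj(ap) * (rhat$R %*% ap)))
  }, numeric(1))
  structure(list(angle_deg = grid_deg, psd = psd,
                 peak_deg = grid_deg[which.max(psd)],
                 eigenvalue_ratio = state$eigenvalue_ratio),
            class = "doa_spectrum")
}

#' @export
print.doa_spectrum <- function(x, ...) {
  cat(sprintf("DoA spectrum: peak at %g deg (eigenvalue ratio %.3g)\n",
              x$peak_deg, x$eigenvalue_ratio))
  invisible(x)
}

#' Combine the antenna pair along the dominant eigenvector
#'
#' `y(t) = e1^H x(t)`: maximal-ratio combination that adds the two channels
#' coherently along the principal signal direction.
#'
#' @param x complex `2 x N` snapshot matrix, or an `iq_series` with exactly
#'   two antennas.
#' @param state a [dominant_eigendecomposition()].
#' @return For a matrix input, a complex vector; for an `iq_series`, an
#'   `iq_series` with a single combined channel.
#' @export
beamform_series <- function(x, state) {
  stopifnot(inherits(state, "beamformer_state"))
  if (inherits(x, "iq_series")) {
    if (ncol(x$values) != 2L)
      stop("beamforming an iq_series requires exactly two antennas",
           call. = FALSE)
    out <- as.vector(x$values %*% Conj(state$e1))
    return(structure(list(values = matrix(out, ncol = 1),
                          sample_rate = x$sample_rate,
                          source_bin = x$source_bin),
                     class = "iq_series"))
  }
  if (!is.matrix(x) || nrow(x) != 2L)
    stop("x must be a 2 x N complex snapshot matrix", call. = FALSE)
  as.vector(Conj(state$e1) %*% x)
}
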