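# Dephasing spectra, tensor-valued encoding spectra b(omega), the b-matrix
# and its scalar summaries (b, b_delta, b_eta, centroid frequency, flow
# vector).

#' Dephasing trajectory of a sampled waveform
#'
#' Cumulative time integral of `gamma * g(t)`; for a refocused waveform the
#' endpoint is zero within grid tolerance.
#'
#' @param w a `waveform_3d`.
#' @return N x 3 matrix of the dephasing vector in rad m^-1.
#' @export
dephasing_trajectory <- function(w) {
  apply(w$g, 2, function(gc) w$gamma * cumtrapz(gc, w$dt))
}

#' Flow-encoding vector
#'
#' Time integral of the dephasing trajectory.  Zero for flow-compensated
#' waveforms; the zero-frequency encoding spectrum is proportional to its
#' outer product with itself.
#'
#' @param w a `waveform_3d`.
#' @return Length-3 numeric vector in s rad m^-1.
#' @export
flow_vector <- function(w) {
  apply(w$q, 2, trapz, dx = w$dt)
}

#' Dephasing spectrum q(omega)
#'
#' Continuous-time Fourier transform `q(omega) = int q(t) exp(i omega t) dt`
#' approximated by a zero-padded FFT times the sampling interval.  For real
#' `q(t)` the spectrum obeys conjugate symmetry, so only the one-sided grid
#' `omega >= 0` is stored together with the quadrature weights that restore
#' two-sided integrals.
#'
#' @param w a `waveform_3d`.
#' @param pad zero-padding factor (>= 8 recommended for smooth spectra).
#' @return An object of class `dephasing_spectrum`: `omega` (rad/s, one
#'   sided), `Q` (complex Nf x 3), `domega`, `weight` (2 except at the grid
#'   ends), `gamma`.
#' @export
dephasing_spectrum <- function(w, pad = 8) {
  N <- nrow(w$q)
  n_pad <- 2^ceiling(log2(N * pad))
  Q <- matrix(0 + 0i, n_pad %/% 2 + 1, 3)
  for (k in 1:3) {
    # exp(+i omega t) convention: conjugate of the R fft kernel
    f <- Conj(stats::fft(c(w$q[, k], rep(0, n_pad - N)))) * w$dt
    Q[, k] <- f[1:(n_pad %/% 2 + 1)]
  }
  domega <- 2 * pi / (n_pad * w$dt)
  nf <- n_pad %/% 2 + 1
  weight <- c(1, rep(2, nf - 2), 1)
  structure(list(omega = (seq_len(nf) - 1) * domega, Q = Q,
                 domega = domega, weight = weight, gamma = w$gamma),
            class = "dephasing_spectrum")
}

#' Tensor-valued encoding spectrum
#'
#' `b(omega) = q(omega) q(-omega)^T / 2 pi`, Hermitian and positive
#' semidefinite at every frequency.  Stored via the one-sided dephasing
#' spectrum; the trace (dephasing power spectrum) is precomputed.
#'
#' @param w a `waveform_3d` or a [dephasing_spectrum()].
#' @param pad zero-padding factor when `w` is a waveform.
#' @return An object of class `encoding_spectrum`: `omega`, `Q`, `trace`
#'   (s m^-2 per rad s^-1), `domega`, `weight`.
#' @export
encoding_spectrum <- function(w, pad = 8) {
  ds <- if (inherits(w, "dephasing_spectrum")) w else dephasing_spectrum(w, pad)
  tr <- rowSums(Mod(ds$Q)^2) / (2 * pi)
  structure(list(omega = ds$omega, Q = ds$Q, trace = tr,
                 domega = ds$domega, weight = ds$weight),
            class = "encoding_spectrum")
}

#' Encoding-spectrum tensor at selected frequencies
#'
#' @param es an `encoding_spectrum`.
#' @param idx frequency indices.
#' @return 3 x 3 x length(idx) complex array of `b(omega)` values.
#' @export
encoding_tensor <- function(es, idx = seq_along(es$omega)) {
  out <- array(0 + 0i, c(3, 3, length(idx)))
  for (j in seq_along(idx)) {
    qv <- es$Q[idx[j], ]
    out[, , j] <- outer(qv, Conj(qv)) / (2 * pi)
  }
  out
}

# time-domain b-matrix, int q q^T dt (trapezoid)
btensor_matrix <- function(w) {
  wts <- rep(w$dt, nrow(w$q))
  wts[c(1, length(wts))] <- w$dt / 2
  crossprod(w$q, w$q * wts)
}

#' Shape metrics of a b-matrix
#'
#' Haeberlen-orders the eigenvalues (largest deviation from the isotropic
#' mean last) and returns the trace `b`, anisotropy `b_delta` and asymmetry
#' `b_eta`.  `b_eta` is set to 0 at the isotropic point where it is
#' otherwise singular.
#'
#' @param B a symmetric 3 x 3 matrix (or a `btensor` object).
#' @return Named list `b`, `b_delta`, `b_eta`, `eigenvalues` (Haeberlen
#'   order: XX, YY, ZZ).
#' @export
shape_metrics <- function(B) {
  if (inherits(B, "btensor")) B <- B$matrix
  b <- sum(diag(B))
  if (b <= 0) stop("undefined shape: b-matrix has non-positive trace")
  ev <- haeberlen_order(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  b_delta <- (ev["ZZ"] - (ev["XX"] + ev["YY"]) / 2) / b
  b_eta <- if (abs(b_delta) < 1e-12) 0 else
    3 * (ev["YY"] - ev["XX"]) / (2 * b * b_delta)
  list(b = b, b_delta = unname(b_delta), b_eta = unname(b_eta),
       eigenvalues = ev)
}

#' Centroid frequency of the encoding power spectrum
#'
#' First moment of the trace of `b(omega)` over the one-sided grid
#' `omega >= 0`, normalized by the one-sided power.  (The two-sided first
#' moment vanishes by symmetry for any real waveform.)
#'
#' @param es an `encoding_spectrum` (or a `waveform_3d`).
#' @return Centroid frequency in rad s^-1.
#' @export
centroid_frequency <- function(es) {
  if (inherits(es, "waveform_3d")) es <- encoding_spectrum(es)
  pw <- sum(es$weight * es$trace)
  if (pw <= 0) stop("undefined centroid: zero encoding power")
  sum(es$weight * es$omega * es$trace) / pw
}

#' Main frequency components of a DOR encoding spectrum
#'
#' In the impulsive (constant dephasing magnitude) limit the encoding power
#' concentrates at `omega1 = n dpsi2 / tau` on the longitudinal axis and at
#' `omega_pm = (n +/- 1) dpsi2 / tau` on the transverse axes.
#'
#' @param n_ratio double-rotation frequency ratio.
#' @param dpsi2 total rotation angle in degrees.
#' @param tau waveform duration in seconds.
#' @return Named list `omega1`, `omega_p`, `omega_m` (rad/s) and the same
#'   values in Hz (`f1`, `f_p`, `f_m`).
#' @export
main_frequencies <- function(n_ratio, dpsi2, tau) {
  stopifnot(tau > 0)
  dp <- deg2rad(dpsi2)
  w1 <- n_ratio * dp / tau
  wp <- (n_ratio + 1) * dp / tau
  wm <- (n_ratio - 1) * dp / tau
  list(omega1 = w1, omega_p = wp, omega_m = wm,
       f1 = w1 / (2 * pi), f_p = wp / (2 * pi), f_m = wm / (2 * pi))
}

#' Full b-tensor summary of a waveform
#'
#' Time-domain b-matrix with Haeberlen-ordered eigenvalues, trace, shape
#' metrics, centroid frequency and flow-encoding vector.
#'
#' @param w a `waveform_3d`.
#' @param pad zero-padding factor for the spectral centroid.
#' @return An object of class `btensor`.
#' @export
btensor <- function(w, pad = 8) {
  B <- btensor_matrix(w)
  sm <- shape_metrics(B)
  es <- encoding_spectrum(w, pad)
  structure(list(matrix = B, b = sm$b, b_delta = sm$b_delta,
                 b_eta = sm$b_eta, eigenvalues = sm$eigenvalues,
                 omega_cent = centroid_frequency(es),
                 q_v = flow_vector(w)),
            class = "btensor")
}

#' @export
print.btensor <- function(x, ...) {
  cat(sprintf("b-tensor: b = %.4g s/m^2, b_delta = %.4f, b_eta = %.4f\n",
              x$b, x$b_delta, x$b_eta))
  cat(sprintf("  centroid frequency = %.2f Hz, |q_v| = %.4g s rad/m\n",
              x$omega_cent / (2 * pi), sqrt(sum(x$q_v^2))))
  invisible(x)
}
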