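# Synthesis of double-rotation (DOR) gradient waveforms.
#
# A DOR waveform is built from a scalar dephasing/rephasing waveform g1D(t)
# whose dephasing vector magnitude q(t) is swept along the unit-vector
# trajectory u(t) generated by two simultaneous rotations about inclined axes
# (inclinations zeta1, zeta2; frequency ratio n).  Component-wise rescaling of
# the resulting 3D waveform sets the anisotropy b_delta and asymmetry b_eta of
# the encoding tensor.

#' Specification of a double-rotation gradient waveform
#'
#' Collects every geometric and timing parameter defining one DOR waveform.
#' Angles are given in degrees at this interface and converted to radians
#' internally.
#'
#' @param tau waveform duration in seconds (per waveform; a bracketing pair
#'   plays two copies).
#' @param n_ratio double-rotation frequency ratio, a non-negative integer.
#'   The inner rotation angle is `n_ratio` times the outer one.
#' @param b_delta target encoding anisotropy in `[-1/2, 1]` (1 = linear,
#'   0 = spherical, -1/2 = planar).
#' @param b_eta target encoding asymmetry, `>= 0`.
#' @param dpsi2 total outer rotation angle in degrees; a positive multiple of
#'   360 for a refocused rotation.
#' @param eps_up,eps_down quarter-sine ramp-up and half-cosine ramp-down
#'   durations of the dephasing lobe, as fractions of `tau`.  Their sum must
#'   not exceed 1/2 so each lobe fits in half the waveform.  Setting both to
#'   zero selects the degenerate rectangular-pulse lobe of width
#'   `delta * tau`.
#' @param delta rectangular lobe width (fraction of `tau`); only used when
#'   `eps_up = eps_down = 0`.
#' @param zeta1,zeta2 rotation-axis inclinations in degrees.  `NULL` selects
#'   the diffusion-DOR defaults: `zeta1 = 0`, `zeta2 = +`[magic_angle()]
#'   for `n_ratio = 0` (q-vector magic-angle spinning) and `zeta1 = 90`,
#'   `zeta2 = -`[magic_angle()] otherwise.
#' @param n_samples number of time samples (uniform grid, endpoints
#'   included); at least 1000.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1 (default 1H).
#' @param pair logical; generate the waveform as a pair of identical copies
#'   bracketing a refocusing pulse.
#' @param gap zero-gradient gap between the two copies of a pair, seconds.
#' @param normalize `NULL` (unit amplitude), `list(b = <target b>)` in
#'   s m^-2, or `list(g_max = <peak gradient>)` in T m^-1.
#' @return An object of class `dor_spec`.
#' @export
dor_spec <- function(tau = 25e-3, n_ratio = 4, b_delta = 0.5, b_eta = 0,
                     dpsi2 = 360, eps_up = 0.015, eps_down = 0.06,
                     delta = 0.075, zeta1 = NULL, zeta2 = NULL,
                     n_samples = 2^15, gamma = GAMMA_1H,
                     pair = FALSE, gap = 0, normalize = NULL) {
  if (is.null(zeta1)) zeta1 <- if (n_ratio == 0) 0 else 90
  if (is.null(zeta2)) zeta2 <- if (n_ratio == 0) magic_angle() else -magic_angle()
  spec <- structure(
    list(tau = tau, n_ratio = n_ratio, b_delta = b_delta, b_eta = b_eta,
         dpsi2 = dpsi2, eps_up = eps_up, eps_down = eps_down, delta = delta,
         zeta1 = zeta1, zeta2 = zeta2, n_samples = as.integer(n_samples),
         gamma = gamma, pair = pair, gap = gap, normalize = normalize),
    class = "dor_spec")
  validate_dor_spec(spec)
  spec
}

validate_dor_spec <- function(spec) {
  with(spec, {
    if (tau <= 0) stop("invalid spec: tau must be positive")
    if (eps_up < 0 || eps_down < 0)
      stop("invalid spec: ramp fractions must be non-negative")
    if (eps_up + eps_down > 0.5 + 1e-12)
      stop("invalid spec: eps_up + eps_down must not exceed 1/2")
    if (b_delta < -0.5 || b_delta > 1)
      stop("invalid spec: b_delta must lie in [-1/2, 1]")
    if (b_eta < 0) stop("invalid spec: b_eta must be non-negative")
    if (n_ratio < 0 || n_ratio != round(n_ratio))
      stop("invalid spec: n_ratio must be a non-negative integer")
    if (dpsi2 <= 0) stop("invalid spec: dpsi2 must be positive")
    if (n_samples < 1000)
      stop("resolution error: n_samples must be at least 1000")
    if (eps_up > 0 && eps_up * (n_samples - 1) < 4)
      stop("resolution error: ramp-up not resolved by the time grid")
    if (eps_down > 0 && eps_down * (n_samples - 1) < 4)
      stop("resolution error: ramp-down not resolved by the time grid")
    if (eps_up == 0 && eps_down == 0 && (delta <= 0 || delta > 0.5))
      stop("invalid spec: rectangular lobe width must lie in (0, 1/2]")
  })
  invisible(spec)
}

#' @export
print.dor_spec <- function(x, ...) {
  cat(sprintf(
    "DOR waveform spec: tau = %g ms, n = %d, b_delta = %g, b_eta = %g\n",
    x$tau * 1e3, x$n_ratio, x$b_delta, x$b_eta))
  cat(sprintf("  zeta1 = %g deg, zeta2 = %g deg, dpsi2 = %g deg\n",
              x$zeta1, x$zeta2, x$dpsi2))
  cat(sprintf("  ramps (up/down) = %g/%g tau, %d samples, pair = %s\n",
              x$eps_up, x$eps_down, x$n_samples, x$pair))
  invisible(x)
}

#' Scalar dephasing/rephasing waveform
#'
#' Builds the 1D gradient waveform `g1D(t)` at unit peak amplitude: a
#' dephasing lobe with a quarter-sine ramp-up of duration `eps_up * tau` and
#' a half-cosine ramp-down of duration `eps_down * tau`, and a rephasing lobe
#' obtained by inversion and time-reversal of the dephasing one.  The scalar
#' dephasing magnitude `q(t)` is the cumulative time integral of
#' `gamma * g1D`.
#'
#' @param spec a [dor_spec()].
#' @return An object of class `waveform_1d` with fields `t`, `g1d`, `q`,
#'   `dt`, `tau`, `gamma`.
#' @export
make_g1d <- function(spec) {
  validate_dor_spec(spec)
  N <- spec$n_samples
  tau <- spec$tau
  t <- seq(0, tau, length.out = N)
  dt <- tau / (N - 1)
  g <- numeric(N)
  if (spec$eps_up == 0 && spec$eps_down == 0) {
    w <- spec$delta * tau
    m <- w / dt
    if (abs(m - round(m)) < 1e-9) {
      # edge on the grid: half-amplitude edge sample makes the trapezoidal
      # lobe area exact
      m <- round(m)
      g[seq_len(m)] <- 1
      g[m + 1] <- 0.5
    } else {
      g[t < w] <- 1
    }
  } else {
    eu <- spec$eps_up * tau
    ed <- spec$eps_down * tau
    iu <- t < eu
    g[iu] <- sin(pi * t[iu] / (2 * eu))
    idown <- t >= eu & t <= eu + ed
    g[idown] <- cos(pi * (t[idown] - eu) / (2 * ed))^2
  }
  # rephasing lobe: inversion + time reversal of the dephasing lobe
  g <- g - rev(g)
  q <- spec$gamma * cumtrapz(g, dt)
  structure(list(t = t, g1d = g, q = q, dt = dt, tau = tau,
                 gamma = spec$gamma),
            class = "waveform_1d")
}

#' Time-dependent double-rotation angle series
#'
#' The outer rotation angle grows with the accumulated squared dephasing,
#' reaching `dpsi2` exactly at the end of the waveform; the inner angle is
#' `n_ratio` times the outer one and the combination angles are
#' `(n_ratio +/- 1)` times the outer one.
#'
#' @param w a [make_g1d()] result (or any list with `q` and `dt`).
#' @param dpsi2 total outer rotation angle, degrees.
#' @param n_ratio double-rotation frequency ratio.
#' @return List with angle series `psi2`, `psi1`, `psip`, `psim` (radians)
#'   and the scalar `b` value of the 1D waveform.
#' @export
rotation_angles <- function(w, dpsi2, n_ratio) {
  dpsi2_rad <- deg2rad(dpsi2)
  q2int <- cumtrapz(w$q^2, w$dt)
  b <- q2int[length(q2int)]
  if (b <= 0) stop("invalid waveform: q(t) is identically zero")
  psi2 <- dpsi2_rad * q2int / b
  list(psi2 = psi2, psi1 = n_ratio * psi2,
       psip = (n_ratio + 1) * psi2, psim = (n_ratio - 1) * psi2,
       b = b)
}

#' Amplitudes of the oscillating terms of a DOR waveform
#'
#' Five coefficients determined by the two rotation-axis inclinations.  At
#' the diffusion-DOR inclinations (90, -54.7) degrees, `a0` and `a2` vanish
#' and the remaining amplitudes evaluate to approximately -0.816, 0.789 and
#' -0.211.
#'
#' @param zeta1,zeta2 inclinations in degrees.
#' @return Named list `a0`, `a1`, `a2`, `ap`, `am`.
#' @export
dor_amplitudes <- function(zeta1, zeta2) {
  z1 <- deg2rad(zeta1); z2 <- deg2rad(zeta2)
  list(a0 = cos(z1) * cos(z2),
       a1 = sin(z1) * sin(z2),
       a2 = cos(z1) * sin(z2),
       ap = sin(z1) * (cos(z2) + 1) / 2,
       am = sin(z1) * (cos(z2) - 1) / 2)
}

# unit-vector trajectory u(t) = Rz(psi2) Ry(zeta2) Rz(psi1) Ry(zeta1) e_z,
# active Z-Y rotations applied right to left; returns N x 3 matrix
dor_unit_vector <- function(psi1, psi2, zeta1, zeta2) {
  z1 <- deg2rad(zeta1); z2 <- deg2rad(zeta2)
  sz1 <- sin(z1); cz1 <- cos(z1)
  sz2 <- sin(z2); cz2 <- cos(z2)
  v2x <- sz1 * cos(psi1); v2y <- sz1 * sin(psi1)
  v3x <- cz2 * v2x + sz2 * cz1
  v3z <- -sz2 * v2x + cz2 * cz1
  u <- cbind(cos(psi2) * v3x - sin(psi2) * v2y,
             sin(psi2) * v3x + cos(psi2) * v2y,
             v3z)
  dimnames(u) <- NULL
  u
}

#' Assemble a 3D double-rotation waveform
#'
#' Sweeps the scalar dephasing magnitude `q(t)` of a 1D waveform along the
#' double-rotation unit-vector trajectory.  The gradient is the exact time
#' derivative of that trajectory, evaluated through the closed
#' trigonometric form (whose sign conventions were fixed against the
#' numerical derivative of `q(t) u(t)`; [dor_numeric_gradient()] exposes
#' that fourth-order finite-difference oracle, and the two agree to better
#' than 1e-6 in relative max-norm for smooth lobes).
#'
#' @param spec a [dor_spec()]; `b_delta`/`b_eta` scaling and normalization
#'   are *not* applied here (see [dor_waveform()]).
#' @param w optional [make_g1d()] result; generated from `spec` when absent.
#' @return An object of class `waveform_3d` with fields `t`, `g` (N x 3),
#'   `q` (N x 3), `dt`, `tau`, `gamma`, `spec`, `orientation`.
#' @export
assemble_dor <- function(spec, w = NULL) {
  if (is.null(w)) w <- make_g1d(spec)
  ang <- rotation_angles(w, spec$dpsi2, spec$n_ratio)
  u <- dor_unit_vector(ang$psi1, ang$psi2, spec$zeta1, spec$zeta2)
  qvec <- w$q * u
  g <- dor_closed_form(spec, w)
  structure(list(t = w$t, g = g, q = qvec, dt = w$dt, tau = w$tau,
                 gamma = spec$gamma, spec = spec,
                 orientation = c(theta = 0, phi = 0)),
            class = "waveform_3d")
}

#' Closed-form DOR gradient
#'
#' Evaluates the trigonometric closed form of the DOR gradient (validated
#' against the numerical derivative of the q-vector trajectory, which
#' resolves the sign conventions).  Returns the N x 3 gradient matrix.
#'
#' @inheritParams assemble_dor
#' @export
dor_numeric_gradient <- function(spec, w = NULL) {
  if (is.null(w)) w <- make_g1d(spec)
  ang <- rotation_angles(w, spec$dpsi2, spec$n_ratio)
  u <- dor_unit_vector(ang$psi1, ang$psi2, spec$zeta1, spec$zeta2)
  apply(w$q * u, 2, fd_derivative, dx = w$dt) / spec$gamma
}

#' @rdname dor_numeric_gradient
#' @export
dor_closed_form <- function(spec, w = NULL) {
  if (is.null(w)) w <- make_g1d(spec)
  n <- spec$n_ratio
  ang <- rotation_angles(w, spec$dpsi2, n)
  a <- dor_amplitudes(spec$zeta1, spec$zeta2)
  dpsi2_rad <- deg2rad(spec$dpsi2)
  grot <- dpsi2_rad * w$q^3 / (spec$gamma * ang$b)
  g1d <- w$g1d
  with(ang, cbind(
    g1d * (a$ap * cos(psip) + a$am * cos(psim) + a$a2 * cos(psi2)) -
      grot * ((n + 1) * a$ap * sin(psip) + (n - 1) * a$am * sin(psim) +
                a$a2 * sin(psi2)),
    g1d * (a$ap * sin(psip) - a$am * sin(psim) + a$a2 * sin(psi2)) +
      grot * ((n + 1) * a$ap * cos(psip) - (n - 1) * a$am * cos(psim) +
                a$a2 * cos(psi2)),
    g1d * (a$a0 - a$a1 * cos(psi1)) + grot * (n * a$a1 * sin(psi1))
  ))
}

#' Scale the Cartesian components to a target encoding shape
#'
#' Multiplies the (X, Y, Z) components by
#' `sqrt(1 - b_delta (1 + b_eta))`, `sqrt(1 - b_delta (1 - b_eta))` and
#' `sqrt(1 + 2 b_delta)`.  Starting from an isotropic-encoding waveform this
#' sets the b-tensor anisotropy and asymmetry while preserving the total b
#' value and the per-axis frequency content.
#'
#' @param w a `waveform_3d`.
#' @param b_delta,b_eta target encoding anisotropy and asymmetry.
#' @return The rescaled `waveform_3d`.
#' @export
shape_scale <- function(w, b_delta, b_eta = 0) {
  rad <- c(1 - b_delta * (1 + b_eta), 1 - b_delta * (1 - b_eta),
           1 + 2 * b_delta)
  if (any(rad < -1e-12))
    stop("invalid shape: b_delta/b_eta combination gives a negative radicand")
  s <- sqrt(pmax(rad, 0))
  w$g <- sweep(w$g, 2, s, `*`)
  w$q <- sweep(w$q, 2, s, `*`)
  w
}

#' Rigidly rotate a waveform
#'
#' Applies the active rotation `Rz(Phi) Ry(Theta)` to the gradient and
#' dephasing trajectories.  The scalar encoding metrics (b, b_delta, b_eta,
#' centroid frequency) are invariant under this operation.
#'
#' @param w a `waveform_3d`.
#' @param theta,phi polar and azimuthal angles in degrees.
#' @export
orient_waveform <- function(w, theta, phi) {
  R <- rot_z(deg2rad(phi)) %*% rot_y(deg2rad(theta))
  w$g <- w$g %*% t(R)
  w$q <- w$q %*% t(R)
  w$orientation <- c(theta = theta, phi = phi)
  w
}

#' Scale the overall waveform amplitude
#'
#' Multiplies the gradient and dephasing trajectories by `s`; the b value
#' scales as `s^2`.
#'
#' @param w a `waveform_3d`.
#' @param s amplitude factor.
#' @export
scale_waveform <- function(w, s) {
  w$g <- w$g * s
  w$q <- w$q * s
  w
}

#' Bracket a refocusing pulse with a pair of identical waveforms
#'
#' Returns the *effective* waveform of two identical copies separated by a
#' zero-gradient gap, with the sign of the effective gradient flipped after
#' the refocusing pulse.  Both copies must be self-refocusing; the total b
#' value doubles relative to a single waveform.
#'
#' @param w a self-refocused `waveform_3d`.
#' @param gap gap duration in seconds (default 0).
#' @export
bracket_pair <- function(w, gap = 0) {
  qmax <- max(abs(w$q))
  if (max(abs(w$q[nrow(w$q), ])) > 1e-6 * qmax)
    stop("invalid waveform: input is not self-refocused")
  n_gap <- if (gap > 0) max(1L, round(gap / w$dt)) else 0L
  zeros <- matrix(0, n_gap, 3)
  g <- rbind(w$g, zeros, -w$g)
  N <- nrow(g)
  t <- seq(0, by = w$dt, length.out = N)
  # the effective-gradient sign flip makes the second copy retrace -q;
  # built from the stored trajectory so refocusing is exact
  q <- rbind(w$q, zeros, -w$q)
  w$t <- t; w$g <- g; w$q <- q
  w$tau <- t[N]
  w
}

#' Generate a complete DOR waveform from its specification
#'
#' Runs the full synthesis chain: 1D lobe pair, double-rotation assembly,
#' shape scaling to the requested (`b_delta`, `b_eta`), optional bracketing
#' of a refocusing pulse, and normalization to either a target b value or a
#' peak-gradient limit.
#'
#' @param spec a [dor_spec()].
#' @return A `waveform_3d`.
#' @export
dor_waveform <- function(spec) {
  w <- assemble_dor(spec)
  w <- shape_scale(w, spec$b_delta, spec$b_eta)
  if (isTRUE(spec$pair)) w <- bracket_pair(w, spec$gap)
  if (!is.null(spec$normalize)) {
    nm <- spec$normalize
    if (!is.null(nm$g_max)) {
      w <- scale_waveform(w, nm$g_max / max(abs(w$g)))
    } else if (!is.null(nm$b)) {
      b_cur <- sum(btensor_matrix(w) * diag(3))
      w <- scale_waveform(w, sqrt(nm$b / b_cur))
    } else stop("normalize must contain either 'b' or 'g_max'")
  }
  w
}

#' @export
print.waveform_3d <- function(x, ...) {
  b <- sum(diag(btensor_matrix(x)))
  cat(sprintf("DOR waveform: %d samples, duration %g ms\n",
              nrow(x$g), x$tau * 1e3))
  cat(sprintf("  max |g| = %.4g T/m, b = %.4g s/m^2\n", max(abs(x$g)), b))
  invisible(x)
}
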