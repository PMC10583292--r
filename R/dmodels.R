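# Diffusion spectra: Lorentzian expansions for restricted geometries and
# axisymmetric Gaussian tensors.

#' Eigenvalue roots of the restricted-diffusion expansion
#'
#' First `K` positive solutions of
#' `xi J_{d/2-1}(xi) - (d-1) J_{d/2}(xi) = 0`, where `J_nu` is the Bessel
#' function of the first kind and `d` the number of restricted dimensions
#' (1 = planar, 2 = cylindrical, 3 = spherical).  The planar case has the
#' analytic roots `(k - 1/2) pi`; the others are bracketed by a sign-change
#' scan and refined by bisection.
#'
#' @param d restriction dimensionality, 1, 2 or 3.
#' @param K number of roots.
#' @return Increasing numeric vector of length `K`.
#' @export
bessel_roots <- function(d, K) {
  stopifnot(d %in% 1:3, K >= 1)
  if (d == 1) return((seq_len(K) - 0.5) * pi)
  f <- function(x) x * besselJ(x, d / 2 - 1) - (d - 1) * besselJ(x, d / 2)
  xs <- seq(1e-6, (K + 3) * pi, by = pi / 50)
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  if (length(sgn) < K)
    stop("numerical error: failed to bracket ", K, " roots for d = ", d)
  roots <- vapply(sgn[seq_len(K)], function(i) {
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  roots
}

#' Restricted-diffusion model
#'
#' Lorentzian-expansion description of the apparent diffusion spectrum in a
#' compartment of radius `r`: widths `Gamma_k = xi_k^2 D0 / r^2` and raw
#' weights `w_k = 2 / (xi_k^2 + 1 - d)`.  The truncated weights are
#' renormalized to sum to one by default so that the zero-frequency limit
#' equals `Dinf` exactly; the raw truncated weights are kept for
#' convergence studies.
#'
#' @param d restriction dimensionality (1, 2 or 3).
#' @param r compartment radius in meters.
#' @param D0 bulk diffusivity, m^2 s^-1.
#' @param Dinf long-range diffusivity, m^2 s^-1 (0 for impermeable walls).
#' @param K number of Lorentzian terms.
#' @param renormalize renormalize the truncated weights to sum to 1.
#' @return Object of class `restricted_model`.
#' @export
restricted_model <- function(d, r, D0, Dinf = 0, K = 50, renormalize = TRUE) {
  stopifnot(r > 0, D0 > 0, Dinf >= 0, Dinf <= D0)
  xi <- bessel_roots(d, K)
  lt <- lorentzian_terms_xi(xi, d, D0, r)
  w <- if (renormalize) lt$w_raw / sum(lt$w_raw) else lt$w_raw
  structure(list(d = d, r = r, D0 = D0, Dinf = Dinf, K = K, xi = xi,
                 Gamma = lt$Gamma, w = w, w_raw = lt$w_raw,
                 truncation_residual = 1 - sum(lt$w_raw)),
            class = "restricted_model")
}

lorentzian_terms_xi <- function(xi, d, D0, r) {
  list(Gamma = xi^2 * D0 / r^2, w_raw = 2 / (xi^2 + 1 - d))
}

#' Lorentzian widths and weights of a restricted model
#'
#' @param m a [restricted_model()].
#' @return List with `Gamma` (rad/s), `w` (weights as used), `w_raw`
#'   (truncated raw weights) and the truncation residual `1 - sum(w_raw)`.
#' @export
lorentzian_terms <- function(m) {
  list(Gamma = m$Gamma, w = m$w, w_raw = m$w_raw,
       truncation_residual = m$truncation_residual)
}

#' Restricted diffusion spectrum
#'
#' `D(omega) = D0 - sum_k w_k (D0 - Dinf) / (1 + omega^2 / Gamma_k^2)`,
#' rising monotonically from `Dinf` at zero frequency to `D0` at high
#' frequency.
#'
#' @param m a [restricted_model()].
#' @param omega frequency grid, rad/s.
#' @return Numeric vector of diffusivities, m^2 s^-1.
#' @export
restricted_spectrum <- function(m, omega) {
  # rows: omega, cols: k
  L <- 1 / (1 + outer(omega^2, m$Gamma^2, `/`))
  m$D0 - as.vector(L %*% m$w) * (m$D0 - m$Dinf)
}

#' Tensor-valued diffusion spectrum model
#'
#' Axisymmetric diffusion models: `cylinder` (restricted in the two
#' transverse dimensions, free along the axis), `planar` (restricted along
#' the axis), `sphere` (isotropic restricted) and `gaussian`
#' (frequency-independent axisymmetric tensor with eigenvalues `Dpar`,
#' `Dperp`).  The symmetry axis is `Rz(phi) Ry(theta) e_z`.
#'
#' @param geometry one of `"cylinder"`, `"planar"`, `"sphere"`,
#'   `"gaussian"`.
#' @param restricted a [restricted_model()] (restricted geometries).
#' @param Dpar,Dperp axial and transverse diffusivities (gaussian case).
#' @param theta,phi orientation angles in degrees.
#' @return Object of class `tensor_spectrum_model`.
#' @export
tensor_spectrum_model <- function(geometry = c("cylinder", "planar", "sphere",
                                               "gaussian"),
                                  restricted = NULL, Dpar = NULL,
                                  Dperp = NULL, theta = 0, phi = 0) {
  geometry <- match.arg(geometry)
  if (geometry == "gaussian") {
    stopifnot(!is.null(Dpar), !is.null(Dperp))
  } else {
    stopifnot(inherits(restricted, "restricted_model"))
    expected_d <- c(cylinder = 2, planar = 1, sphere = 3)[[geometry]]
    if (restricted$d != expected_d)
      warning("restricted model dimensionality (", restricted$d,
              ") does not match geometry '", geometry, "'")
  }
  structure(list(geometry = geometry, restricted = restricted,
                 Dpar = Dpar, Dperp = Dperp, theta = theta, phi = phi),
            class = "tensor_spectrum_model")
}

# symmetry axis in the lab frame
model_axis <- function(tm) {
  as.vector(rot_z(deg2rad(tm$phi)) %*% rot_y(deg2rad(tm$theta)) %*% c(0, 0, 1))
}

# axial (along axis) and transverse diffusivity spectra on a grid
model_axial_spectra <- function(tm, omega) {
  switch(tm$geometry,
    cylinder = {
      dr <- restricted_spectrum(tm$restricted, omega)
      list(par = rep(tm$restricted$D0, length(omega)), perp = dr)
    },
    planar = {
      dr <- restricted_spectrum(tm$restricted, omega)
      list(par = dr, perp = rep(tm$restricted$D0, length(omega)))
    },
    sphere = {
      dr <- restricted_spectrum(tm$restricted, omega)
      list(par = dr, perp = dr)
    },
    gaussian = list(par = rep(tm$Dpar, length(omega)),
                    perp = rep(tm$Dperp, length(omega)))
  )
}

#' Evaluate a tensor-valued diffusion spectrum
#'
#' @param tm a [tensor_spectrum_model()].
#' @param omega frequency grid, rad/s.
#' @return 3 x 3 x length(omega) array.
#' @export
tensor_spectrum <- function(tm, omega) {
  ax <- model_axis(tm)
  sp <- model_axial_spectra(tm, omega)
  P <- outer(ax, ax)
  Iperp <- diag(3) - P
  out <- array(0, c(3, 3, length(omega)))
  for (j in seq_along(omega))
    out[, , j] <- sp$perp[j] * Iperp + sp$par[j] * P
  out
}

#' Isotropic diffusivity and normalized anisotropy
#'
#' `Diso = (Dpar + 2 Dperp) / 3` and
#' `Ddelta = (Dpar - Dperp) / (3 Diso)`, the axisymmetric-tensor analogues
#' of the encoding shape metrics (1 = stick, 0 = isotropic, -1/2 = plane).
#'
#' @param Dpar,Dperp axial and transverse diffusivities.
#' @return Named list `Diso`, `Ddelta`.
#' @export
iso_aniso_metrics <- function(Dpar, Dperp) {
  stopifnot(Dpar >= 0, Dperp >= 0)
  Diso <- (Dpar + 2 * Dperp) / 3
  if (Diso == 0) stop("undefined anisotropy: Diso is zero")
  list(Diso = Diso, Ddelta = (Dpar - Dperp) / (3 * Diso))
}

#' @export
print.restricted_model <- function(x, ...) {
  cat(sprintf(
    "restricted diffusion model: d = %d, r = %.3g um, D0 = %.3g, Dinf = %.3g m^2/s\n",
    x$d, x$r * 1e6, x$D0, x$Dinf))
  cat(sprintf("  K = %d Lorentzians, truncation residual %.2e\n",
              x$K, x$truncation_residual))
  invisible(x)
}
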