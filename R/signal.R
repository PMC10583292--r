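# Forward signal models: the general spectral attenuation exponent, special
# cases for fitting, multicomponent sums and the closed-form powder average.

#' General attenuation exponent
#'
#' `beta = int b(omega) : D(omega) domega` over the full two-sided frequency
#' axis, evaluated from the one-sided encoding spectrum (both factors are
#' even in frequency).  Axisymmetric diffusion models are contracted via
#' their axis decomposition for speed.
#'
#' @param es an `encoding_spectrum` (or a `waveform_3d`).
#' @param tm a [tensor_spectrum_model()].
#' @return The dimensionless attenuation exponent.
#' @export
attenuation_general <- function(es, tm) {
  if (inherits(es, "waveform_3d")) es <- encoding_spectrum(es)
  ax <- model_axis(tm)
  sp <- model_axial_spectra(tm, es$omega)
  p_tot <- rowSums(Mod(es$Q)^2)
  p_ax <- Mod(es$Q %*% ax)^2
  integrand <- (sp$perp * (p_tot - p_ax) + sp$par * p_ax) / (2 * pi)
  sum(es$weight * integrand) * es$domega
}

#' Closed-form powder-averaged signal
#'
#' Orientation average of the axisymmetric Gaussian signal over uniformly
#' distributed domain orientations:
#' `S = S0 exp(-b Diso) sqrt(pi)/2 exp(A/3) erf(sqrt(A)) / sqrt(A)` with
#' `A = 3 b Diso b_delta Ddelta`.  The `A -> 0` limit is handled by series
#' expansion and negative `A` (mixed-sign encoding/diffusion anisotropy) by
#' analytic continuation through the imaginary error function.
#'
#' @param b b value, s m^-2.
#' @param b_delta encoding anisotropy.
#' @param Diso isotropic diffusivity, m^2 s^-1.
#' @param Ddelta normalized diffusion anisotropy.
#' @param S0 unattenuated signal.
#' @return Signal amplitude(s); vectorized over `b` and `b_delta`.
#' @export
powder_average_signal <- function(b, b_delta, Diso, Ddelta, S0 = 1) {
  A <- 3 * b * Diso * b_delta * Ddelta
  S0 * exp(-b * Diso) * powder_factor(A)
}

#' Diffusion model component of a multicomponent signal
#'
#' @param kind `"iso_gaussian"`, `"aniso_gaussian"` or `"iso_restricted"`.
#' @param fraction signal fraction in `[0, 1]`.
#' @param D diffusivity for `iso_gaussian`.
#' @param Dpar,Dperp,theta,phi axisymmetric tensor for `aniso_gaussian`.
#' @param model a [restricted_model()] for `iso_restricted` (spherical).
#' @return Object of class `signal_component`.
#' @export
signal_component <- function(kind = c("iso_gaussian", "aniso_gaussian",
                                      "iso_restricted"),
                             fraction = 1, D = NULL, Dpar = NULL,
                             Dperp = NULL, theta = 0, phi = 0,
                             model = NULL) {
  kind <- match.arg(kind)
  if (fraction < 0) stop("negative component fraction")
  structure(list(kind = kind, fraction = fraction, D = D, Dpar = Dpar,
                 Dperp = Dperp, theta = theta, phi = phi, model = model),
            class = "signal_component")
}

#' Forward signal for one acquisition from explicit waveform objects
#'
#' Computes `S = S0 sum_i f_i exp(-beta_i)` for a list of
#' [signal_component()]s under a given waveform; the component fractions
#' must sum to one.  When a mean velocity is supplied the flow phase factor
#' `exp(i q_v . v)` is included and the returned value is complex.
#'
#' @param w a `waveform_3d` (already scaled to the acquisition b value and
#'   orientation).
#' @param components list of [signal_component()]s.
#' @param S0 reference signal.
#' @param v optional mean velocity 3-vector, m/s.
#' @param es optional precomputed `encoding_spectrum` of `w`.
#' @return Signal (numeric, or complex when `v` is given).
#' @export
signal_forward <- function(w, components, S0 = 1, v = NULL, es = NULL) {
  if (inherits(components, "signal_component")) components <- list(components)
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (any(fr < 0)) stop("negative component fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("component fractions must sum to 1")
  b <- sum(diag(btensor_matrix(w)))
  betas <- vapply(components, function(cp) {
    switch(cp$kind,
      iso_gaussian = b * cp$D,
      aniso_gaussian = {
        tm <- tensor_spectrum_model("gaussian", Dpar = cp$Dpar,
                                    Dperp = cp$Dperp, theta = cp$theta,
                                    phi = cp$phi)
        D <- tensor_spectrum(tm, 0)[, , 1]
        sum(btensor_matrix(w) * D)
      },
      iso_restricted = {
        if (is.null(es)) es <<- encoding_spectrum(w)
        tm <- tensor_spectrum_model("sphere", restricted = cp$model)
        attenuation_general(es, tm)
      })
  }, numeric(1))
  S <- S0 * sum(fr * exp(-betas))
  if (!is.null(v)) S * exp(1i * sum(flow_vector(w) * v)) else S
}
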