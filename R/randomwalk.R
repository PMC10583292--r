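# Monte Carlo validation of the Gaussian phase approximation: random-walk
# spin ensembles under restricted diffusion and flow with phase tracking.

#' Simulate a spin ensemble under a gradient waveform
#'
#' Random walkers take Gaussian displacement steps (plus a constant drift)
#' with specular reflection at the compartment boundary, while the spin
#' phase is accrued by trapezoidal integration of `-gamma g(t) . r(t)`.
#' The waveform is resampled onto the simulation time grid.  The step must
#' resolve both the gradient oscillations (at least 50 steps per period of
#' the fastest main frequency) and the compartment (r.m.s. step length at
#' most a fifth of the radius).
#'
#' @param w a `waveform_3d`.
#' @param geometry `"free"`, `"planar"`, `"cylinder"` or `"sphere"`.
#' @param radius compartment radius (half-separation for `planar`), m.
#' @param D0 step-generating diffusivity, m^2 s^-1.
#' @param v mean (drift) velocity 3-vector, m/s.
#' @param n_spins ensemble size.
#' @param dt simulation step, s (default `tau / 1e4`).
#' @param seed RNG seed.
#' @param n_store_spins,store_every store decimated trajectories for the
#'   first few spins (for inspection/plotting).
#' @param check_resolution disable to bypass the step-size guards.
#' @return Object of class `walker_ensemble` with per-spin phases, initial
#'   and final positions, and simulation metadata.
#' @export
simulate_walkers <- function(w, geometry = c("free", "planar", "cylinder",
                                             "sphere"),
                             radius = Inf, D0 = 2e-9, v = c(0, 0, 0),
                             n_spins = 1e4, dt = NULL, seed = 42,
                             n_store_spins = 0, store_every = 10,
                             check_resolution = TRUE) {
  geometry <- match.arg(geometry)
  gi <- match(geometry, c("free", "planar", "cylinder", "sphere")) - 1L
  if (gi > 0 && !is.finite(radius))
    stop("restricted geometry requires a finite radius")
  if (is.null(dt)) dt <- w$tau / 1e4
  if (check_resolution) {
    sp <- w$spec
    if (!is.null(sp)) {
      f_fast <- max(unlist(main_frequencies(sp$n_ratio, sp$dpsi2,
                                            sp$tau)[c("f1", "f_p")]))
      if (f_fast > 0 && 1 / (f_fast * dt) < 50)
        stop("resolution error: fewer than 50 steps per gradient oscillation")
    }
    if (gi > 0) {
      d_dim <- c(1, 2, 3)[gi]
      if (sqrt(2 * d_dim * D0 * dt) > radius / 5)
        stop("resolution error: step length exceeds radius / 5")
    }
  }
  tg <- seq(0, w$tau, by = dt)
  g <- vapply(1:3, function(k) stats::approx(w$t, w$g[, k], tg)$y,
              numeric(length(tg)))
  set.seed(seed)
  sim <- walk_engine(g, dt, w$gamma, gi, radius, D0, as.numeric(v),
                     as.integer(n_spins), as.integer(n_store_spins),
                     as.integer(store_every))
  structure(list(phase = sim$phase, pos0 = sim$pos0, pos = sim$pos,
                 traj = sim$traj, geometry = geometry, radius = radius,
                 D0 = D0, v = v, dt = dt, n_spins = n_spins, seed = seed,
                 waveform = w),
            class = "walker_ensemble")
}

#' Phase statistics of a walker ensemble
#'
#' Mean phase `alpha`, attenuation exponent `beta` (half the phase
#' variance), the complex ensemble signal `E = <exp(i phi)>`, bootstrap
#' standard errors, and simple distribution-shape diagnostics (skewness and
#' excess kurtosis) indicating whether the Gaussian-phase signal expression
#' `|E| = exp(-beta)` can be trusted.
#'
#' @param ens a [simulate_walkers()] ensemble.
#' @param n_boot bootstrap replicates for the standard errors.
#' @return Object of class `phase_stats`.
#' @export
phase_stats <- function(ens, n_boot = 200) {
  ph <- ens$phase
  n <- length(ph)
  if (n < 100) warning("fewer than 100 spins: unreliable phase statistics")
  alpha <- mean(ph)
  beta <- 0.5 * mean((ph - alpha)^2)
  E <- mean(exp(1i * ph))
  bs <- vapply(seq_len(n_boot), function(i) {
    x <- ph[sample.int(n, n, replace = TRUE)]
    c(mean(x), 0.5 * mean((x - mean(x))^2), Mod(mean(exp(1i * x))))
  }, numeric(3))
  m2 <- mean((ph - alpha)^2)
  structure(list(alpha = alpha, beta = beta, E = E,
                 alpha_se = stats::sd(bs[1, ]), beta_se = stats::sd(bs[2, ]),
                 E_se = stats::sd(bs[3, ]),
                 skewness = mean((ph - alpha)^3) / m2^1.5,
                 kurtosis_excess = mean((ph - alpha)^4) / m2^2 - 3,
                 n_spins = n),
            class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  cat(sprintf("phase statistics (n = %d spins)\n", x$n_spins))
  cat(sprintf("  alpha = %.4g +/- %.2g rad, beta = %.4g +/- %.2g\n",
              x$alpha, x$alpha_se, x$beta, x$beta_se))
  cat(sprintf("  |E| = %.4g, exp(-beta) = %.4g; skew %.3f, ex. kurtosis %.3f\n",
              Mod(x$E), exp(-x$beta), x$skewness, x$kurtosis_excess))
  invisible(x)
}

#' Validate the Gaussian phase approximation against the spectral theory
#'
#' Runs a random-walk simulation and compares the Monte Carlo attenuation
#' exponent (half the phase variance) with the spectral prediction
#' `int b(omega) : D(omega) domega` computed from the analytic restricted
#' diffusion spectrum, and the Monte Carlo mean phase with the flow
#' prediction `q_v . v`.
#'
#' @inheritParams simulate_walkers
#' @param Dinf,K restricted-model parameters for the spectral prediction.
#' @param ... passed to [simulate_walkers()].
#' @return List with Monte Carlo and spectral values, relative deviations
#'   and standard errors.
#' @export
gpa_validate <- function(w, geometry = c("planar", "cylinder", "sphere"),
                         radius, D0, v = c(0, 0, 0), Dinf = 0, K = 50, ...) {
  geometry <- match.arg(geometry)
  d_dim <- c(planar = 1, cylinder = 2, sphere = 3)[[geometry]]
  ens <- simulate_walkers(w, geometry, radius = radius, D0 = D0, v = v, ...)
  ps <- phase_stats(ens)
  m <- restricted_model(d_dim, radius, D0, Dinf, K)
  tm <- tensor_spectrum_model(geometry, restricted = m)
  beta_spec <- attenuation_general(encoding_spectrum(w), tm)
  alpha_pred <- sum(flow_vector(w) * v)
  list(beta_mc = ps$beta, beta_se = ps$beta_se, beta_spectral = beta_spec,
       beta_rel_dev = ps$beta / beta_spec - 1,
       alpha_mc = ps$alpha, alpha_se = ps$alpha_se,
       alpha_predicted = alpha_pred,
       E_mc = ps$E, E_gpa = exp(1i * ps$alpha - ps$beta),
       stats = ps)
}
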