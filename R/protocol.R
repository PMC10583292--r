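# Acquisition-protocol construction: the 2D (centroid frequency x encoding
# anisotropy) waveform grid, identical-b normalization under a peak-gradient
# limit, b-value shells and orientation sets; synthetic phantom datasets.

# compress a one-sided trace spectrum to <= n_bins quadrature nodes that
# conserve per-bin power and first moment; returns nodes (rad/s) and weights
# normalized so that sum(weight * D(node)) * b is the attenuation exponent
# of an isotropic spectrum D for total encoding b
bin_spectrum <- function(es, n_bins = 1024, omega_max = NULL) {
  p <- es$weight * es$trace * es$domega
  if (!is.null(omega_max)) {
    keep <- es$omega <= omega_max
    p <- p[keep]
    om <- es$omega[keep]
  } else om <- es$omega
  bins <- ceiling(seq_along(om) / (length(om) / n_bins))
  wsum <- tapply(p, bins, sum)
  msum <- tapply(p * om, bins, sum)
  keep <- wsum > 0
  node <- as.numeric(msum[keep] / wsum[keep])
  weight <- as.numeric(wsum[keep])
  list(omega = node, weight = weight / sum(weight))
}

#' Build the DOR acquisition protocol
#'
#' Generates the full waveform grid (by default frequency ratios 0 to 5
#' crossed with encoding anisotropies -0.5, 0, 0.5 and 1, ramps of 0.03 and
#' 0.12 of the waveform duration, a 360 degree rotation and zero asymmetry,
#' with the magic-angle-spinning inclinations for ratio 0 and the
#' diffusion-DOR inclinations otherwise), plays each waveform as a pair
#' bracketing a refocusing pulse, and normalizes all waveforms to the common
#' b value attainable by the most gradient-demanding member at the hardware
#' peak-gradient limit.  Encoding metrics are recomputed from the generated
#' waveforms, never trusted from the request.
#'
#' @param tau single-waveform duration, s.
#' @param g_max peak gradient amplitude, T/m.
#' @param n_list frequency ratios.
#' @param b_delta_list target encoding anisotropies.
#' @param n_b number of b-value shells (linearly spaced up to the maximum).
#' @param n_orient number of orientations (deterministic sphere covering).
#' @param b_max optional b value override; must not exceed the attainable
#'   maximum.
#' @param eps_up,eps_down,dpsi2,b_eta,n_samples,gamma,pair,gap passed to
#'   [dor_spec()].
#' @param pad zero-padding factor for the encoding spectra.
#' @param n_bins number of compressed spectral quadrature nodes kept per
#'   waveform for restricted-diffusion fitting.
#' @param store_waveforms keep the sampled waveforms in the returned object.
#' @return Object of class `dor_protocol` with waveform metadata
#'   (`$waveforms`), compressed trace spectra (`$spectra`), unit-b shape
#'   matrices (`$shapes`), b shells, orientations and the full entry table
#'   (`$entries`).
#' @export
build_protocol <- function(tau = 25e-3, g_max = 3, n_list = 0:5,
                           b_delta_list = c(-0.5, 0, 0.5, 1), n_b = 8,
                           n_orient = 15, b_max = NULL, eps_up = 0.03,
                           eps_down = 0.12, dpsi2 = 360, b_eta = 0,
                           n_samples = 2^15, gamma = GAMMA_1H, pair = TRUE,
                           gap = 0, pad = 8, n_bins = 1024,
                           store_waveforms = FALSE) {
  grid <- expand.grid(n_ratio = n_list, b_delta = b_delta_list,
                      KEEP.OUT.ATTRS = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    dor_spec(tau = tau, n_ratio = grid$n_ratio[i],
             b_delta = grid$b_delta[i], b_eta = b_eta, dpsi2 = dpsi2,
             eps_up = eps_up, eps_down = eps_down, n_samples = n_samples,
             gamma = gamma, pair = pair, gap = gap)
  })
  ws <- lapply(specs, dor_waveform)  # unit amplitude
  b_unit <- vapply(ws, function(w) sum(diag(btensor_matrix(w))), numeric(1))
  g_peak <- vapply(ws, function(w) max(abs(w$g)), numeric(1))
  b_att <- (g_max / g_peak)^2 * b_unit
  b_ceiling <- min(b_att)
  if (is.null(b_max)) {
    b_max <- b_ceiling
  } else if (b_max > b_ceiling * (1 + 1e-9)) {
    stop("infeasible g_max: requested b exceeds the attainable ",
         format(b_ceiling, digits = 4), " s/m^2")
  }
  ids <- sprintf("n%d_bd%+.1f", grid$n_ratio, grid$b_delta)
  spectra <- vector("list", length(ws)); names(spectra) <- ids
  shapes <- vector("list", length(ws)); names(shapes) <- ids
  meta <- vector("list", length(ws))
  fmax <- max(vapply(grid$n_ratio, function(n)
    main_frequencies(n, dpsi2, tau)$f_p, numeric(1)))
  for (i in seq_along(ws)) {
    w <- scale_waveform(ws[[i]], sqrt(b_max / b_unit[i]))
    ws[[i]] <- w
    es <- encoding_spectrum(w, pad)
    bt <- btensor_matrix(w)
    sm <- shape_metrics(bt)
    spectra[[i]] <- bin_spectrum(es, n_bins = n_bins,
                                 omega_max = 2 * pi * 20 * fmax)
    shapes[[i]] <- bt / sm$b
    meta[[i]] <- data.frame(
      waveform_id = ids[i], n_ratio = grid$n_ratio[i],
      b_delta_nominal = grid$b_delta[i], b = sm$b, b_delta = sm$b_delta,
      b_eta = sm$b_eta, omega_cent_Hz = centroid_frequency(es) / (2 * pi),
      g_peak = max(abs(w$g)), q_v_norm = sqrt(sum(flow_vector(w)^2)),
      stringsAsFactors = FALSE)
  }
  waveforms <- do.call(rbind, meta)
  b_values <- b_max * seq_len(n_b) / n_b
  dirs <- sphere_directions(n_orient)
  orientations <- data.frame(theta_deg = rad2deg(acos(pmin(1, pmax(-1, dirs[, 3])))),
                             phi_deg = rad2deg(atan2(dirs[, 2], dirs[, 1])))
  entries <- merge(merge(waveforms[, c("waveform_id", "b_delta_nominal",
                                       "b_delta", "omega_cent_Hz")],
                         data.frame(b = b_values)),
                   orientations)
  entries <- entries[order(entries$waveform_id, entries$b), ]
  rownames(entries) <- NULL
  structure(list(tau = tau, gamma = gamma, g_max = g_max, b_max = b_max,
                 b_values = b_values, orientations = orientations,
                 waveforms = waveforms, spectra = spectra, shapes = shapes,
                 specs = stats::setNames(specs, ids), entries = entries,
                 waveform_objects = if (store_waveforms)
                   stats::setNames(ws, ids) else NULL),
            class = "dor_protocol")
}

#' @export
print.dor_protocol <- function(x, ...) {
  cat(sprintf(
    "DOR acquisition protocol: %d waveforms x %d b values x %d orientations (%d entries)\n",
    nrow(x$waveforms), length(x$b_values), nrow(x$orientations),
    nrow(x$entries)))
  cat(sprintf("  tau = %g ms, g_max = %g T/m, b_max = %.4g s/m^2\n",
              x$tau * 1e3, x$g_max, x$b_max))
  cat(sprintf("  centroid frequencies %.0f-%.0f Hz\n",
              min(x$waveforms$omega_cent_Hz), max(x$waveforms$omega_cent_Hz)))
  invisible(x)
}

# attenuation exponent of the restricted component per waveform and unit b:
# sum of compressed spectral weights times the restricted spectrum
beta_restricted_unit <- function(protocol, m) {
  vapply(protocol$spectra, function(sp)
    sum(sp$weight * restricted_spectrum(m, sp$omega)), numeric(1))
}

default_phantom_params <- function(phantom) {
  switch(phantom,
    two_iso = list(D_fast = 2.0e-9, D_slow = 0.4e-9, f_fast = 0.6),
    lamellar_powder = list(Dpar = 0, Dperp = 1.5e-9),
    yeast = list(r = 2.5e-6, D0_intra = 1.0e-9, f_intra = 0.55,
                 D_free = 1.2e-9, d = 3, Dinf = 0, K = 50),
    stop("unknown phantom: ", phantom))
}

#' Synthetic phantom dataset
#'
#' Forward-model signals for the three benchmark phantoms: `two_iso`
#' (two-component isotropic Gaussian diffusion, e.g. a water/brine
#' tube-in-tube assembly), `lamellar_powder` (randomly oriented lamellar
#' domains, closed-form powder average with strongly negative diffusion
#' anisotropy) and `yeast` (spherically restricted intracellular plus
#' Gaussian extracellular water).  Signals are computed with `S0 = 1` per
#' protocol entry and corrupted with seeded Gaussian (default) or Rician
#' noise.
#'
#' @param protocol a [build_protocol()] result.
#' @param phantom `"two_iso"`, `"lamellar_powder"` or `"yeast"`.
#' @param params named list overriding the default phantom parameters.
#' @param noise_sd noise standard deviation relative to `S0`.
#' @param seed RNG seed.
#' @param noise noise model, `"gaussian"` or `"rician"`.
#' @return A `data.frame` of class `dor_dataset` with columns
#'   `waveform_id`, `b`, `bdelta_nominal`, `bdelta`, `omega_cent_Hz`,
#'   `theta_deg`, `phi_deg`, `S`, `S0`.
#' @export
synth_phantom <- function(protocol, phantom = c("two_iso", "lamellar_powder",
                                                "yeast"),
                          params = NULL, noise_sd = 0, seed = 1,
                          noise = c("gaussian", "rician")) {
  phantom <- match.arg(phantom)
  noise <- match.arg(noise)
  p <- utils::modifyList(default_phantom_params(phantom),
                         if (is.null(params)) list() else params)
  en <- protocol$entries
  E <- switch(phantom,
    two_iso = p$f_fast * exp(-en$b * p$D_fast) +
      (1 - p$f_fast) * exp(-en$b * p$D_slow),
    lamellar_powder = {
      am <- iso_aniso_metrics(p$Dpar, p$Dperp)
      powder_average_signal(en$b, en$b_delta, am$Diso, am$Ddelta)
    },
    yeast = {
      m <- restricted_model(p$d, p$r, p$D0_intra, p$Dinf, p$K)
      bu <- beta_restricted_unit(protocol, m)
      p$f_intra * exp(-en$b * bu[en$waveform_id]) +
        (1 - p$f_intra) * exp(-en$b * p$D_free)
    })
  set.seed(seed)
  S <- if (noise_sd == 0) E else switch(noise,
    gaussian = E + stats::rnorm(length(E), sd = noise_sd),
    rician = sqrt((E + stats::rnorm(length(E), sd = noise_sd))^2 +
                    stats::rnorm(length(E), sd = noise_sd)^2))
  ds <- data.frame(waveform_id = en$waveform_id, b = en$b,
                   bdelta_nominal = en$b_delta_nominal, bdelta = en$b_delta,
                   omega_cent_Hz = en$omega_cent_Hz,
                   theta_deg = en$theta_deg, phi_deg = en$phi_deg,
                   S = S, S0 = 1, stringsAsFactors = FALSE)
  attr(ds, "phantom") <- phantom
  attr(ds, "params") <- p
  class(ds) <- c("dor_dataset", "data.frame")
  ds
}

#' Powder-average a dataset over orientations
#'
#' Averages `S/S0` over the orientation dimension within each
#' (waveform, b) group.
#'
#' @param ds a dataset with the [synth_phantom()] columns.
#' @return A `data.frame` with one row per (waveform, b).
#' @export
powder_average <- function(ds) {
  key <- interaction(ds$waveform_id, ds$b, drop = TRUE)
  agg <- stats::aggregate(cbind(E = ds$S / ds$S0), list(key = key), mean)
  first <- !duplicated(key)
  out <- data.frame(ds[first, c("waveform_id", "b", "bdelta_nominal",
                                "bdelta", "omega_cent_Hz")],
                    row.names = NULL)
  out$E <- agg$E[match(key[first], agg$key)]
  out$n_orient <- as.vector(table(key)[as.character(key[first])])
  out[order(out$waveform_id, out$b), ]
}
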