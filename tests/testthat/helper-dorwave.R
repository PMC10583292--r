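# Shared fixtures: all inputs are generated in code.

.dorwave_cache <- new.env(parent = emptyenv())

# the default full acquisition protocol (25 ms, 3 T/m, 24 paired waveforms);
# built once per test run
cached_protocol <- function() {
  if (is.null(.dorwave_cache$protocol))
    .dorwave_cache$protocol <- build_protocol()
  .dorwave_cache$protocol
}

# a single generated waveform from the grid family, cached by parameters
cached_waveform <- function(n_ratio, b_delta, b_eta = 0, pair = FALSE,
                            n_samples = 2^14, normalize = NULL,
                            eps_up = 0.03, eps_down = 0.12) {
  key <- paste(n_ratio, b_delta, b_eta, pair, n_samples, eps_up, eps_down,
               paste(unlist(normalize), collapse = "_"), sep = "|")
  if (is.null(.dorwave_cache[[key]])) {
    spec <- dor_spec(tau = 25e-3, n_ratio = n_ratio, b_delta = b_delta,
                     b_eta = b_eta, eps_up = eps_up, eps_down = eps_down,
                     n_samples = n_samples, pair = pair,
                     normalize = normalize)
    .dorwave_cache[[key]] <- dor_waveform(spec)
  }
  .dorwave_cache[[key]]
}

# rectangular Stejskal-Tanner pair along z: lobe width delta_frac * tau
st_waveform <- function(g = 0.1, delta_frac = 0.2, tau = 25e-3,
                        n_samples = 8001) {
  spec <- dor_spec(tau = tau, n_ratio = 0, b_delta = 1, eps_up = 0,
                   eps_down = 0, delta = delta_frac, n_samples = n_samples,
                   zeta1 = 0)
  w <- dor_waveform(spec)
  scale_waveform(w, g / max(abs(w$g)))
}

# numerical orientation average of exp(-b : D) over a quasi-uniform
# ensemble, with explicit tensor contraction (independent powder oracle)
powder_oracle <- function(b, b_delta, Diso, Ddelta, n_dirs = 1e4) {
  dirs <- sphere_directions(n_dirs)
  bperp <- b * (1 - b_delta) / 3
  bpar <- b * (1 + 2 * b_delta) / 3
  B <- diag(c(bperp, bperp, bpar))
  Dpar <- Diso * (1 + 2 * Ddelta)
  Dperp <- Diso * (1 - Ddelta)
  mean(vapply(seq_len(n_dirs), function(i) {
    u <- dirs[i, ]
    D <- Dperp * (diag(3) - outer(u, u)) + Dpar * outer(u, u)
    exp(-sum(B * D))
  }, numeric(1)))
}
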