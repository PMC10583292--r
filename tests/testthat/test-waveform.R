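# DOR waveform synthesis: 1D lobes, rotation angles, amplitudes, assembly,
# shape scaling, orientation and bracketing.

test_that("1D lobe pair refocuses and has the stated ramp areas", {
  spec <- dor_spec(eps_up = 0.03, eps_down = 0.12, n_samples = 2^14)
  w <- make_g1d(spec)
  # total integral of g1d vanishes (antisymmetric lobe pair)
  expect_lt(abs(dorwave:::trapz(w$g1d, w$dt)), 1e-12)
  expect_lt(abs(w$q[length(w$q)]), 1e-9 * max(w$q))
  expect_true(all(w$q > -1e-9 * max(w$q)))
  # plateau between the lobes carries zero gradient but maximal q
  mid <- abs(w$t - spec$tau / 2) < 0.1 * spec$tau
  expect_equal(max(abs(w$g1d[mid])), 0)
  expect_equal(mean(w$q[mid]), max(w$q), tolerance = 1e-12)
  # lobe area oracle: quadrature of the quarter-sine and half-cosine ramps
  area_up <- stats::integrate(function(x) sin(pi * x / (2 * 0.03)),
                              0, 0.03)$value
  area_down <- stats::integrate(function(x) cos(pi * x / (2 * 0.12))^2,
                                0, 0.12)$value
  expect_equal(max(w$q), spec$gamma * spec$tau * (area_up + area_down),
               tolerance = 1e-6)
  # degenerate rectangle: q max is the rectangle area
  wr <- make_g1d(dor_spec(eps_up = 0, eps_down = 0, delta = 0.2,
                          n_samples = 8001))
  expect_equal(max(wr$q), wr$gamma * 0.2 * 25e-3, tolerance = 1e-12)
})

test_that("invalid or under-resolved lobe specifications are rejected", {
  expect_error(dor_spec(eps_up = 0.3, eps_down = 0.3), "eps_up")
  expect_error(dor_spec(n_samples = 500), "resolution")
  expect_error(dor_spec(eps_up = 1e-4, n_samples = 1100), "resolution")
  expect_error(dor_spec(b_delta = 1.2), "b_delta")
  expect_error(dor_spec(n_ratio = 2.5), "n_ratio")
})

test_that("rotation angles reach their prescribed totals and are monotone", {
  w <- make_g1d(dor_spec(n_samples = 2^13))
  ang <- rotation_angles(w, dpsi2 = 360, n_ratio = 4)
  expect_equal(ang$psi2[length(ang$psi2)], 2 * pi)
  expect_equal(ang$psi1[length(ang$psi1)], 8 * pi)
  expect_equal(ang$psip[length(ang$psip)], 10 * pi)
  expect_equal(ang$psim[length(ang$psim)], 6 * pi)
  expect_true(all(diff(ang$psi2) >= 0))
  # constant-q plateau: psi2 grows linearly in time
  wc <- list(q = rep(1, 2001), dt = 1e-5)
  angc <- rotation_angles(wc, 360, 2)
  expect_equal(angc$psi2, 2 * pi * seq(0, 1, length.out = 2001),
               tolerance = 1e-10)
  # all-zero q is caught
  expect_error(rotation_angles(list(q = numeric(100), dt = 1e-5), 360, 2),
               "zero")
})

test_that("oscillation amplitudes match the printed diffusion-DOR values", {
  a <- dor_amplitudes(90, -magic_angle())
  expect_lt(abs(a$a0), 1e-15)
  expect_lt(abs(a$a2), 1e-15)
  # printed to three decimals: compare with absolute half-unit tolerance
  expect_lt(abs(a$a1 - (-0.816)), 5e-4)
  expect_lt(abs(a$ap - 0.789), 5e-4)
  expect_lt(abs(a$am - (-0.211)), 5e-4)
  # zeta1 = 0 kills every oscillating amplitude (sin zeta1 factor)
  a0 <- dor_amplitudes(0, magic_angle())
  expect_equal(a0$a1, 0)
  expect_equal(a0$ap, 0)
  expect_equal(a0$am, 0)
  expect_equal(a0$a0, cos(0) * cos(dorwave:::deg2rad(magic_angle())))
})

test_that("closed-form gradient equals the numerical q-trajectory derivative", {
  for (n in c(0L, 1L, 3L, 5L)) {
    for (bd in c(0, 1)) {
      spec <- dor_spec(n_ratio = n, b_delta = bd, eps_up = 0.03,
                       eps_down = 0.12, n_samples = 2^14)
      w1 <- make_g1d(spec)
      g_cf <- dor_closed_form(spec, w1)
      g_num <- dor_numeric_gradient(spec, w1)
      expect_lt(max(abs(g_cf - g_num)) / max(abs(g_cf)), 1e-6)
    }
  }
  # and the stored gradient integrates back to the stored trajectory
  spec <- dor_spec(n_ratio = 4, b_delta = 0.5, b_eta = 0.25,
                   eps_up = 0.015, eps_down = 0.06, n_samples = 2^15)
  w <- dor_waveform(spec)
  expect_lt(max(abs(dephasing_trajectory(w) - w$q)) / max(abs(w$q)), 1e-6)
  expect_lt(max(abs(w$q[nrow(w$q), ])) / max(abs(w$q)), 1e-9)
})

test_that("impulsive-limit trajectory at the DOR inclinations is isotropic", {
  N <- 10001
  psi2 <- 2 * pi * seq(0, 1, length.out = N)
  wts <- rep(1 / (N - 1), N)
  wts[c(1, N)] <- wts[c(1, N)] / 2
  for (n in 2:5) {
    u <- dorwave:::dor_unit_vector(n * psi2, psi2, 90, -magic_angle())
    sm <- shape_metrics(crossprod(u, u * wts))
    expect_lt(abs(sm$b_delta), 1e-6)
  }
  # n = 0 with the magic-angle-spinning inclinations: a cone at the magic
  # angle, also isotropic, with constant z component
  u0 <- dorwave:::dor_unit_vector(0 * psi2, psi2, 0, magic_angle())
  expect_lt(abs(shape_metrics(crossprod(u0, u0 * wts))$b_delta), 1e-6)
  expect_equal(unname(u0[, 3]), rep(cos(dorwave:::deg2rad(magic_angle())), N))
})

test_that("shape scaling hits the requested anisotropy and preserves spectra", {
  w <- cached_waveform(2, 0)  # isotropic base
  expect_equal(shape_scale(w, 0, 0)$g, w$g)
  w1 <- shape_scale(w, 1, 0)
  expect_true(all(w1$g[, 1:2] == 0))
  expect_equal(w1$g[, 3], sqrt(3) * w$g[, 3])
  sm <- shape_metrics(dorwave:::btensor_matrix(shape_scale(w, 0.5, 0)))
  expect_equal(sm$b_delta, 0.5, tolerance = 1e-3)
  expect_error(shape_scale(w, 1, 3), "radicand")
  # normalized per-axis power spectra unchanged by the scaling
  qs0 <- dephasing_spectrum(w, pad = 2)
  qs1 <- dephasing_spectrum(shape_scale(w, 0.5, 0.25), pad = 2)
  for (k in 1:3) {
    p0 <- Mod(qs0$Q[, k])^2
    p1 <- Mod(qs1$Q[, k])^2
    expect_lt(max(abs(p0 / sum(p0) - p1 / sum(p1))), 1e-12)
  }
})

test_that("rigid rotation leaves the encoding invariants unchanged", {
  w <- cached_waveform(3, 0.5, n_samples = 2^13)
  expect_equal(orient_waveform(w, 0, 0)$g, w$g)
  wr <- orient_waveform(w, 63, 117)
  B0 <- dorwave:::btensor_matrix(w)
  B1 <- dorwave:::btensor_matrix(wr)
  expect_equal(sum(diag(B1)), sum(diag(B0)), tolerance = 1e-10)
  expect_equal(eigen(B1, symmetric = TRUE)$values,
               eigen(B0, symmetric = TRUE)$values,
               tolerance = 1e-9)
  es0 <- encoding_spectrum(w, pad = 2)
  es1 <- encoding_spectrum(wr, pad = 2)
  expect_equal(centroid_frequency(es1), centroid_frequency(es0),
               tolerance = 1e-9)
})

test_that("bracketing a refocusing pulse doubles b and refocuses twice", {
  w <- cached_waveform(3, 1, n_samples = 2^13)
  wp <- bracket_pair(w, gap = 0)
  b1 <- sum(diag(dorwave:::btensor_matrix(w)))
  b2 <- sum(diag(dorwave:::btensor_matrix(wp)))
  expect_equal(b2, 2 * b1, tolerance = 1e-9)
  N <- nrow(w$q)
  expect_lt(max(abs(wp$q[N, ])), 1e-9 * max(abs(wp$q)))      # midpoint
  expect_lt(max(abs(wp$q[nrow(wp$q), ])), 1e-9 * max(abs(wp$q)))  # end
  # centroid frequency of the pair close to the single waveform
  f1 <- centroid_frequency(encoding_spectrum(w))
  f2 <- centroid_frequency(encoding_spectrum(wp))
  expect_equal(f2 / f1, 1, tolerance = 0.02)
  # a non-refocused input is rejected
  bad <- w
  bad$q <- bad$q + max(abs(bad$q)) * 0.01
  expect_error(bracket_pair(bad), "not self-refocused")
})
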