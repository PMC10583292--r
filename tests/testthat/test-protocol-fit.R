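# Acquisition protocol, synthetic phantoms and the three model fits.

test_that("protocol has the full entry grid at identical b values", {
  p <- cached_protocol()
  expect_equal(nrow(p$waveforms), 24)
  expect_equal(nrow(p$entries), 24 * 8 * 15)
  # identical b across waveforms
  expect_lt(diff(range(p$waveforms$b)) / mean(p$waveforms$b), 1e-6)
  # peak gradients within the hardware limit
  expect_true(all(p$waveforms$g_peak <= p$g_max * (1 + 1e-9)))
  # recomputed anisotropy close to requested (finite-lobe non-ideality);
  # the n = 1 member sits outside the exact-isotropy condition (ratio > 1)
  # and carries the largest deviation
  dev <- abs(p$waveforms$b_delta - p$waveforms$b_delta_nominal)
  expect_true(all(dev <= 0.05))
  expect_true(all(dev[p$waveforms$n_ratio != 1] <= 0.02))
  # centroid frequency strictly increases with the frequency ratio within
  # each anisotropy row
  for (bd in unique(p$waveforms$b_delta_nominal)) {
    row <- p$waveforms[p$waveforms$b_delta_nominal == bd, ]
    row <- row[order(row$n_ratio), ]
    expect_true(all(diff(row$omega_cent_Hz) > 0))
  }
  # bracketed pairs are flow-compensated: near-zero flow vectors
  qscale <- sqrt(p$b_max / p$tau) * p$tau  # ~ q_rms * tau
  expect_lt(max(p$waveforms$q_v_norm) / qscale, 1e-6)
  expect_error(build_protocol(n_samples = 2^12, b_max = 1e12),
               "infeasible")
})

test_that("synthetic phantoms show their characteristic signatures", {
  p <- cached_protocol()
  # isotropic Gaussian: identical signal across all waveforms at fixed b
  pa1 <- powder_average(synth_phantom(p, "two_iso", noise_sd = 0))
  spread <- tapply(pa1$E, pa1$b, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)
  # lamellar powder: one curve per encoding anisotropy, no frequency
  # dependence within a (b, nominal-anisotropy) group
  pa2 <- powder_average(synth_phantom(p, "lamellar_powder", noise_sd = 0))
  grp <- interaction(pa2$b, pa2$bdelta_nominal)
  within_spread <- tapply(pa2$E, grp, function(x) diff(range(x)) / mean(x))
  # small within-group spread (only residual b_delta non-ideality)...
  expect_lt(max(within_spread), 0.02)
  # ...but clear separation between anisotropy groups at the largest b
  top <- pa2[pa2$b == max(pa2$b), ]
  expect_gt(diff(range(tapply(top$E, top$bdelta_nominal, mean))) /
              mean(top$E), 0.2)
  # yeast: signal depends on the centroid frequency at fixed b
  pa3 <- powder_average(synth_phantom(p, "yeast", noise_sd = 0))
  top3 <- pa3[pa3$b == max(pa3$b), ]
  expect_gt(diff(range(top3$E)) / mean(top3$E), 0.2)
  expect_gt(stats::cor(top3$omega_cent_Hz, -top3$E), 0.5)
  expect_error(synth_phantom(p, "gel"), "arg")
})

test_that("two-component isotropic fit recovers generating parameters", {
  p <- cached_protocol()
  ds <- synth_phantom(p, "two_iso", noise_sd = 0)
  f <- fit_two_iso(ds)
  expect_equal(f$D_fast / 2.0e-9, 1, tolerance = 1e-3)
  expect_equal(f$D_slow / 0.4e-9, 1, tolerance = 1e-3)
  expect_equal(f$f_fast / 0.6, 1, tolerance = 1e-3)
  # 1 % noise: recovery within 5 %
  dsn <- synth_phantom(p, "two_iso", noise_sd = 0.01, seed = 3)
  fn <- fit_two_iso(dsn, seed = 3)
  expect_equal(fn$D_fast / 2.0e-9, 1, tolerance = 0.05)
  expect_equal(fn$D_slow / 0.4e-9, 1, tolerance = 0.05)
  expect_equal(fn$f_fast / 0.6, 1, tolerance = 0.05)
  # single-component data flagged as degenerate
  ds1 <- synth_phantom(p, "two_iso",
                       params = list(D_fast = 1e-9, D_slow = 1e-9),
                       noise_sd = 0)
  f1 <- fit_two_iso(ds1)
  expect_false(is.null(f1$identifiability))
})

test_that("powder-averaged axisymmetric fit recovers the lamellar tensor", {
  p <- cached_protocol()
  ds <- synth_phantom(p, "lamellar_powder", noise_sd = 0)
  f <- fit_powder_aniso(ds)
  expect_equal(f$Ddelta, -0.5, tolerance = 0.01)
  expect_equal(f$Diso / 1e-9, 1, tolerance = 0.01)
  expect_lt(abs(f$Dpar), 0.05e-9)
  expect_equal(f$Dperp / 1.5e-9, 1, tolerance = 0.02)
  # 1 % noise: Diso within 3 %, Ddelta within 0.05
  dsn <- synth_phantom(p, "lamellar_powder", noise_sd = 0.01, seed = 5)
  fn <- fit_powder_aniso(dsn, seed = 5)
  expect_equal(fn$Diso / 1e-9, 1, tolerance = 0.03)
  expect_lt(abs(fn$Ddelta - (-0.5)), 0.05)
  # isotropic data give near-zero anisotropy, consistent with the
  # single-component Gaussian description
  dsi <- synth_phantom(p, "lamellar_powder",
                       params = list(Dpar = 1e-9, Dperp = 1e-9),
                       noise_sd = 0)
  fi <- fit_powder_aniso(dsi)
  expect_lt(abs(fi$Ddelta), 0.02)
  # a single encoding anisotropy is unidentifiable
  one <- synth_phantom(p, "lamellar_powder", noise_sd = 0)
  one <- one[one$bdelta_nominal == 1, ]
  expect_error(fit_powder_aniso(one), "unidentifiable")
})

test_that("restricted-plus-free fit recovers radius and diffusivities", {
  p <- cached_protocol()
  ds <- synth_phantom(p, "yeast", noise_sd = 0)
  f <- fit_restricted_plus_free(ds, p)
  expect_equal(f$r / 2.5e-6, 1, tolerance = 0.02)
  expect_equal(f$D0_intra / 1.0e-9, 1, tolerance = 0.02)
  expect_equal(f$f_intra / 0.55, 1, tolerance = 0.02)
  expect_equal(f$D_free / 1.2e-9, 1, tolerance = 0.02)
  # residuals show no trend against encoding anisotropy
  pa <- powder_average(ds)
  bu <- with(f, {
    m <- restricted_model(3, r, D0_intra, 0, 50)
    dorwave:::beta_restricted_unit(p, m)
  })
  model <- f$S0 * (f$f_intra * exp(-pa$b * bu[pa$waveform_id]) +
                     (1 - f$f_intra) * exp(-pa$b * f$D_free))
  res <- log(model) - log(pa$E)
  expect_lt(abs(stats::cor(res, pa$bdelta_nominal)), 0.2)
  # omega-independent data push the radius to the Gaussian regime
  dsg <- synth_phantom(p, "two_iso", noise_sd = 0)
  fg <- fit_restricted_plus_free(dsg, p, n_starts = 4)
  expect_false(is.null(fg$note))
})

test_that("noisy restricted-plus-free recovery stays within 5 %", {
  p <- cached_protocol()
  dsn <- synth_phantom(p, "yeast", noise_sd = 0.01, seed = 7)
  fn <- fit_restricted_plus_free(dsn, p, seed = 7)
  expect_equal(fn$r / 2.5e-6, 1, tolerance = 0.05)
  expect_equal(fn$f_intra / 0.55, 1, tolerance = 0.05)
  expect_equal(fn$D_free / 1.2e-9, 1, tolerance = 0.05)
})
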