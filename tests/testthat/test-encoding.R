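# Encoding spectra and scalar encoding metrics.

test_that("dephasing trajectory and flow vector follow the classical forms", {
  # zero gradient -> zero trajectory
  w0 <- st_waveform()
  w0$g[] <- 0
  expect_true(all(dephasing_trajectory(w0) == 0))
  # rectangular lobe pair: plateau magnitude gamma g delta, flow vector
  # gamma g delta Delta along the gradient axis
  g <- 0.1; delta <- 0.2 * 25e-3; Delta <- 25e-3 - delta
  w <- st_waveform(g = g, delta_frac = 0.2)
  plateau <- abs(w$t - 12.5e-3) < 2e-3
  expect_equal(unname(w$q[plateau, 3]), rep(w$gamma * g * delta, sum(plateau)),
               tolerance = 1e-9)
  qv <- flow_vector(w)
  expect_equal(qv[3], w$gamma * g * delta * Delta, tolerance = 1e-6)
  expect_lt(max(abs(qv[1:2])), 1e-9 * abs(qv[3]))
  # the n = 1, b_delta = 1 member is flow-compensated: residual flow
  # sensitivity (from the finite lobes) is a few percent of the
  # non-compensated n = 0 counterpart at matched amplitude
  w1 <- cached_waveform(1, 1, n_samples = 2^13)
  w0 <- cached_waveform(0, 1, n_samples = 2^13)
  qv1 <- sqrt(sum(flow_vector(w1)^2)) / max(abs(w1$q))
  qv0 <- sqrt(sum(flow_vector(w0)^2)) / max(abs(w0$q))
  expect_lt(qv1 / qv0, 0.05)
})

test_that("dephasing spectrum obeys the transform conventions and Parseval", {
  w <- cached_waveform(4, 0.5, n_samples = 2^13)
  ds <- dephasing_spectrum(w, pad = 8)
  # Parseval: one-sided spectral power equals the time-domain power
  lhs <- sum(ds$weight * rowSums(Mod(ds$Q)^2)) * ds$domega / (2 * pi)
  rhs <- sum(vapply(1:3, function(k) dorwave:::trapz(w$q[, k]^2, w$dt),
                    numeric(1)))
  expect_equal(lhs / rhs, 1, tolerance = 1e-6)
  # windowed sine concentrates near its carrier frequency
  f0 <- 400
  ws <- w
  ws$q <- cbind(sin(2 * pi * f0 * w$t), 0, 0)
  dss <- dephasing_spectrum(ws, pad = 8)
  pk <- dss$omega[which.max(Mod(dss$Q[, 1])^2)]
  expect_equal(pk / (2 * pi), f0, tolerance = 0.02)
})

test_that("encoding spectrum is Hermitian positive semidefinite", {
  w <- cached_waveform(3, -0.5, n_samples = 2^13)
  es <- encoding_spectrum(w, pad = 4)
  idx <- round(seq(1, length(es$omega) / 8, length.out = 200))
  bt <- encoding_tensor(es, idx)
  scale <- max(es$trace)
  for (j in seq_along(idx)) {
    B <- bt[, , j]
    expect_lt(max(Mod(B - Conj(t(B)))), 1e-12 * scale)
    ev <- eigen(B, symmetric = FALSE, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-12 * scale)
  }
  # single-axis waveform: only the zz element is nonzero
  wz <- st_waveform()
  esz <- encoding_spectrum(wz, pad = 2)
  expect_equal(max(Mod(esz$Q[, 1:2])), 0)
  expect_gt(max(Mod(esz$Q[, 3])), 0)
})

test_that("b-tensor matches classical closed forms and Parseval", {
  # rectangular Stejskal-Tanner pair
  g <- 0.1; delta <- 0.2 * 25e-3; Delta <- 25e-3 - delta
  w <- st_waveform(g = g, delta_frac = 0.2)
  b_num <- sum(diag(dorwave:::btensor_matrix(w)))
  b_cf <- (w$gamma * g * delta)^2 * (Delta - delta / 3)
  expect_equal(b_num / b_cf, 1, tolerance = 1e-6)
  # isotropic member: b-matrix = (b/3) identity
  wi <- cached_waveform(2, 0)
  B <- dorwave:::btensor_matrix(wi)
  expect_equal(B / (sum(diag(B)) / 3), diag(3), tolerance = 1e-4)
  expect_lt(abs(shape_metrics(B)$b_delta), 1e-3)
  # frequency-domain b-matrix equals the time-domain one
  es <- encoding_spectrum(wi, pad = 8)
  b_freq <- sum(es$weight * es$trace) * es$domega
  expect_equal(b_freq / sum(diag(B)), 1, tolerance = 1e-6)
})

test_that("shape metrics implement the Haeberlen convention", {
  b <- 4e9
  expect_equal(shape_metrics(diag(rep(b / 3, 3)))$b_delta, 0)
  expect_equal(shape_metrics(diag(rep(b / 3, 3)))$b_eta, 0)
  expect_equal(shape_metrics(diag(c(0, 0, b)))$b_delta, 1)
  expect_equal(shape_metrics(diag(c(b / 2, b / 2, 0)))$b_delta, -0.5)
  sm <- shape_metrics(diag(c(0.2, 0.3, 0.5) * b))
  expect_true(sm$b_delta >= -0.5 && sm$b_delta <= 1)
  expect_error(shape_metrics(matrix(0, 3, 3)), "trace")
})

test_that("centroid frequency recovers a narrowband carrier", {
  # cosine gradient over integer periods
  tau <- 25e-3; f0 <- 320; N <- 2^13
  t <- seq(0, tau, length.out = N)
  g <- cbind(0, 0, cos(2 * pi * f0 * t) - 0)
  # taper to an integer number of periods so q refocuses
  w <- structure(list(t = t, g = g, dt = tau / (N - 1), tau = tau,
                      gamma = GAMMA_1H, spec = NULL,
                      orientation = c(theta = 0, phi = 0)),
                 class = "waveform_3d")
  w$q <- dephasing_trajectory(w)
  fc <- centroid_frequency(encoding_spectrum(w, pad = 8)) / (2 * pi)
  expect_equal(fc / f0, 1, tolerance = 0.02)
})

test_that("main frequency components follow the ratio arithmetic", {
  mf <- main_frequencies(4, 360, 25e-3)
  expect_equal(mf$f1, 160)
  expect_equal(main_frequencies(5, 360, 25e-3)$f_p, 240)
  expect_equal(main_frequencies(0, 360, 25e-3)$omega1, 0)
  # impulsive-limit (constant dephasing magnitude) spectral peaks sit at
  # omega1 on the z axis and omega_p on the transverse axes
  tau <- 25e-3; N <- 2^13
  t <- seq(0, tau, length.out = N)
  psi2 <- 2 * pi * t / tau
  u <- dorwave:::dor_unit_vector(4 * psi2, psi2, 90, -magic_angle())
  wimp <- list(q = u, dt = tau / (N - 1))
  es <- dephasing_spectrum(structure(wimp, class = "waveform_3d"), pad = 8)
  pz <- es$omega[which.max(Mod(es$Q[, 3])^2)] / (2 * pi)
  px <- es$omega[which.max(Mod(es$Q[, 1])^2)] / (2 * pi)
  expect_equal(pz / 160, 1, tolerance = 0.02)
  expect_equal(px / 200, 1, tolerance = 0.02)
  # with finite lobes the peaks shift up by the plateau/duration ratio but
  # keep the z vs transverse ordering
  wf <- cached_waveform(4, 0)
  esf <- dephasing_spectrum(bracket_pair(wf), pad = 8)
  pzf <- esf$omega[which.max(Mod(esf$Q[, 3])^2)]
  pxf <- esf$omega[which.max(Mod(esf$Q[, 1])^2)]
  expect_equal(pxf / pzf, 5 / 4, tolerance = 0.02)
})
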