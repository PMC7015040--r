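test_that("mu normalization follows the printed formula", {
  # nu = 1.3, tau = 1.0: mu = 2*pi*1e-4/1.3 ~ 4.8332e-4
  expect_equal(compute_mu("accel", 0.1, 0.001, 1.3, 1.0), 4.8332e-4,
               tolerance = 1e-4)
  expect_equal(compute_mu("decel", 0.1, 0.001, 1.3, 1.0),
               -compute_mu("accel", 0.1, 0.001, 1.3, 1.0))
  # linear in the impulse duration
  expect_equal(compute_mu("accel", 0.1, 0.002, 1.3, 1.0),
               2 * compute_mu("accel", 0.1, 0.001, 1.3, 1.0))
})

test_that("phase-shift readout implements the event-time formula", {
  mu <- 4.8332e-4
  # unperturbed surrogate: crossings exactly at n*tau
  expect_equal(phase_shift_from_events(50 * 1.0, 50, 1.0, mu), 0)
  # a 1% early crossing maps to 2*pi*0.01/mu ~ 130.0
  expect_equal(phase_shift_from_events(50 - 0.01, 50, 1.0, mu),
               2 * pi * 0.01 / mu, tolerance = 1e-10)
  expect_equal(phase_shift_from_events(50 - 0.01, 50, 1.0, mu), 130.0,
               tolerance = 0.05)
  expect_error(phase_shift_from_events(NA, 50, 1, mu))
})

test_that("prescribed-PRC oscillator: constant and sinusoidal curves recovered", {
  # constant PRC: estimate equals the constant at every phase, both
  # directions
  m <- toy_phase_oscillator(tau = 1, Zfun = function(p) rep(0.7, length(p)),
                            mu_mag = 1e-3)
  est <- run_prc_experiment(m, phases = (0:7) / 8, n = 20)
  expect_true(all(est$ok))
  expect_equal(est$Z, rep(0.7, 16), tolerance = 1e-6)
  # sinusoidal PRC at small mu: within 2% of the amplitude
  m2 <- toy_phase_oscillator(tau = 1, Zfun = sin, mu_mag = 1e-3)
  ph <- (0:19) / 20
  est2 <- run_prc_experiment(m2, phases = ph, n = 20,
                             directions = "accel")
  expect_lt(max(abs(est2$Z - sin(2 * pi * ph))), 0.02)
})

test_that("finite-impulse bias grows with mu and shrinks as mu -> 0", {
  ph <- (0:9) / 10
  err <- vapply(c(1e-2, 1e-3, 1e-4) * 2 * pi, function(mm) {
    m <- toy_phase_oscillator(tau = 1, Zfun = sin, mu_mag = mm)
    est <- run_prc_experiment(m, phases = ph, n = 20, directions = "accel")
    max(abs(est$Z - sin(2 * pi * ph)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # error decreases monotonically
  expect_gt(err[1], 10 * err[3])
})

test_that("planar limit-cycle clock: estimator converges to the analytic PRC", {
  ph <- (0:14) / 15
  m <- toy_planar_oscillator(tau = 1, gamma = 3, beta = 1, kick = 1e-3)
  zan <- m$Z_analytic(2 * pi * ph)
  est <- run_prc_experiment(m, phases = ph, n = 30, directions = "accel")
  est <- est[order(est$phase_pct), ]
  expect_lt(max(abs(est$Z - zan)), 0.02 * max(abs(zan)))
  # fewer cycles leave a larger isochron-mismatch residual
  e5 <- run_prc_experiment(m, phases = ph, n = 3, directions = "accel")
  e5 <- e5[order(e5$phase_pct), ]
  expect_gt(max(abs(e5$Z - zan)), max(abs(est$Z - zan)))
})

test_that("sign correctness: delayed crossings give negative Z for accel", {
  # crossings uniformly delayed by 0.02 s: phase was pushed back
  mu <- 1e-3
  Z <- phase_shift_from_events(10 + 0.02, 10, 1.0, mu)
  expect_lt(Z, 0)
  # sign flips with the perturbation direction
  expect_gt(phase_shift_from_events(10 + 0.02, 10, 1.0, -mu), 0)
})

test_that("experiment bookkeeping: one row per phase and direction", {
  m <- toy_phase_oscillator(tau = 1, Zfun = sin)
  est <- run_prc_experiment(m, phases = c(0, 0.25, 0.5, 0.75), n = 12)
  expect_equal(nrow(est), 8)
  expect_setequal(unique(est$direction), c("accel", "decel"))
  expect_true(all(sort(unique(est$phase_pct)) == c(0, 25, 50, 75)))
  expect_true(all(est$converged))
})

test_that("feature extraction on closed-form curves", {
  ph <- 0:99
  est <- data.frame(phase_pct = ph, Z = sin(2 * pi * ph / 100),
                    ok = TRUE, direction = "accel")
  f <- extract_features(est)
  expect_equal(f$crossings, c(0, 50), tolerance = 1)
  expect_equal(f$max$phase_pct, 25, tolerance = 1)
  expect_equal(f$min$phase_pct, 75, tolerance = 1)
  # an all-zero curve has no crossings and no peaks
  f0 <- extract_features(data.frame(phase_pct = ph, Z = rep(0, 100),
                                    ok = TRUE))
  expect_length(f0$crossings, 0)
  expect_null(f0$peaks)
  expect_null(f0$troughs)
  # double-stance annotation
  f2 <- extract_features(est, double_stance = cbind(20, 30))
  expect_true(f2$max$in_double_stance)
  expect_false(f2$min$in_double_stance)
})

test_that("estimator floor is small at matched settings and finite", {
  fl <- estimator_floor(mu = 5e-4, n = 15, tau = 1)
  expect_true(is.finite(fl))
  expect_gt(fl, 0)
  expect_lt(fl, 0.05)
})
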