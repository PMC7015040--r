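test_that("synergy pulses reproduce the printed onset/duration table", {
  cfg <- default_config()
  # pulse 2: onset 1.48, duration 0.90
  expect_equal(synergy_pulse(2.0, 2, cfg), 1)
  expect_equal(synergy_pulse(1.48, 2, cfg), 0)     # strict left boundary
  expect_equal(synergy_pulse(2.38, 2, cfg), 1)     # closed right boundary
  expect_equal(synergy_pulse(2.39, 2, cfg), 0)
  # pulse 1 wraps through 2*pi: 6.12 + 0.70 - 2*pi ~ 0.537
  expect_equal(synergy_pulse(0.3, 1, cfg), 1)
  expect_equal(synergy_pulse(0.6, 1, cfg), 0)
  expect_equal(synergy_pulse(6.2, 1, cfg), 1)
  expect_error(synergy_pulse(1, 6, cfg), "index")
})

test_that("synergy command combines the printed weights only", {
  cfg <- default_config()
  # phase inside pulse 2 only: SO and GC active with printed weights
  u <- synergy_command(2.0, cfg)
  expect_equal(u[["SO"]], 1.26)
  expect_equal(u[["GC"]], 0.87)
  expect_equal(unname(u[setdiff(names(u), c("SO", "GC"))]), rep(0, 7))
  # a phase in no pulse: all zero (gap between pulse 1 end 0.537 and 1.48)
  expect_equal(unname(synergy_command(1.0, cfg)), rep(0, 9))
  # zero amplitudes kill everything
  cfg0 <- cfg; cfg0$ctrl$Lambda <- rep(0, 5)
  expect_equal(unname(synergy_command(2.0, cfg0)), rep(0, 9))
  # exactly 12 nonzero weights in the printed pattern
  expect_equal(sum(cfg$ctrl$weights != 0), 12)
  # piecewise constant with at most 10 discontinuities over a cycle
  phis <- seq(0, 2 * pi, length.out = 20001)
  U <- vapply(phis, function(p) sum(synergy_command(p, cfg)), numeric(1))
  expect_lte(sum(diff(U) != 0), 10)
})

test_that("phase dynamics: antiphase equilibrium and -2K relaxation rate", {
  cfg <- default_config()
  om <- 2 * pi / cfg$ctrl$cycle_period
  expect_equal(phase_rate(c(0, pi), "right", cfg), om)
  expect_equal(phase_rate(c(0, pi), "left", cfg), om)
  expect_equal(phase_rate(c(0, 0), "right", cfg),
               om - cfg$ctrl$K_phi * sin(-pi))
  # two uncoupled-from-body oscillators: the phase difference relaxes to
  # pi with eigenvalue -2 K_phi (checked against the linearized solution)
  K <- cfg$ctrl$K_phi
  dt <- 1e-5
  d <- pi + 0.1   # small offset from antiphase
  for (i in seq_len(round(1 / dt))) {
    dd <- -2 * K * sin(d - pi)   # difference dynamics
    d <- d + dt * dd
  }
  expect_equal(d - pi, 0.1 * exp(-2 * K), tolerance = 1e-3)
  # and the full two-oscillator integration converges to antiphase
  ph <- c(0.3, 0.8)
  for (i in seq_len(round(20 / K / dt))) {
    ph <- ph + dt * c(phase_rate(ph, "right", cfg),
                      phase_rate(ph, "left", cfg))
  }
  expect_lt(abs((ph[1] - ph[2]) %% (2 * pi) - pi), 1e-3)
})

test_that("phase reset assigns phi_fc exactly and respects the ablation flag", {
  cfg <- default_config()
  st <- list(phi = c(1.2, 3.0), due = c(10.05, NA))
  out <- apply_phase_reset(st, "right", t_now = 10.05, cfg = cfg)
  expect_equal(out$phi[1], cfg$ctrl$phi_fc)
  expect_true(is.na(out$due[1]))
  # already at phi_fc: no change
  st2 <- list(phi = c(cfg$ctrl$phi_fc, 0), due = c(5, NA))
  expect_equal(apply_phase_reset(st2, "right", 5, cfg)$phi[1],
               cfg$ctrl$phi_fc)
  # ablated model: event consumed, phase untouched
  out <- apply_phase_reset(st, "right", 10.05, cfg, resetting = FALSE)
  expect_equal(out$phi[1], 1.2)
  expect_true(is.na(out$due[1]))
  # errors: no pending event, or called before due time
  expect_error(apply_phase_reset(st, "left", 10.05, cfg), "pending")
  expect_error(apply_phase_reset(st, "right", 9.0, cfg), "due")
})

test_that("trunk regulation: printed gains, stance gating", {
  cfg <- default_config()
  th_hat <- cfg$ctrl$theta_ref
  # at the reference with zero rate: silent
  expect_equal(unname(trunk_regulation(th_hat, 0, c(TRUE, TRUE), cfg)),
               rep(0, 18))
  # theta error +0.1 in right stance: p_GM = -2.0 * 0.1, p_IL = +0.1
  p <- trunk_regulation(th_hat + 0.1, 0, c(TRUE, FALSE), cfg)
  expect_equal(p[["GM_r"]], -0.2)
  expect_equal(p[["IL_r"]], 0.1)
  expect_equal(unname(p[10:18]), rep(0, 9))   # swing leg silent
  # rate feedback uses the printed sigmas
  p <- trunk_regulation(th_hat, 0.5, c(TRUE, FALSE), cfg)
  expect_equal(p[["GM_r"]], -0.4 * 0.5)
  expect_equal(p[["IL_r"]], 0.2 * 0.5)
})

test_that("speed regulation: printed gains, push-off increased when slow", {
  cfg <- default_config()
  expect_equal(unname(speed_regulation(cfg$ctrl$v_ref, c(TRUE, TRUE), cfg)),
               rep(0, 18))
  # 0.1 m/s below target: SO up by 0.012, TA down by 0.02
  p <- speed_regulation(cfg$ctrl$v_ref - 0.1, c(TRUE, FALSE), cfg)
  expect_equal(p[["SO_r"]], 0.012)
  expect_equal(p[["TA_r"]], -0.02)
  expect_equal(unname(p[10:18]), rep(0, 9))
})

test_that("delayed regulation command: warm-up zeros and exact sinusoid lag", {
  tau_reg <- default_config()$ctrl$tau_reg
  # history shorter than the delay: zero command
  expect_equal(regulation_command(c(0, 0.01), matrix(1, 2, 1), 0.05,
                                  tau_reg), 0)
  # constant history passes through
  ts <- seq(0, 1, by = 1e-3)
  expect_equal(regulation_command(ts, matrix(0.7, length(ts), 1), 0.9,
                                  tau_reg), 0.7)
  # sinusoid at the gait frequency: phase lag exactly omega * tau_reg
  om <- 2 * pi
  p <- matrix(sin(om * ts), ncol = 1)
  got <- regulation_command(ts, p, 0.8, tau_reg)
  expect_equal(got, sin(om * (0.8 - tau_reg)), tolerance = 1e-5)
})

test_that("total command sums and clamps", {
  expect_equal(total_command(0.3, 0.2), 0.5)
  expect_equal(total_command(0.1, -0.5), 0)
  expect_equal(total_command(0.9, 0.5), 1)
  expect_equal(total_command(0.4, 0), 0.4)
  expect_equal(total_command(1.5, 0.5, clamp = FALSE), 2.0)
})
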