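test_that("identical configurations give bit-identical trajectories", {
  cfg <- default_config()
  r1 <- run_walking(cfg, duration = 1)
  r2 <- run_walking(cfg, duration = 1)
  expect_identical(r1$traj, r2$traj)
  expect_identical(r1$events, r2$events)
})

test_that("resuming a run continues it exactly", {
  cfg <- default_config()
  whole <- run_walking(cfg, duration = 1.2)
  first <- run_walking(cfg, duration = 0.6)
  second <- run_walking(cfg, duration = 0.6, state = first$state)
  expect_equal(second$state$q, whole$state$q, tolerance = 1e-10)
  expect_equal(second$state$qd, whole$state$qd, tolerance = 1e-10)
  expect_equal(second$state$phi, whole$state$phi, tolerance = 1e-10)
})

test_that("passive airborne trunk follows ballistic motion", {
  cfg <- passive_config()
  q0 <- rep(0, 9); q0[2] <- 5
  qd0 <- rep(0, 9); qd0[1] <- 0.4; qd0[2] <- 0.3
  st <- initial_state(q = q0, qd = qd0, act = rep(0, 18), cfg = cfg,
                      settle_z = FALSE)
  r <- run_walking(cfg, duration = 0.5, state = st, belt = list(nu = 0.01))
  tr <- r$traj
  t <- tr[, "t"]
  expect_equal(tr[, "x"], 0.4 * t, tolerance = 1e-9)
  expect_equal(tr[, "z"], 5 + 0.3 * t - 0.5 * cfg$body$g * t^2,
               tolerance = 1e-9)
})

test_that("foot-contact events are located by interpolation near the analytic time", {
  cfg <- passive_config()
  # drop the skeleton flat-footed from a small height; contact is
  # registered when the sole penetrates 2 mm
  h0 <- 0.05
  q0 <- rep(0, 9); q0[2] <- standing_height(cfg) + h0
  st <- initial_state(q = q0, qd = rep(0, 9), act = rep(0, 18), cfg = cfg,
                      settle_z = FALSE)
  r <- run_walking(cfg, duration = 0.3, state = st, belt = list(nu = 0.01))
  t_pred <- sqrt(2 * (h0 + 0.002) / cfg$body$g)
  expect_gt(length(r$events$contact_r), 0)
  expect_equal(r$events$contact_r[1], t_pred, tolerance = 2e-3)
  expect_equal(r$events$contact_l[1], t_pred, tolerance = 2e-3)
})

test_that("no contact events are produced while fully airborne", {
  cfg <- passive_config()
  q0 <- rep(0, 9); q0[2] <- 5
  st <- initial_state(q = q0, act = rep(0, 18), cfg = cfg, settle_z = FALSE)
  r <- run_walking(cfg, duration = 0.3, state = st, belt = list(nu = 0.01))
  expect_length(r$events$contact_r, 0)
  expect_length(r$events$contact_l, 0)
})

test_that("zeroed synergy weights cannot sustain gait", {
  cfg <- default_config()
  cfg$ctrl$weights[] <- 0
  r <- run_walking(cfg, duration = 6)
  expect_equal(r$status, "fall")
  expect_lt(r$fall_time, 6)
})

test_that("perturbation schedules map phase to onset time", {
  b <- apply_perturbation(0, "accel", t_anchor = 12.3, tau = 1.0, nu = 1.3)
  expect_equal(b$pert_on, 12.3)    # s = 0 is a right-foot contact
  expect_equal(b$pert_sign, 1)
  b2 <- apply_perturbation(0.4, "decel", t_anchor = 12.3, tau = 0.9,
                           nu = 1.3)
  expect_equal(b2$pert_on, 12.3 + 0.36)
  expect_equal(b2$pert_sign, -1)
  # accel/decel at the same phase differ only in sign
  b3 <- apply_perturbation(0.4, "accel", 12.3, 0.9, 1.3)
  expect_equal(b3[names(b3) != "pert_sign"], b2[names(b2) != "pert_sign"])
  # 100 equally spaced phases span exactly one cycle
  on <- vapply((0:99) / 100, function(s)
    apply_perturbation(s, "accel", 0, 1, 1.3)$pert_on, numeric(1))
  expect_equal(on, (0:99) / 100)
})

test_that("the nominal model walks several strides and then the run ends cleanly", {
  cfg <- default_config()
  r <- run_walking(cfg, duration = 10)
  ge <- gait_events(r)
  expect_gte(length(ge$cycles), 3)
  # contacts alternate between legs while the gait lasts
  ev <- rbind(data.frame(t = ge$cycles, leg = "r"),
              data.frame(t = ge$contact_l, leg = "l"))
  ev <- ev[order(ev$t), ]
  expect_true(all(ev$leg[-1] != ev$leg[-nrow(ev)]))
  # a fall is a structured outcome, not an error
  expect_true(r$status %in% c("ok", "fall"))
  if (r$status == "fall") expect_true(is.finite(r$fall_time))
})

test_that("trajectory and events round-trip through the writers", {
  cfg <- default_config()
  r <- run_walking(cfg, duration = 0.5)
  dir <- withr::local_tempdir()
  paths <- write_run(r, dir, "t", cfg = cfg)
  tr <- read_trajectory(paths[["trajectory"]])
  expect_equal(unname(tr), unname(r$traj), tolerance = 1e-12)
  expect_identical(colnames(tr), colnames(r$traj))
  ev <- jsonlite::read_json(paths[["events"]], simplifyVector = TRUE)
  expect_equal(ev$events$contact_r, r$events$contact_r, tolerance = 1e-12)
  expect_true(file.exists(paths[["manifest"]]))
})
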