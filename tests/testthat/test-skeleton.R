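test_that("forward kinematics: symmetry, rigid translation, ordering", {
  cfg <- default_config()
  q0 <- rep(0, 9)
  q0[2] <- standing_height(cfg)
  pts <- forward_kinematics(q0, cfg = cfg)
  # identical straight legs: matching points of both feet coincide
  expect_equal(pts[1:4, "z"], pts[5:8, "z"], ignore_attr = TRUE)
  expect_equal(pts[1:4, "x"], pts[5:8, "x"], ignore_attr = TRUE)
  # soles flat on the surface
  expect_equal(unname(pts[, "z"]), rep(0, 8), tolerance = 1e-12)
  # heel-to-toe span equals the sole length, inner points 0.04 m inside
  expect_equal(pts["r_toe", "x"] - pts["r_heel", "x"],
               cfg$body$d_toe + cfg$body$d_heel)
  expect_equal(pts["r_toe", "x"] - pts["r_toe_in", "x"],
               cfg$body$inner_offset)
  expect_equal(pts["r_heel_in", "x"] - pts["r_heel", "x"],
               cfg$body$inner_offset)
  # rigid translation moves every point by the same offset
  q1 <- q0; q1[1] <- q1[1] + 0.1
  pts1 <- forward_kinematics(q1, cfg = cfg)
  expect_equal(pts1[, "x"], pts[, "x"] + 0.1, tolerance = 1e-12)
  expect_equal(pts1[, "z"], pts[, "z"], tolerance = 1e-12)
})

test_that("forward kinematics velocities match finite differences", {
  cfg <- default_config()
  set.seed(11)
  for (rep in 1:5) {
    q <- runif(9, -0.5, 0.5)
    qd <- runif(9, -2, 2)
    eps <- 1e-6
    p1 <- forward_kinematics(q + eps * qd / 2, qd, cfg)
    p0 <- forward_kinematics(q - eps * qd / 2, qd, cfg)
    vfd <- (p1[, 1:2] - p0[, 1:2]) / eps
    v <- forward_kinematics(q, qd, cfg)[, 3:4]
    expect_lt(max(abs(vfd - v)) / max(1, max(abs(v))), 1e-6)
  }
})

test_that("forward kinematics rejects non-finite state", {
  q <- rep(0, 9); q[4] <- NaN
  expect_error(forward_kinematics(q), "non-finite")
})

test_that("contact forces: unilateral spring-damper with belt-convected anchor", {
  cfg <- default_config()
  # point above the surface: no force
  f <- contact_forces(c(0, 0.01), c(0, -1), cfg = cfg)
  expect_equal(unname(f), c(0, 0))
  # static penetration with the anchor at the point: pure normal spring
  d <- 0.003
  f <- contact_forces(c(0.2, -d), c(0, 0), anchor_x = 0.2, belt_speed = 0,
                      cfg = cfg)
  expect_equal(f[["fz"]], cfg$contact$k_normal * d)
  expect_equal(f[["fx"]], 0)
  # upward-moving point: damping can cancel the spring but never sucks down
  f <- contact_forces(c(0, -1e-4), c(0, 1), cfg = cfg)
  expect_equal(unname(f), c(0, 0))
  # stationary penetrating point, moving belt: the anchor convects with
  # the belt, so the tangential spring stretches linearly in time; the
  # force direction drags the foot with the belt (backward)
  nu <- 1.3
  dtt <- 0.01
  anchor <- 0.0 - nu * dtt  # anchor after dtt of convection
  f <- contact_forces(c(0, -0.005), c(0, 0), anchor_x = anchor,
                      belt_speed = nu, cfg = cfg)
  expected <- -cfg$contact$k_tangent * (0 - anchor) -
    cfg$contact$c_tangent * (0 - (-nu))
  cap <- cfg$contact$mu_tangent * f[["fz"]]
  expect_equal(f[["fx"]], max(min(expected, cap), -cap))
  expect_lt(f[["fx"]], 0)
  # tangential force is bounded by the normal load
  f2 <- contact_forces(c(0, -1e-4), c(5, 0), anchor_x = 1, belt_speed = nu,
                       cfg = cfg)
  expect_lte(abs(f2[["fx"]]), cfg$contact$mu_tangent * f2[["fz"]] + 1e-9)
})

test_that("passive joint torques: viscosity and one-sided limits", {
  cfg <- default_config()
  q <- rep(0, 9); q[2] <- 1
  q[5] <- 0.5 * (cfg$joints$knee_lo + cfg$joints$knee_hi)  # inside limits
  q[8] <- q[5]
  tau <- passive_joint_torques(q, rep(0, 9), cfg)
  expect_equal(unname(tau), rep(0, 6))
  # pure rate: torque = -viscosity * rate
  qd <- rep(0, 9); qd[4] <- 2
  tau <- passive_joint_torques(q, qd, cfg)
  expect_equal(tau[["hip_r"]], -cfg$joints$visc_hip * 2)
  # knee beyond its extension limit: linear restoring torque
  q2 <- rep(0, 9); q2[5] <- cfg$joints$knee_lo - 0.1
  tau <- passive_joint_torques(q2, rep(0, 9), cfg)
  expect_equal(tau[["knee_r"]], cfg$joints$k_limit * 0.1)
  # viscous power is dissipative for random states
  set.seed(2)
  cfg0 <- default_config(); cfg0$joints$k_limit <- 0; cfg0$joints$c_limit <- 0
  for (i in 1:20) {
    qd <- runif(9, -3, 3)
    tau <- passive_joint_torques(runif(9, -0.5, 0.5), qd, cfg0)
    expect_lte(sum(tau * qd[4:9]), 1e-12)
  }
})

test_that("mass matrix is symmetric positive definite across configurations", {
  cfg <- default_config()
  set.seed(3)
  for (i in 1:100) {
    q <- runif(9, -1, 1)
    M <- mass_matrix(q, cfg)
    expect_equal(M, t(M), tolerance = 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("free fall: trunk acceleration is -g, horizontal zero", {
  cfg <- default_config()
  q <- rep(0, 9); q[2] <- 5
  a <- accelerations(q, rep(0, 9), cfg = cfg)
  expect_equal(a[1], 0, tolerance = 1e-10)
  expect_equal(a[2], -cfg$body$g, tolerance = 1e-10)
  expect_equal(a[3], 0, tolerance = 1e-10)
})

test_that("accelerations match the finite-difference Lagrangian oracle", {
  cfg <- default_config()
  set.seed(4)
  for (rep in 1:3) {
    q <- runif(9, -0.6, 0.6); q[2] <- 2
    qd <- runif(9, -1.5, 1.5)
    tau6 <- runif(6, -10, 10)
    a_pkg <- accelerations(q, qd, tau6, matrix(0, 8, 2), cfg)
    a_fd <- accelerations_fd(q, qd, tau6, cfg)
    expect_lt(max(abs(a_pkg - a_fd)) / max(abs(a_pkg)), 1e-5)
  }
})

test_that("unit torque maps to the corresponding column of M^-1", {
  cfg <- default_config()
  q <- c(0, 2, 0.1, 0.3, 0.2, -0.1, -0.2, 0.4, 0.05)
  M <- mass_matrix(q, cfg)
  tau6 <- c(1, 0, 0, 0, 0, 0)
  a <- accelerations(q, rep(0, 9), tau6, cfg = cfg, gravity = FALSE)
  expect_equal(a, solve(M)[, 4], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("mirror symmetry: swapping legs mirrors all per-leg outputs", {
  cfg <- default_config()
  set.seed(5)
  q <- runif(9, -0.5, 0.5); q[2] <- 1
  qd <- runif(9, -1, 1)
  pts <- forward_kinematics(q, qd, cfg)
  pts_sw <- forward_kinematics(swap_legs(q), swap_legs(qd), cfg)
  expect_equal(unname(pts_sw[c(5:8, 1:4), ]), unname(pts),
               tolerance = 1e-12)
  tau <- passive_joint_torques(q, qd, cfg)
  tau_sw <- passive_joint_torques(swap_legs(q), swap_legs(qd), cfg)
  expect_equal(unname(tau_sw[c(4:6, 1:3)]), unname(tau), tolerance = 1e-12)
  a <- accelerations(q, qd, cfg = cfg)
  a_sw <- accelerations(swap_legs(q), swap_legs(qd), cfg = cfg)
  expect_equal(swap_legs(a_sw), a, tolerance = 1e-9)
})

test_that("passive frictionless skeleton conserves energy in flight", {
  cfg <- passive_config()
  q0 <- c(0, 8, 0.1, 0.3, 0.4, -0.1, -0.2, 0.3, 0.2)
  qd0 <- c(0.3, 0.5, 0.5, -1, 0.5, 0.3, 1, -0.5, 0.2)
  st <- initial_state(q = q0, qd = qd0, act = rep(0, 18), cfg = cfg,
                      settle_z = FALSE)
  r <- run_walking(cfg, duration = 1, state = st, belt = list(nu = 0.01))
  E0 <- sum(mechanical_energy(q0, qd0, cfg))
  E1 <- sum(mechanical_energy(r$state$q, r$state$qd, cfg))
  expect_lt(abs(E1 - E0) / abs(E0), 1e-8)
  # and the compiled energies agree with the R-only oracle
  Er <- energies_r(q0, qd0, cfg)
  Ec <- mechanical_energy(q0, qd0, cfg)
  expect_equal(unname(Ec), unname(Er), tolerance = 1e-5)
})
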