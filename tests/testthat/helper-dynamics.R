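# R-only reimplementation of the center-of-mass kinematics and energies,
# used as the independent oracle for the compiled dynamics.

com_positions_r <- function(q, cfg) {
  b <- cfg$body
  e <- function(a) c(sin(a), -cos(a))
  rot <- function(a, v) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  hip <- q[1:2]
  th <- q[3]
  out <- matrix(NA_real_, 7, 2)
  out[1, ] <- hip + b$c_trunk * c(-sin(th), cos(th))
  angs <- numeric(7)
  angs[1] <- th
  for (leg in 0:1) {
    jb <- 4 + 3 * leg
    a_th <- th + q[jb]; a_sh <- a_th - q[jb + 1]; a_ft <- a_sh + q[jb + 2]
    knee <- hip + b$L_thigh * e(a_th)
    ankle <- knee + b$L_shank * e(a_sh)
    ib <- 2 + 3 * leg
    out[ib, ] <- hip + b$c_thigh * e(a_th)
    out[ib + 1, ] <- knee + b$c_shank * e(a_sh)
    out[ib + 2, ] <- ankle + rot(a_ft, c(b$foot_com_x, b$foot_com_z))
    angs[ib:(ib + 2)] <- c(a_th, a_sh, a_ft)
  }
  list(com = out, ang = angs)
}

com_velocities_r <- function(q, qd, cfg) {
  b <- cfg$body
  e <- function(a) c(sin(a), -cos(a))
  de <- function(a, w) w * c(cos(a), sin(a))
  drot <- function(a, v, w) w * c(-sin(a) * v[1] - cos(a) * v[2],
                                  cos(a) * v[1] - sin(a) * v[2])
  vhip <- qd[1:2]
  th <- q[3]; wth <- qd[3]
  v <- matrix(NA_real_, 7, 2)
  w <- numeric(7)
  v[1, ] <- vhip + b$c_trunk * wth * c(-cos(th), -sin(th))
  w[1] <- wth
  for (leg in 0:1) {
    jb <- 4 + 3 * leg
    a_th <- th + q[jb]; a_sh <- a_th - q[jb + 1]; a_ft <- a_sh + q[jb + 2]
    w_th <- wth + qd[jb]; w_sh <- w_th - qd[jb + 1]
    w_ft <- w_sh + qd[jb + 2]
    vknee <- vhip + b$L_thigh * de(a_th, w_th)
    vankle <- vknee + b$L_shank * de(a_sh, w_sh)
    ib <- 2 + 3 * leg
    v[ib, ] <- vhip + b$c_thigh * de(a_th, w_th)
    v[ib + 1, ] <- vknee + b$c_shank * de(a_sh, w_sh)
    v[ib + 2, ] <- vankle + drot(a_ft, c(b$foot_com_x, b$foot_com_z), w_ft)
    w[ib:(ib + 2)] <- c(w_th, w_sh, w_ft)
  }
  list(v = v, w = w)
}

energies_r <- function(q, qd, cfg) {
  b <- cfg$body
  masses <- with(b, c(m_trunk, m_thigh, m_shank, m_foot,
                      m_thigh, m_shank, m_foot))
  inert <- with(b, c(I_trunk, I_thigh, I_shank, I_foot,
                     I_thigh, I_shank, I_foot))
  vel <- com_velocities_r(q, qd, cfg)
  kc <- com_positions_r(q, cfg)
  ke <- sum(0.5 * masses * rowSums(vel$v^2)) + sum(0.5 * inert * vel$w^2)
  pe <- sum(masses * b$g * kc$com[, 2])
  c(kinetic = ke, potential = pe)
}

# Finite-difference Lagrangian oracle: generalized accelerations from
# numeric derivatives of the R-only energies, independent of the compiled
# mass-matrix/bias assembly.
accelerations_fd <- function(q, qd, tau6, cfg, h = 1e-5) {
  KE <- function(q, qd) energies_r(q, qd, cfg)["kinetic"]
  PE <- function(q) energies_r(q, rep(0, 9), cfg)["potential"]
  M <- matrix(0, 9, 9)
  for (i in 1:9) for (j in i:9) {
    ei <- ej <- rep(0, 9); ei[i] <- h; ej[j] <- h
    M[i, j] <- M[j, i] <- (KE(q, ei + ej) - KE(q, ei) - KE(q, ej)) / h^2
  }
  dKEdqd <- function(q, qd) {
    vapply(1:9, function(i) {
      e <- rep(0, 9); e[i] <- h
      (KE(q, qd + e) - KE(q, qd - e)) / (2 * h)
    }, numeric(1))
  }
  dLdq <- vapply(1:9, function(i) {
    e <- rep(0, 9); e[i] <- h
    (KE(q + e, qd) - PE(q + e) - KE(q - e, qd) + PE(q - e)) / (2 * h)
  }, numeric(1))
  pdot <- (dKEdqd(q + h * qd, qd) - dKEdqd(q - h * qd, qd)) / (2 * h)
  Q <- c(rep(0, 3), tau6)
  solve(M, Q + dLdq - pdot)
}

# a configuration with every dissipative and active element disabled:
# the passive frictionless skeleton
passive_config <- function() {
  cfg <- default_config()
  cfg$joints$visc_hip <- cfg$joints$visc_knee <- cfg$joints$visc_ankle <- 0
  cfg$joints$k_limit <- 0
  cfg$joints$c_limit <- 0
  cfg$muscles$table[, "kpe"] <- 0
  cfg$ctrl$weights[] <- 0
  cfg$ctrl$kappa_IL <- cfg$ctrl$kappa_GM <- 0
  cfg$ctrl$sigma_IL <- cfg$ctrl$sigma_GM <- 0
  cfg$ctrl$lambda_TA <- cfg$ctrl$lambda_SO <- 0
  cfg
}

# swap the left and right leg entries of a 9-vector (q or qd)
swap_legs <- function(q) q[c(1, 2, 3, 7, 8, 9, 4, 5, 6)]
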