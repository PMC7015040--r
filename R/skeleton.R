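#' Forward kinematics of the eight sole contact points
#'
#' Positions and velocities, in the world frame, of the four contact points
#' of each sole (toe, toe inner, heel inner, heel; right foot first).  The
#' two inner points sit `inner_offset` (0.04 m) inside the toe and heel
#' points.
#'
#' @param q,qd generalized coordinates and velocities, length 9, in the
#'   order of [coord_names()]
#' @param cfg configuration list (see [default_config()])
#' @return 8 x 4 matrix with columns `x`, `z`, `vx`, `vz`
#' @export
forward_kinematics <- function(q, qd = rep(0, 9), cfg = default_config()) {
  pg_fk_points(as.numeric(q), as.numeric(qd), cpp_params(cfg))
}

#' Treadmill contact force at one sole point
#'
#' Unilateral linear spring-damper in each direction.  The vertical force
#' acts on penetration depth and rate and is clamped to be non-negative (no
#' adhesion).  The tangential force acts on the displacement of the point
#' from its anchor and on the velocity relative to the moving belt; the
#' anchor convects with the belt while the point is in contact, which is
#' what makes a belt-speed change a mechanical perturbation.  A point above
#' the surface produces zero force.
#'
#' @param pos,vel point position and velocity `c(x, z)`
#' @param anchor_x current tangential anchor position
#' @param belt_speed belt speed `nu` (m/s, positive; the belt surface moves
#'   backward, i.e. at world velocity `-nu`)
#' @param cfg configuration list
#' @return named vector `c(fx, fz)`
#' @export
contact_forces <- function(pos, vel, anchor_x = pos[1], belt_speed = 1.3,
                           cfg = default_config()) {
  pg_contact_force(as.numeric(pos), as.numeric(vel), anchor_x, -belt_speed,
                   cpp_params(cfg))
}

#' Passive joint torques
#'
#' Linear viscous torque at every joint, plus large linear elastic and
#' damping torques at the knee and ankle when the angle exceeds its limits.
#'
#' @inheritParams forward_kinematics
#' @return named vector of 6 torques (hip/knee/ankle, right then left)
#' @export
passive_joint_torques <- function(q, qd, cfg = default_config()) {
  pg_passive_torques(as.numeric(q), as.numeric(qd), cpp_params(cfg))
}

#' Mass matrix of the skeleton
#'
#' @inheritParams forward_kinematics
#' @return symmetric positive-definite 9 x 9 matrix
#' @export
mass_matrix <- function(q, cfg = default_config()) {
  pg_mass_matrix(as.numeric(q), cpp_params(cfg))
}

#' Generalized accelerations
#'
#' Solves `M(q) qdd + h(q, qd) = Q` for `qdd`, where `Q` collects the six
#' joint torques (muscle plus passive) and the external forces at the eight
#' sole points.
#'
#' @inheritParams forward_kinematics
#' @param joint_torques length-6 torque vector (hip/knee/ankle, right then
#'   left, flexion positive)
#' @param point_forces 8 x 2 matrix of `(fx, fz)` at the sole points, in
#'   the row order of [forward_kinematics()]
#' @param gravity include gravity (disable for analytic checks)
#' @return length-9 acceleration vector
#' @export
accelerations <- function(q, qd, joint_torques = rep(0, 6),
                          point_forces = matrix(0, 8, 2),
                          cfg = default_config(), gravity = TRUE) {
  stopifnot(length(joint_torques) == 6)
  pg_accelerations(as.numeric(q), as.numeric(qd),
                   as.numeric(joint_torques), point_forces,
                   cpp_params(cfg), gravity)
}

#' Total mechanical energy of the skeleton
#'
#' Kinetic plus gravitational potential energy; used by the conservation
#' checks on the passive frictionless skeleton.
#'
#' @inheritParams forward_kinematics
#' @return named vector `c(kinetic, potential)`
#' @export
mechanical_energy <- function(q, qd, cfg = default_config()) {
  pg_energy(as.numeric(q), as.numeric(qd), cpp_params(cfg))
}

#' Standing hip height implied by the segment parameters
#' @param cfg configuration list
#' @export
standing_height <- function(cfg = default_config()) {
  with(cfg$body, L_thigh + L_shank + sole_z)
}

#' Build a full simulation state from a posture
#'
#' Assembles the resume-state structure used by [run_walking()]: body
#' coordinates and velocities, muscle activations, oscillator phases,
#' tangential contact anchors and an empty regulation-delay history.  By
#' default the vertical position is adjusted so the lowest sole point just
#' touches the belt.
#'
#' @param q length-9 posture; `z` is overridden when `settle_z` is TRUE
#' @param qd length-9 velocities
#' @param phi oscillator phases `c(right, left)`
#' @param act 18 muscle activations
#' @param cfg configuration list
#' @param settle_z drop the model so the lowest sole point sits 1 mm below
#'   the surface
#' @return state list consumed by [run_walking()]
#' @export
initial_state <- function(q = default_posture(), qd = rep(0, 9),
                          phi = c(0.36, 2.76), act = NULL,
                          cfg = default_config(), settle_z = TRUE) {
  q <- as.numeric(q); qd <- as.numeric(qd)
  if (is.null(act))
    act <- c(seed_activations(phi[1], cfg), seed_activations(phi[2], cfg))
  if (settle_z) {
    pts <- pg_fk_points(q, qd, cpp_params(cfg))
    q[2] <- q[2] - min(pts[, "z"]) - 0.004
  }
  pts <- pg_fk_points(q, qd, cpp_params(cfg))
  # feet already touching at t = 0 count as in stance, so that the first
  # foot-contact events (and phase resets) fire only on a real touchdown
  in_contact <- c(any(pts[1:4, "z"] < 0.002), any(pts[5:8, "z"] < 0.002))
  list(t = 0, q = q, qd = qd, act = as.numeric(act), phi = as.numeric(phi),
       anchors = as.numeric(pts[, "x"]),
       contact = in_contact, due = c(NA_real_, NA_real_),
       buf_t = numeric(0), buf_p = matrix(0, 0, 8))
}

#' Default bootstrap posture
#'
#' Symmetric split double-stance posture with both knees resting on the
#' extension stop.  Paired with the default oscillator phases (right leg
#' just reset at contact, left leg in late stance about to push off) the
#' treadmill belt starts the cycle from a statically supported state.
#' @param cfg configuration list
#' @export
default_posture <- function(cfg = default_config()) {
  stats::setNames(
    c(0, standing_height(cfg), -0.012,
      0.15, -0.10, 0.00,
      -0.15, -0.10, 0.00),
    coord_names())
}

# steady-state activation profile of the first-order filter driven by the
# periodic synergy command, evaluated at phase `phi`
seed_activations <- function(phi, cfg = default_config()) {
  omega <- 2 * pi / cfg$ctrl$cycle_period
  dt <- 0.002
  n <- ceiling(2 * cfg$ctrl$cycle_period / dt)
  a <- numeric(9)
  ph <- phi - omega * dt * (n:1)
  for (i in seq_len(n)) {
    u <- pmin(synergy_command(ph[i], cfg), 1)
    a <- a + dt * (u - a) / cfg$muscles$T_act
  }
  a
}
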