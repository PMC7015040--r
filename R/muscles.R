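#' Activation dynamics rate
#'
#' First-order low-pass filtering of the motor command:
#' `da/dt = (u - a) / T_act`.  Commands are clamped to `[0, 1]` before
#' filtering so activations stay physiological.
#'
#' @param u motor command (clamped to `[0, 1]`)
#' @param a current activation
#' @param T_act time constant (s)
#' @return `da/dt`
#' @export
activation_rate <- function(u, a, T_act = default_config()$muscles$T_act) {
  u <- pmin(pmax(u, 0), 1)
  (u - a) / T_act
}

#' Muscle lengths and lengthening velocities
#'
#' Constant-moment-arm geometry: `length = lopt - sum_j r_j * angle_j`,
#' with signed arms, so each muscle is at its optimal (rest) length in the
#' reference upright posture.  Biarticular muscles (RF, BFL, GC) sum over
#' both of their joints.  Lengthening velocity is positive.
#'
#' @inheritParams forward_kinematics
#' @return 18 x 2 matrix (`length`, `velocity`), right leg muscles first
#' @export
muscle_length_velocity <- function(q, qd = rep(0, 9),
                                   cfg = default_config()) {
  out <- pg_muscle_geometry(as.numeric(q), as.numeric(qd), cpp_params(cfg))
  rownames(out) <- c(paste0(muscle_names(), "_r"),
                     paste0(muscle_names(), "_l"))
  out
}

#' Hill-type muscle force
#'
#' `F = a * Fmax * fL(l) * fV(v) + Fpe(l)`, with a Gaussian force-length
#' curve peaking at the optimal length, a Hill force-velocity curve that is
#' 1 at zero velocity, 0 at the maximal shortening velocity and saturates
#' at an eccentric plateau for lengthening, and a linear passive element
#' engaged above the rest length.  The total force is tension-only (never
#' negative).
#'
#' @param act 18 activations in `[0, 1]`
#' @param geom 18 x 2 matrix from [muscle_length_velocity()]
#' @param cfg configuration list
#' @return 18 tensile forces (N)
#' @export
muscle_force <- function(act, geom, cfg = default_config()) {
  pg_muscle_forces(as.numeric(act), as.numeric(geom[, 1]),
                   as.numeric(geom[, 2]), cpp_params(cfg))
}

#' Joint torques from muscle forces
#'
#' `tau_j = sum_m r_{m,j} F_m` with the signed constant moment arms, in the
#' flexion-positive joint convention.
#'
#' @param forces 18 tensile forces from [muscle_force()]
#' @param cfg configuration list
#' @return named vector of 6 joint torques
#' @export
joint_torques_from_muscles <- function(forces, cfg = default_config()) {
  pg_muscle_torques(as.numeric(forces), cpp_params(cfg))
}
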