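wrap_phase <- function(phi) {
  out <- phi %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

#' Rectangular synergy pulse
#'
#' Indicator of the i-th pulse interval, `1` when
#' `Phi_i < phi <= Phi_i + dPhi_i` evaluated modulo `2*pi` (intervals may
#' wrap past `2*pi`); the left boundary is strict.
#'
#' @param phi oscillator phase (rad, any real; wrapped internally)
#' @param i pulse index in 1..5
#' @param cfg configuration list
#' @return 0 or 1 (vectorized over `phi`)
#' @export
synergy_pulse <- function(phi, i, cfg = default_config()) {
  if (!(i %in% 1:5)) stop("pulse index must be in 1..5")
  d <- wrap_phase(phi - cfg$ctrl$Phi[i])
  as.numeric(d > 0 & d <= cfg$ctrl$dPhi[i])
}

#' Muscle-synergy motor command
#'
#' Weighted sum of the five rectangular pulses:
#' `u_syn_m = sum_i w_{m,i} Lambda_i p_i(phi)`.  Only muscles with nonzero
#' weights can ever be driven by the synergy pathway.
#'
#' @param phi oscillator phase (rad)
#' @param cfg configuration list
#' @return named length-9 command vector
#' @export
synergy_command <- function(phi, cfg = default_config()) {
  p <- vapply(1:5, function(i) synergy_pulse(phi, i, cfg), numeric(1))
  u <- as.numeric(cfg$ctrl$weights %*% (cfg$ctrl$Lambda * p))
  stats::setNames(u, muscle_names())
}

#' Continuous part of the oscillator phase dynamics
#'
#' `dphi/dt = omega - K_phi * sin(dphi_leg - pi)` where `dphi_leg` is this
#' leg's phase minus the other leg's.  The coupling keeps the two legs in
#' antiphase; around the antiphase state the phase difference relaxes with
#' eigenvalue `-2 K_phi`.
#'
#' @param phi named or ordered phases `c(right, left)`
#' @param leg `"right"` or `"left"`
#' @param cfg configuration list
#' @return `dphi/dt` (rad/s) for that leg
#' @export
phase_rate <- function(phi, leg = c("right", "left"),
                       cfg = default_config()) {
  leg <- match.arg(leg)
  d <- if (leg == "right") phi[1] - phi[2] else phi[2] - phi[1]
  2 * pi / cfg$ctrl$cycle_period - cfg$ctrl$K_phi * sin(d - pi)
}

#' Apply a foot-contact phase reset
#'
#' The Dirac term of the phase dynamics integrates to a jump: at the due
#' time (`t_contact + tau_fc`) the leg's phase is reassigned to `phi_fc`
#' exactly.  With resetting disabled (the ablated model) the event is
#' discarded and the phase is unchanged.
#'
#' @param state CPG state list with fields `phi` (length 2) and `due`
#'   (length 2, absolute due times, `NA` when none pending)
#' @param leg `"right"` or `"left"`
#' @param t_now current time; must be at or past the due time
#' @param cfg configuration list
#' @param resetting whether the resetting pathway is enabled
#' @return updated state list
#' @export
apply_phase_reset <- function(state, leg = c("right", "left"), t_now,
                              cfg = default_config(), resetting = TRUE) {
  leg <- match.arg(leg)
  i <- if (leg == "right") 1L else 2L
  if (is.na(state$due[i]))
    stop("no registered foot-contact event pending for this leg")
  if (t_now < state$due[i])
    stop("reset applied before its due time")
  if (resetting) state$phi[i] <- cfg$ctrl$phi_fc
  state$due[i] <- NA_real_
  state
}

#' Trunk posture regulation signal
#'
#' PD feedback on trunk pitch, emitted only for the hip muscles (IL, GM) of
#' a leg in stance: `p_m = -kappa_m (theta - theta_ref) - sigma_m thetad`.
#'
#' @param theta,thetad trunk pitch (rad) and pitch rate (rad/s)
#' @param stance logical `c(right, left)`
#' @param cfg configuration list
#' @return 18-vector (right leg muscles then left)
#' @export
trunk_regulation <- function(theta, thetad, stance, cfg = default_config()) {
  ct <- cfg$ctrl
  p <- stats::setNames(numeric(9), muscle_names())
  p["IL"] <- -ct$kappa_IL * (theta - ct$theta_ref) - ct$sigma_IL * thetad
  p["GM"] <- -ct$kappa_GM * (theta - ct$theta_ref) - ct$sigma_GM * thetad
  out <- c(p * as.numeric(stance[1]), p * as.numeric(stance[2]))
  names(out) <- c(paste0(muscle_names(), "_r"), paste0(muscle_names(), "_l"))
  out
}

#' Forward-speed regulation signal
#'
#' Proportional feedback on trunk forward speed, emitted only for the
#' ankle muscles (TA, SO) of a leg in stance:
#' `p_m = -lambda_m (v - v_ref)`.  With the printed gains a speed below
#' target increases the soleus push-off and suppresses the tibialis.
#'
#' @param v trunk forward speed (m/s, lab frame)
#' @param stance logical `c(right, left)`
#' @param cfg configuration list
#' @return 18-vector (right leg muscles then left)
#' @export
speed_regulation <- function(v, stance, cfg = default_config()) {
  ct <- cfg$ctrl
  p <- stats::setNames(numeric(9), muscle_names())
  p["TA"] <- -ct$lambda_TA * (v - ct$v_ref)
  p["SO"] <- -ct$lambda_SO * (v - ct$v_ref)
  out <- c(p * as.numeric(stance[1]), p * as.numeric(stance[2]))
  names(out) <- c(paste0(muscle_names(), "_r"), paste0(muscle_names(), "_l"))
  out
}

#' Delayed regulation command
#'
#' `u_reg(t) = p(t - tau_reg)`, looked up from a sampled history of the
#' summed trunk and speed signals by linear interpolation.  Before the
#' history covers the delay (start-up) the command is zero.
#'
#' @param times sample times of the history (increasing)
#' @param p history matrix, one row per sample
#' @param t_now lookup time
#' @param tau_reg delay (s)
#' @return the delayed row (zeros during warm-up)
#' @export
regulation_command <- function(times, p, t_now,
                               tau_reg = default_config()$ctrl$tau_reg) {
  p <- as.matrix(p)
  tq <- t_now - tau_reg
  if (length(times) == 0 || tq < times[1]) return(numeric(ncol(p)) * 0)
  if (tq >= times[length(times)]) return(p[length(times), ])
  i <- findInterval(tq, times)
  w <- (tq - times[i]) / (times[i + 1] - times[i])
  (1 - w) * p[i, ] + w * p[i + 1, ]
}

#' Total motor command
#'
#' `u_m = u_syn_m + u_reg_m`, clamped to `[0, 1]` before the activation
#' filter.
#'
#' @param u_syn,u_reg synergy and regulation commands (same length)
#' @param clamp clamp the sum to `[0, 1]` (the physiological default)
#' @export
total_command <- function(u_syn, u_reg, clamp = TRUE) {
  u <- u_syn + u_reg
  if (clamp) u <- pmin(pmax(u, 0), 1)
  u
}
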