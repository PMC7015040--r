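#' Run the closed-loop walking simulation
#'
#' Integrates body, muscles and controller jointly with fixed-step RK4,
#' splitting steps exactly at phase-reset due times and belt perturbation
#' edges.  Foot-contact events (per-leg OR over the four sole points, with
#' a small release hysteresis) are located by linear interpolation of the
#' crossing point's height; each first contact of a step schedules a phase
#' reset at `t_contact + tau_fc`.  The run stops early on a fall (hip below
#' `fall_frac` of standing height) or if the state diverges.
#'
#' @param cfg configuration list
#' @param duration simulated time (s)
#' @param state resume state from a previous run or [initial_state()];
#'   `NULL` starts from the default bootstrap posture
#' @param resetting enable foot-contact phase resetting (`FALSE` is the
#'   ablated "without phase resetting" model); `NULL` uses the config flag
#' @param belt belt schedule: list with `nu` (baseline speed, m/s) and
#'   optionally `pert_on`, `pert_sign`, `pert_mag`, `pert_dur` describing a
#'   belt-speed impulse; `NULL` uses the config baseline with no
#'   perturbation.  For bootstrap experiments the schedule also accepts
#'   `ramp_dur` (linear belt ramp-up) and `assist_until`/`assist_hold`
#'   (fading or rigid trunk-support scaffolds, always off by default and
#'   never used on the limit cycle)
#' @param store_traj keep the sampled trajectory (disable for long
#'   bootstraps to save memory)
#' @return list with `status` (`"ok"`, `"fall"`, `"diverged"`), `t_end`,
#'   `fall_time`, `state` (resume state), `events` (per-leg contact/off and
#'   reset times) and `traj` (matrix sampled every `sim$log_dt`)
#' @export
run_walking <- function(cfg = default_config(), duration = 10, state = NULL,
                        resetting = NULL, belt = NULL, store_traj = TRUE) {
  validate_config(cfg)
  if (is.null(state)) state <- initial_state(cfg = cfg)
  if (is.null(belt)) belt <- list(nu = cfg$belt$nu)
  if (is.null(belt$nu)) belt$nu <- cfg$belt$nu
  res <- pg_run(cpp_params(cfg, resetting), state, duration, cfg$sim$dt,
                belt, cfg$sim$log_dt, store_traj)
  res$belt <- belt
  res
}

#' Gait events and cycle bookkeeping
#'
#' Derives cycle boundaries (right-foot contacts, the Poincare section),
#' per-cycle periods, a steady-state flag, and double-stance intervals
#' from the raw event times of a run.
#'
#' @param run result of [run_walking()]
#' @param steady_tol relative period tolerance for the steady-state flag
#' @param steady_cycles number of trailing cycles that must agree
#' @return list with `cycles` (right contacts), `periods`, `steady`,
#'   `double_stance` (matrix of start/end times), and the raw events
#' @export
gait_events <- function(run, steady_tol = 0.005, steady_cycles = 10) {
  ev <- run$events
  rc <- ev$contact_r
  periods <- diff(rc)
  steady <- FALSE
  if (length(periods) >= steady_cycles) {
    last <- utils::tail(periods, steady_cycles)
    steady <- (max(last) - min(last)) / stats::median(last) < steady_tol
  }
  # double stance after a right contact: until the next left foot-off
  ds <- NULL
  for (t0 in rc) {
    t1 <- ev$off_l[ev$off_l > t0]
    nl <- ev$contact_l[ev$contact_l > t0]
    if (length(t1)) {
      t1 <- min(t1)
      if (!length(nl) || t1 < min(nl)) ds <- rbind(ds, c(t0, t1))
    }
  }
  list(cycles = rc, periods = periods, steady = steady,
       double_stance = ds, contact_l = ev$contact_l, off_r = ev$off_r,
       off_l = ev$off_l, reset_r = ev$reset_r, reset_l = ev$reset_l)
}

#' Mean belt-relative forward speed over trailing cycles
#'
#' The trunk's forward speed relative to the moving belt surface
#' (`v_lab + nu`), averaged over the last `n_cycles` gait cycles.  For
#' steady treadmill walking this matches the commanded belt speed up to
#' the small lab-frame drift the speed regulation permits.
#'
#' @param run result of [run_walking()]
#' @param n_cycles trailing cycles to average over
#' @return speed in m/s
#' @export
belt_relative_speed <- function(run, n_cycles = 10) {
  ge <- gait_events(run)
  rc <- ge$cycles
  if (length(rc) < n_cycles + 1)
    stop("not enough gait cycles recorded (", length(rc), ")")
  t0 <- rc[length(rc) - n_cycles]
  t1 <- rc[length(rc)]
  tr <- run$traj
  i <- tr[, "t"] >= t0 & tr[, "t"] <= t1
  # average lab-frame speed from displacement, plus the mean belt speed
  x <- tr[i, "x"]; tt <- tr[i, "t"]
  drift <- (x[length(x)] - x[1]) / (tt[length(tt)] - tt[1])
  drift + mean(tr[i, "belt_speed"])
}

#' Bootstrap the walking limit cycle
#'
#' Starts from the default double-stance posture, discards a transient of
#' `cfg$sim$warmup` seconds, and returns the resume state together with an
#' unperturbed reference continuation: mean cycle period `tau` over the
#' reference cycles and the reference Poincare (right-foot-contact) times.
#'
#' @param cfg configuration list
#' @param resetting ablation flag passed to [run_walking()]
#' @param ref_cycles number of reference cycles for the period average
#' @return list with `state` (on the limit cycle), `tau`, `ref` (reference
#'   run), `events`, `steady`
#' @export
bootstrap_limit_cycle <- function(cfg = default_config(), resetting = NULL,
                                  ref_cycles = 20) {
  # discard the start-up transient: integrate past the first committed
  # right-foot contact, then snapshot the resumable state
  warm <- run_walking(cfg, duration = cfg$sim$warmup, resetting = resetting,
                      store_traj = FALSE)
  if (!length(warm$events$contact_r))
    stop("bootstrap failed: no right-foot contact before ",
         signif(warm$t_end, 4), " s (", warm$status, ")")
  dur <- (ref_cycles + 3) * cfg$ctrl$cycle_period
  ref <- run_walking(cfg, duration = dur, state = warm$state,
                     resetting = resetting)
  ge <- gait_events(ref)
  rc <- ge$cycles
  if (length(rc) < 2)
    stop("bootstrap failed: fewer than two reference cycles (",
         ref$status, " at ", signif(ref$t_end, 4), " s)")
  periods <- diff(rc)
  tau <- mean(utils::tail(periods, min(ref_cycles, length(periods))))
  # double-stance intervals as % of the cycle after a right contact
  ds <- NULL
  if (!is.null(ge$double_stance)) {
    w <- (ge$double_stance[, 2] - ge$double_stance[, 1]) / tau * 100
    st <- vapply(ge$double_stance[, 1], function(t0) {
      prev <- rc[rc <= t0]
      if (!length(prev)) NA_real_ else (t0 - max(prev)) / tau * 100
    }, numeric(1))
    ds <- cbind(start = st, end = st + w)
    ds <- ds[is.finite(ds[, 1]) & ds[, 1] < 100, , drop = FALSE]
  }
  list(state = warm$state, tau = tau, ref = ref, events = ge,
       ref_contacts = rc, steady = ge$steady, n_cycles = length(periods),
       double_stance_pct = ds)
}

#' Belt schedule for a perturbation at a given gait phase
#'
#' Converts a trial phase `s` (fraction of the gait cycle, 0 = right foot
#' contact) into a belt schedule whose impulse onset is
#' `t_anchor + s * tau`, where `t_anchor` is a right-foot-contact time of
#' the unperturbed reference.
#'
#' @param s phase in `[0, 1)` as fraction of the cycle
#' @param direction `"accel"` or `"decel"`
#' @param t_anchor reference right-contact time (absolute simulation time)
#' @param tau limit-cycle period (s)
#' @param nu baseline belt speed (m/s)
#' @param mag,dur impulse magnitude (m/s) and duration (s)
#' @return belt schedule list for [run_walking()]
#' @export
apply_perturbation <- function(s, direction = c("accel", "decel"), t_anchor,
                               tau, nu = 1.3, mag = 0.1, dur = 0.001) {
  direction <- match.arg(direction)
  stopifnot(s >= 0, s < 1, dur > 0, nu > 0)
  list(nu = nu, pert_on = t_anchor + s * tau,
       pert_sign = if (direction == "accel") 1 else -1,
       pert_mag = mag, pert_dur = dur)
}
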