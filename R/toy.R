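#' Toy phase oscillator with a prescribed phase response curve
#'
#' A pure phase oscillator `psi' = 2*pi/tau` whose response to an impulse
#' of strength `mu` at phase `psi` is obtained by integrating
#' `d psi / d h = Z(psi)` over `h in [0, mu]` — the exact finite-strength
#' response implied by the prescribed infinitesimal PRC.  Poincare
#' crossings (`psi = 0 mod 2*pi`) are computed in closed form, so the
#' handle validates the impulse-method pipeline against a known answer,
#' including the finite-`mu` bias when `mu` is large.
#'
#' @param tau period (s)
#' @param Zfun prescribed PRC, a function of phase in radians
#' @param mu_mag impulse strength magnitude (rad of phase advance per unit
#'   Z)
#' @return model handle for [run_prc_experiment()] with elements `tau`,
#'   `trial`, `Z_analytic`
#' @export
toy_phase_oscillator <- function(tau = 1.0, Zfun = function(psi) sin(psi),
                                 mu_mag = 1e-3) {
  stopifnot(tau > 0, mu_mag > 0)
  trial <- function(s_frac, direction = "accel", n_max = 50) {
    mu <- if (direction == "accel") mu_mag else -mu_mag
    s <- s_frac * tau
    psi_s <- 2 * pi * s / tau
    # exact finite-impulse response: integrate dpsi/dh = Z(psi) over mu
    nstep <- 200
    h <- mu / nstep
    psi <- psi_s
    for (i in seq_len(nstep)) { # RK4 in the impulse variable
      k1 <- Zfun(psi)
      k2 <- Zfun(psi + h * k1 / 2)
      k3 <- Zfun(psi + h * k2 / 2)
      k4 <- Zfun(psi + h * k3)
      psi <- psi + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    # crossings psi = 2*pi*k after s, measured from t0 = 0 (last crossing
    # at or before s, since psi(0) = 0); a backward kick at the section
    # must not re-count the crossing that defines t0
    k1st <- max(floor(psi / (2 * pi)), floor(psi_s / (2 * pi))) + 1
    ks <- seq(k1st, k1st + n_max - 1)
    crossings <- s + (2 * pi * ks - psi) * tau / (2 * pi)
    list(crossings = crossings, mu = mu)
  }
  list(kind = "phase", tau = tau, trial = trial, Z_analytic = Zfun)
}

#' Toy planar limit-cycle oscillator with analytic PRC
#'
#' A radial-twist clock: `r' = gamma r (1 - r)`, `theta' = omega +
#' beta (1 - r)`, with limit cycle `r = 1`.  Its asymptotic phase is
#' `psi = theta - (beta/gamma) log r`, so a horizontal kick of size `k`
#' applied on the cycle has the analytic PRC
#' `Z(theta) = -sin(theta) - (beta/gamma) cos(theta)` per unit kick.
#' Because `beta != 0` twists the isochrons away from the radial Poincare
#' section (`theta = 0`), the finite-`n` impulse readout shows the
#' isochron-mismatch transient that motivates the large-`n` convention —
#' making this the estimator-floor reference.  Trajectories and crossing
#' times are evaluated from the closed-form solution.
#'
#' @param tau period (s)
#' @param gamma radial contraction rate (1/s)
#' @param beta isochron twist (1/s)
#' @param kick horizontal displacement magnitude per impulse
#' @return model handle with `tau`, `trial`, `Z_analytic`
#' @export
toy_planar_oscillator <- function(tau = 1.0, gamma = 3.0, beta = 1.0,
                                  kick = 1e-3) {
  stopifnot(tau > 0, gamma > 0, kick > 0)
  omega <- 2 * pi / tau
  theta_of_t <- function(t, r0, th0) {
    th0 + omega * t - (beta / gamma) * log(r0 + (1 - r0) * exp(-gamma * t))
  }
  trial <- function(s_frac, direction = "accel", n_max = 50) {
    k <- if (direction == "accel") kick else -kick
    s <- s_frac * tau
    th_s <- omega * s
    x <- cos(th_s) + k
    y <- sin(th_s)
    r0 <- sqrt(x^2 + y^2)
    th0 <- atan2(y, x)
    # unwrap the kicked angle to stay near th_s
    th0 <- th0 + 2 * pi * round((th_s - th0) / (2 * pi))
    crossings <- numeric(n_max)
    for (j in seq_len(n_max)) {
      target <- 2 * pi * (floor(th0 / (2 * pi)) + j)
      f <- function(t) theta_of_t(t, r0, th0) - target
      lo <- (target - th0) / (omega + abs(beta)) * 0.5
      hi <- (target - th0) / omega + (abs(beta) / gamma) / omega + 1
      crossings[j] <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root + s
    }
    list(crossings = crossings, mu = k)
  }
  Z_analytic <- function(theta) -sin(theta) - (beta / gamma) * cos(theta)
  list(kind = "planar", tau = tau, trial = trial, Z_analytic = Z_analytic)
}

#' PRC model handle for the neuromusculoskeletal walker
#'
#' Bootstraps the walking model, caches the post-transient state and the
#' unperturbed reference (Poincare section = committed right-foot
#' contact), and exposes the `trial` interface used by
#' [run_prc_experiment()]: each trial resumes from the cached state,
#' schedules a belt-speed impulse at the requested gait phase (fraction of
#' the cycle after a reference right-foot contact), and returns the
#' post-perturbation crossing times.
#'
#' @param cfg configuration list
#' @param resetting ablation flag (`FALSE` = without phase resetting)
#' @param dnu,dt impulse magnitude (m/s) and duration (s)
#' @param anchor_cycle which reference right contact anchors the phase
#'   (cycles after the cached state)
#' @return model handle with `tau`, `trial`, `reference`, `steady`,
#'   `double_stance_pct`
#' @export
gait_prc_model <- function(cfg = default_config(), resetting = NULL,
                           dnu = 0.1, dt = 0.001, anchor_cycle = 2) {
  boot <- bootstrap_limit_cycle(cfg, resetting = resetting)
  tau <- boot$tau
  rc <- boot$ref_contacts
  if (length(rc) < anchor_cycle + 1)
    stop("bootstrap produced too few reference cycles for PRC trials")
  anchor <- rc[anchor_cycle]
  ds <- boot$double_stance_pct
  trial <- function(s_frac, direction = "accel", n_max = 50) {
    belt <- apply_perturbation(s_frac, direction, t_anchor = anchor,
                               tau = tau, nu = cfg$belt$nu, mag = dnu,
                               dur = dt)
    dur <- (belt$pert_on - boot$state$t) + (n_max + 1.5) * tau
    r <- run_walking(cfg, duration = dur, state = boot$state,
                     resetting = resetting, belt = belt, store_traj = FALSE)
    cr <- r$events$contact_r
    t0 <- cr[cr <= belt$pert_on]
    if (!length(t0)) return(NULL)
    t0 <- max(t0)
    post <- cr[cr > belt$pert_on] - t0
    mu <- compute_mu(direction, dnu = dnu, dt = dt, nu = cfg$belt$nu,
                     tau = tau)
    list(crossings = post, mu = mu, status = r$status)
  }
  list(kind = "gait", tau = tau, trial = trial, reference = boot,
       steady = boot$steady, double_stance_pct = ds)
}
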