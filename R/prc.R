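#' Normalized perturbation strength of a belt-speed impulse
#'
#' A belt-speed step of magnitude `dnu` lasting `dt` applied to a gait
#' with belt speed `nu` and cycle period `tau` corresponds to the
#' impulsive phase-perturbation strength
#' `mu = 2*pi * (sign * dnu * dt) / (nu * tau)` (rad); accelerations are
#' positive, decelerations negative.
#'
#' @param direction `"accel"` or `"decel"`
#' @param dnu impulse magnitude (m/s)
#' @param dt impulse duration (s)
#' @param nu baseline belt speed (m/s)
#' @param tau limit-cycle period (s)
#' @return signed `mu` in radians
#' @export
compute_mu <- function(direction = c("accel", "decel"), dnu = 0.1,
                       dt = 0.001, nu = 1.3, tau = 1.0) {
  direction <- match.arg(direction)
  stopifnot(dnu > 0, dt > 0, nu > 0, tau > 0)
  s <- if (direction == "accel") 1 else -1
  2 * pi * (s * dnu * dt) / (nu * tau)
}

#' Asymptotic phase shift from Poincare-section event times
#'
#' The impulse-method readout: with `t = 0` at the last section crossing
#' before the perturbation and `t_n` the time of the n-th crossing after
#' it, `Z = (2*pi / mu) * (n*tau - t_n) / tau`.  For large `n` the
#' mismatch between the Poincare section and the isochrons has decayed and
#' `Z` estimates the phase response at the perturbation phase.
#'
#' @param t_n time of the n-th post-perturbation crossing, measured from
#'   the last pre-perturbation crossing (s)
#' @param n crossing index used
#' @param tau unperturbed period (s)
#' @param mu signed perturbation strength (rad), nonzero
#' @return the phase response value `Z`
#' @export
phase_shift_from_events <- function(t_n, n, tau, mu) {
  stopifnot(n >= 1, tau > 0, mu != 0, is.finite(t_n))
  (2 * pi / mu) * (n * tau - t_n) / tau
}

#' Run an impulse-method PRC experiment on a model handle
#'
#' A model handle (see [toy_phase_oscillator()], [toy_planar_oscillator()],
#' [gait_prc_model()]) exposes `tau` and a
#' `trial(s_frac, direction, n_max)` function returning the
#' post-perturbation Poincare crossing times (relative to the last
#' crossing before the perturbation) together with the `mu` realized.  For
#' every requested phase and direction one trial is run and the phase
#' shift is read out at crossing `n`; a second readout at `n - 10` (or
#' `ceiling(n/2)` when `n <= 10`) provides the convergence diagnostic.
#'
#' @param model model handle list with elements `tau` and `trial`
#' @param phases perturbation phases as fractions of the cycle in `[0,1)`;
#'   default 100 equally spaced trials
#' @param n Poincare crossing index for the readout (default 50)
#' @param directions subset of `c("accel", "decel")`
#' @return data.frame with columns `phase_pct`, `direction`, `Z`,
#'   `Z_early`, `n`, `converged`, `ok`; failed trials (too few crossings,
#'   e.g. a fall) carry `ok = FALSE` and are reported with a warning
#' @export
run_prc_experiment <- function(model, phases = (0:99) / 100, n = 50,
                               directions = c("accel", "decel")) {
  stopifnot(is.list(model), is.function(model$trial), n >= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  n_early <- if (n > 10) n - 10 else ceiling(n / 2)
  out <- NULL
  n_fail <- 0
  for (dir in directions) {
    for (s in phases) {
      tr <- model$trial(s, dir, n)
      ok <- !is.null(tr) && length(tr$crossings) >= n
      if (ok) {
        Z <- phase_shift_from_events(tr$crossings[n], n, model$tau, tr$mu)
        Ze <- phase_shift_from_events(tr$crossings[n_early], n_early,
                                      model$tau, tr$mu)
        conv <- abs(Z - Ze) < 0.05 * max(1, abs(Z))
      } else {
        Z <- Ze <- NA_real_
        conv <- FALSE
        n_fail <- n_fail + 1
      }
      out <- rbind(out, data.frame(
        phase_pct = 100 * s, direction = dir, Z = Z, Z_early = Ze,
        n = n, converged = conv, ok = ok))
    }
  }
  if (n_fail > 0)
    warning(n_fail, " trial(s) did not yield ", n,
            " Poincare crossings (fall or early termination); excluded")
  out[order(out$direction, out$phase_pct), ]
}

#' Shape features of an estimated phase response curve
#'
#' Zero crossings are located by sign-change linear interpolation on the
#' phase-sorted curve; positive peaks and negative troughs are the extrema
#' between consecutive crossings.  When double-stance intervals (in % of
#' the gait cycle) are supplied, each feature is annotated with whether it
#' falls inside one.
#'
#' @param est data.frame from [run_prc_experiment()] (one direction), or
#'   any data.frame with `phase_pct` and `Z`
#' @param double_stance optional 2-column matrix of double-stance interval
#'   start/end in % gait cycle
#' @return list with `crossings` (% phases), `peaks` and `troughs`
#'   (data.frames with `phase_pct`, `Z`, `in_double_stance`), and the
#'   global `max`/`min` rows
#' @export
extract_features <- function(est, double_stance = NULL) {
  est <- est[is.finite(est$Z), ]
  est <- est[order(est$phase_pct), ]
  x <- est$phase_pct; z <- est$Z
  if (length(z) < 3) stop("too few PRC points for feature extraction")
  in_ds <- function(p) {
    if (is.null(double_stance) || !nrow(double_stance)) return(NA)
    any(p >= double_stance[, 1] & p <= double_stance[, 2])
  }
  crossings <- c()
  for (i in seq_len(length(z) - 1)) {
    if (z[i] == 0 && ((i == 1 && z[i + 1] != 0) ||
                      (i > 1 && z[i - 1] * z[i + 1] < 0)))
      crossings <- c(crossings, x[i])   # exact zero between opposite signs
    else if (z[i] * z[i + 1] < 0)
      crossings <- c(crossings,
                     x[i] + (x[i + 1] - x[i]) * abs(z[i]) / (abs(z[i]) + abs(z[i + 1])))
  }
  segs <- findInterval(x, crossings)
  peaks <- troughs <- NULL
  for (sg in unique(segs)) {
    idx <- which(segs == sg)
    zz <- z[idx]
    if (all(zz >= 0) && max(zz) > 0) {
      i <- idx[which.max(zz)]
      peaks <- rbind(peaks, data.frame(phase_pct = x[i], Z = z[i],
                                       in_double_stance = in_ds(x[i])))
    } else if (all(zz <= 0) && min(zz) < 0) {
      i <- idx[which.min(zz)]
      troughs <- rbind(troughs, data.frame(phase_pct = x[i], Z = z[i],
                                           in_double_stance = in_ds(x[i])))
    }
  }
  imax <- which.max(z); imin <- which.min(z)
  list(crossings = crossings, peaks = peaks, troughs = troughs,
       max = data.frame(phase_pct = x[imax], Z = z[imax],
                        in_double_stance = in_ds(x[imax])),
       min = data.frame(phase_pct = x[imin], Z = z[imin],
                        in_double_stance = in_ds(x[imin])))
}

#' Empirical estimator floor from the planar toy oscillator
#'
#' The impulse-method readout at finite `n` retains a residual from the
#' mismatch between the Poincare section and the isochrons, decaying with
#' the oscillator's transverse contraction rate.  This measures the
#' maximal absolute estimation error on the analytic planar limit-cycle
#' clock at matched `mu` and `n`; it is the yardstick for calling an
#' estimated PRC "zero".
#'
#' @param mu perturbation strength to match (rad)
#' @param n readout crossing index to match
#' @param tau oscillator period (s)
#' @param gamma transverse contraction rate (1/s); the default `1.5/tau`
#'   is of the order of the gait model's cycle-to-cycle settling
#' @param beta isochron twist parameter (1/s)
#' @param phases probe phases (fractions)
#' @return maximal absolute error `max |Z_est - Z_analytic|`
#' @export
estimator_floor <- function(mu, n, tau = 1.0, gamma = 1.5 / tau,
                            beta = 0.5 * gamma, phases = (0:19) / 20) {
  m <- toy_planar_oscillator(tau = tau, gamma = gamma, beta = beta,
                             kick = abs(mu))
  est <- run_prc_experiment(m, phases = phases, n = n, directions = "accel")
  zan <- vapply(2 * pi * phases, m$Z_analytic, numeric(1))
  max(abs(est$Z[order(est$phase_pct)] - zan[order(100 * phases)]))
}
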