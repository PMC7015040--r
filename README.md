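# prcgait

Forward-dynamic simulation of human treadmill walking with a
muscle-synergy central pattern generator (CPG), and phase-response-curve
(PRC) estimation by the impulse method.

## What it is for

How does the nervous system keep the walking rhythm stable when the
ground perturbs it?  One candidate mechanism is *phase resetting*: at
every foot contact the spinal rhythm generator's phase is reassigned to
a fixed value, locking the motor pattern to the mechanics.  This
package implements a sagittal-plane neuromusculoskeletal model — a
7-link, 9-DOF skeleton, nine Hill-type muscles per leg, motor commands
built from five phase-locked rectangular pulses, delayed posture and
speed regulation, and two coupled phase oscillators with optional
foot-contact resetting — walking on a treadmill whose belt speed can be
perturbed impulsively.  The response of the gait is read out as a PRC:
for a limit-cycle oscillator with period τ perturbed by an impulse
μ·δ(t−s), the asymptotic shift of the Poincaré-section (right
foot contact) event times gives

    Z(ψ(s)) = (2π/μ) · (nτ − t_n)/τ ,   μ = 2π(±Δν·Δt)/(ν·τ)

so the with-resetting and without-resetting models can be compared at
the level at which human treadmill experiments are analysed.  Toy
limit-cycle oscillators with known analytic PRCs validate the estimator
independently of the walking model.

Intended users: researchers in computational motor control and
neuromechanics who want a self-contained, deterministic testbed for
rhythm-regulation hypotheses and for PRC methodology.

## Worked example

```r
library(prcgait)

# validate the PRC estimator on an oscillator with a known answer
m   <- toy_phase_oscillator(tau = 1, Zfun = sin, mu_mag = 1e-3)
est <- run_prc_experiment(m, phases = (0:19)/20, n = 50, directions = "accel")
max(abs(est$Z - sin(2 * pi * est$phase_pct / 100)))
#> [1] 0.0002378057

# simulate the walker on the 1.3 m/s belt
cfg <- gait_preset("nominal")
run <- run_walking(cfg, duration = 10)
run$status
#> [1] "fall"
gait_events(run)$periods
#> [1] 0.92452 1.07493 0.93177
belt_relative_speed(run, n_cycles = 3)
#> [1] 0.673714
```

The first number is the estimator's maximal error against the exact
sinusoidal PRC — a fraction of a percent.  The walker takes four
alternating, load-bearing strides with cycle periods near the CPG's
1 s and then falls: with the published controller constants on this
package's canonical 60 kg / 1.70 m anthropometry the pattern
under-propels the body relative to the belt, so the measured
belt-relative speed (0.67 m/s over the trailing cycles) sits well below
the commanded 1.3 m/s and steady walking is not reached.  The
`prcgait-methods` vignette documents the model, the estimator, and this
limitation in detail.  Ablating the resetting pathway
(`run_walking(..., resetting = FALSE)`) shortens survival from ≈3.2 s
to ≈0.7 s under identical conditions — the stabilizing role of phase
resetting in miniature.

A command-line front end (`inst/cli/prcgait.R`) exposes `simulate`,
`perturb` and `prc` subcommands over the same functions.

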