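---
title: "Evolutionary game dynamics of county medical community construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary game dynamics of county medical community construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcgame)
```

## The model

A county medical community (CMC) is an alliance of a county-level lead
hospital, township health centers, and village clinics under unified
management, built largely through the integration of their information
systems. `cmcgame` models the strategic interaction driving that
construction as an evolutionary game among boundedly rational
organisations:

* the **lead hospital** (LH) chooses between *efficient* and *inefficient*
  construction of the community, with population share `x` playing
  efficient;
* the **primary healthcare institutions** (PHI) choose between *active*
  and *passive* participation, with share `y` active;
* optionally, the **government departments** (GD) choose between
  *adequate* and *prudent* support, with share `z` adequate.

The cost–benefit structure is captured by the parameters of
`cmc_params()`. Magnitudes (all in the same abstract payoff unit, strictly
positive): the lead hospital's information-integration cost `I` and the
medical resources `U` it delivers downward; the service capacities `Sl`
and `Sp`; the information and management authority `Tp` the primary
institutions cede; their performance allocation `R` and the attendance
loss `D` they suffer when the community fails to retain patients; for the
tripartite game, the authority `Tg` ceded by government, the construction
funds `F`, and the political gains `A`. Dimensionless coefficients in
`[0, 1]`: the policy effect `v` (amplifies `R`, dampens `D`), the
information-construction integration coefficient `pi` (amplifies `Sl`,
`Sp`, `Tp`), the resource-absorption ratio `eps` of passive institutions,
the information-integration intensity `xi` (scales `I + U` and the ceded
authorities), and the government support intensity `phi` (scales `F` and
the political gains under prudent support).

The default parameterisation, `cmc_baseline()`, is `I = 26`, `U = 5`,
`Sl = 14`, `Tp = 12`, `R = 3`, `Sp = 2`, `D = 25`, and all coefficients
`0.5`, with `Tg = 6`, `F = 6`, `A = 10`, `phi = 0.5` added for the
tripartite game. These are the study conditions for every preset scenario;
they are stylised magnitudes for theoretical analysis, not an empirical
calibration (none exists for this system).

## Replicator dynamics and the two drift variants

Each role's share evolves by replicator dynamics: with `f` the payoff
advantage of the role's aggressive strategy over its passive one
(a function of the co-players' shares),

    dp/dt = p (1 - p) f(state).

`cmc_drift()` exposes two variants of the drift factors:

* `mode = "printed"` evaluates the closed-form factor expressions the
  simulation analysis is defined over, exactly as typeset there. For the
  two-subject game,
  `f_x = (xi-1)(I+U) + y pi (1-xi) Tp + pi Sl + xi Tp` and
  `f_y = pi Sp + (1+v) R + (xi-1) Tp + (1-eps) xi U + (1-eps)(1-xi) U x +
  (1-x) v D`; the tripartite `f_x` gains `z pi (1-xi) Tg + xi Tg +
  (1-xi) phi F`, `f_y` replaces `(1-x) v D` by `(1-z) v D`, and
  `f_z = A (phi - v + phi v)(xy - x - y) + (xi-1) Tg - (1-phi) F + A`.
  Flattened typeset expressions of this kind are ambiguous; the parse
  adopted here is the one that makes the two-subject `f_y` agree exactly
  with the payoff-matrix derivation, and it is pinned by tests.
* `mode = "derived"` recomputes each factor as `e1 - e2` from the payoff
  cells (`cmc_payoff()`, `cmc_expected_payoffs()`), i.e. the textbook
  replicator construction.

The two variants do **not** coincide. Their difference is closed-form and
state-independent where nonzero per component:
`xi Tp (1 - pi)` in the two-subject `f_x`, zero in `f_y` (both games), and
`(xi - 1) Tg (1 - x)(1 - y)` in the tripartite `f_z`.
`cmc_drift_discrepancy()` (and the CLI's `compare-drifts`) surface this
audit. The default is `mode = "printed"` because that is the system the
reference simulations integrate, and the reported threshold behaviour of
`xi` (see below) is only consistent with it: the printed `f_x` at full
participation is `37 xi - 18`, whose root is `xi* = 18/37 ≈ 0.486`,
inside the reported bracket `(0.3, 0.5)`, while the payoff-derived factor
`31 xi - 18` would place the flip at `18/31 ≈ 0.58`. The derived mode is
retained as an audit tool, not as the default dynamic.

A second degree of freedom is the `form`: the canonical replicator drift
`p (1 - p) f` (default, `form = "replicator"`) versus the literal linear
recursion `p f` that the discretised system writes (`form = "linear"`).
With state clamping the two share vertex attractors and drift-factor
signs; the replicator form is the declared dynamic, the linear form is
kept for fidelity to the discretised notation.

The tripartite payoff cells are read term-by-term from the roles'
expectation expressions rather than from the tabulated matrix, because the
two sources disagree in two cells (the government's
(inefficient, passive, prudent) payoff, and whether the passive
institutions' attendance-loss reduction follows the lead hospital's or the
government's strategy) and only the expectation expressions feed the
replicator construction. The asymmetric `Tg`/`F` terms inside the
efficient lead hospital's prudent-support cells are implemented exactly as
given, not "repaired": a repair would be a guess.

## Stochastic extension

Information transformation is uncertain, so the deterministic system is
perturbed with multiplicative Gaussian white noise, giving per role the
Itô SDE

    dp = drift(p) dt + sigma p dW.

`cmc_simulate()` discretises this with the fixed-step forward Euler
(Euler–Maruyama) scheme,

    p[n+1] = p[n] + drift(p[n]) h + sigma p[n] dw[n],   dw[n] ~ N(0, h),

clamping every component to `[0, 1]` after each step. Clamping (rather
than reflection or rejection) is the simplest contract that preserves
probability semantics; together with the multiplicative noise it makes
the boundary `p = 0` absorbing. No higher-order scheme is offered: the
model is defined over the forward Euler expansion, and the questions asked
of it (which vertex attracts) are insensitive to weak-order refinements.

Defaults, chosen once and used by all presets: `sigma = 0.05` (small
relative to drift factors of order 1–10, so the qualitative transitions
survive the noise), `h = 0.01` and `steps = 10000` (horizon `T = 100`,
resolving the slowest relevant drift timescale, of order 2 time units,
with hundreds of steps), initial state `(0.5, 0.5[, 0.5])` (maximal
uncertainty, symmetric across strategies; no canonical start exists).
Each role gets its own independent Brownian stream by default —
disturbances to distinct organisations are distinct — with
`noise = "shared"` available for the single-stream reading. Replicate `r`
of an ensemble is seeded `base_seed + r`, so any replicate can be
reproduced as a single run and the whole ensemble from one integer.

With `sigma = 0` the stochastic path equals the deterministic integrator
(`cmc_integrate()`) bit for bit; that equivalence, seed determinism, the
`N(0, h)` increment moments, and state validity under large noise are all
enforced by tests.

## Equilibria and convergence classification

`cmc_vertex_stability()` classifies each pure-strategy vertex by the signs
of the drift factors there: stable when every role's factor pushes its
share back toward the vertex value, unstable when every role is pushed
away, saddle otherwise, and degenerate (unclassified) when any factor is
exactly zero — a measure-zero tie that should be surfaced, not broken
arbitrarily. No Jacobian eigen-analysis or interior-equilibrium machinery
is provided: the model family is analysed by simulation, and vertex
sign bookkeeping is exactly what that requires.

Sweep trajectories are classified by `cmc_run_sweep()` as converged to a
vertex when the mean state over the final 10% of the horizon lies within
0.05 of it componentwise. The window *mean* matters: under multiplicative
noise the state is kicked off a vertex by about `sigma * sqrt(h)` per
step even after the system has settled, so a sustained raw-deviation band
would spuriously flag settled noisy runs as non-converged, while for
`sigma = 0` the mean and raw readings agree. The reported convergence
time is the first raw entry into the tolerance ball after the
window-mean condition holds for good, and the fluctuation measure is the
largest raw deviation after that time.

## Preset sweep scenarios

`cmc_scenario()` encodes seven sweeps, each holding everything else at the
baseline: `Tp` over `{5, 10, 15, 20, 25}`; `pi`, `xi`, `v`, `phi` over
`{0.1, 0.3, 0.5, 0.7, 0.9}`; `U` over `{1, 3, 5, 7, 9}` (a symmetric
bracket of the baseline `U = 5`; this grid is a package choice); and the
composite `Tp + Tg` over `{5, 10, 15, 20, 25}`, split 2:1 between `Tp`
and `Tg` — the only split consistent with the baseline ratio `12:6`, and
configurable via `split`.

Two deterministic results anchor the suite and the acceptance script:

* sweeping `xi` (printed factors, replicator form, `sigma = 0`, from
  `(0.5, 0.5)`, `h = 0.01`, horizon 100), the lead hospital's terminal
  strategy flips from inefficient (`x < 0.1` at `xi <= 0.3`) to efficient
  (`x > 0.9` at `xi >= 0.5`), bracketing the analytic root `18/37`;
* the tripartite baseline converges to the all-aggressive profile
  `(1, 1, 1)` — in particular the government settles on adequate support.

One known tension is recorded rather than reconciled: the narrative
describing the `Tp` (and `Tp + Tg`) sweeps reports inefficient
construction at the upper-middle grid values, but every drift variant
implemented here has `f_x > 0` there, so no implemented dynamic produces
that outcome; it would require unreported run settings (noise intensity,
initial state). The sweep presets reproduce what the equations, as
parsed and tested here, actually imply.

```{r xi-sweep}
sc <- cmc_scenario("fig4", sigma = 0)
cmc_threshold_scan(sc, role = "LH", target = "reaches_one")$terminals
```

## Numerical and testing choices

Tolerances: payoff/drift identities are checked to `1e-12` (pure floating
point algebra); the bisection recovery of `xi* = 18/37` to `1e-9`; Euler
step-halving stability of terminals to `1e-3`; an adaptive-solver
cross-check (deSolve, when available) to `1e-3`. Monte Carlo checks use
`1e5` increment draws and ensembles of 30–50 replicates at 4,000–20,000
steps; property loops use 50–200 random parameter draws on 4–7 point
state grids. These sizes keep the default suite under a couple of minutes
on one CPU while leaving the Monte Carlo bounds far from their
thresholds.

Degenerate inputs are handled explicitly: states outside `[0, 1]` and
non-positive magnitudes are rejected by validation; a non-finite state
during integration aborts with the step index; exactly-zero vertex
factors flag the vertex degenerate.

## What the simulations do and do not show

Everything here is forward simulation of a stylised model at assumed
magnitudes. Passing tests show internal consistency — payoffs, drifts,
discretisation, and classification agree with their independent oracles
and closed forms — and robustness of the qualitative transitions to small
noise. They do not show that real CMC construction follows replicator
dynamics, that the baseline magnitudes describe any actual county, or
that the thresholds transfer beyond the model: no empirical data enters
at any point. The package deliberately stops short of welfare analysis,
empirical calibration, and stability-in-probability proofs.
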