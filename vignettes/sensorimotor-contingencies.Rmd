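---
title: "Operational sensorimotor-contingency analysis of a minimal categorical-perception agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational sensorimotor-contingency analysis of a minimal categorical-perception agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcagent)
```

## The model

`smcagent` implements a minimal model of active categorical perception in
the Beer tradition of minimal cognition: a point agent on a circular
one-dimensional track (circumference $L = 40$ world units) that must
*approach* narrow bell-shaped gradients and *avoid* wide ones.  The two
shape classes differ only in steepness and horizontal extent — peak
heights are varied across trials — so no instantaneous sensor reading can
solve the task and an active strategy is required.

The environment is a static sensor field built from Gaussian bumps.  An
object with center $c$, height $h \in (0, 1]$ and width $w > 0$
contributes $h\,e^{-d(p,c)^2/(2w^2)}$ at body position $p$, with $d$ the
signed minimal wrapped distance; contributions sum and the sensor clips
at 1 ("normalized proximity").  The agent senses the field height at its
own position; what actually drives its controller is the *time
derivative* $\Delta s = v\,\partial s/\partial p$.

The controller is a two-neuron continuous-time recurrent neural network
(CTRNN): an interneuron with a self-connection, driven by $\Delta s$, and
a motor neuron it feeds,

$$\tau_1 \dot y_1 = -y_1 + w_{11}\,\sigma(y_1+\theta_1) + g_s\,\Delta s,
\qquad
\tau_2 \dot y_2 = -y_2 + w_{21}\,\sigma(y_1+\theta_1),$$

with $\sigma$ the logistic function, and the motor mapping
$v = v_{max}\,(2\sigma(y_2+\theta_2) - 1)$, symmetric so both movement
directions are reachable.  There is no sensor-to-motor shortcut and no
motor self-loop; the wiring is exactly sensor → interneuron (with
self-loop) → motor.  The closed loop is integrated with forward Euler at
`dt = 0.01` for `T = 100` time units per trial; the canonical trial has a
single shape at mid-circle and the agent starting 8 units away with
zeroed neurons.

### Parameters that matter

| parameter | meaning | units | default / range |
|---|---|---|---|
| $L$ | track circumference | world units | 40 |
| $w$ | shape width | world units | narrow 1, wide 3 |
| $h$ | shape height | sensor units | drawn from $[0.5, 1]$ per trial |
| $w_{11}$ | interneuron self-weight | — | evolved in $[-16, 16]$ |
| $w_{21}$ | interneuron→motor weight | — | evolved in $[-16, 16]$ |
| $\theta_1, \theta_2$ | biases | — | evolved in $[-16, 16]$ |
| $\tau_1, \tau_2$ | time constants | time units | evolved in $[0.1, 10]$ |
| $g_s$ | sensor gain | — | evolved in $[-50, 50]$ |
| $v_{max}$ | speed scale | world units / time unit | fixed at 1 |

$v_{max}$ is excluded from the genome because it is degenerate with a
joint rescaling of the time constants.  The box bounds are the
conventional CTRNN evolution ranges.  Track length, shape widths and the
height range are the package's own study conditions: $L = 40$ keeps a
wide shape ($6w = 18$ units of meaningful support) well clear of its own
wrap-around tail, and $w = 1$ vs $w = 3$ makes the categories
distinguishable only through sensorimotor dynamics once heights vary.

## The four analyses

**Sensorimotor environment** (`smc_surface()`).  Cutting the loop at the
motor command and treating velocity as a free variable gives the open-loop
law $S(p, v) = v\,\partial s/\partial p$: the sensory change that would
result from commanding velocity $v$ at position $p$.  It depends only on
world and sensor, never on the controller.  For a single shape it has
exactly two peaks and two troughs — at the points of greatest slope,
$p = c \pm w$, on the velocity boundary — and obeys the two-fold symmetry
$S(c+\delta, v) = S(c-\delta, -v)$, one fold contributed by the bell
shape's mirror symmetry and one by the agent's symmetric motor
capability.  `surface_extrema()` uses strict 8-neighbour comparison with
boundary cells included and the zero plateau excluded, so the flat
background never produces spurious extrema.

**Sensorimotor habitat** (`sample_habitat()`, `solve_fixed_points()`,
`bifurcation_diagram()`, `attractor_landscape()`).  The habitat is the
set of trajectories the *closed* loop actually produces over ranges of
initial and environmental conditions.  Because the coupled system resists
closed-form treatment, the quasi-static method clamps the sensory drive
$I = g_s \Delta s$ as a parameter and computes the internal system's
limit sets.  The clamped interneuron equation has fixed points at the
roots of $F(y_1) = -y_1 + w_{11}\sigma(y_1+\theta_1) + I$; since
$\sigma' \le 1/4$, self-weights $w_{11} \le 4$ guarantee a single root
for every input, while $w_{11} > 4$ yields a saddle-node fold pair and a
bistable input band.  The landscape maps each $(p, v)$ cell to the signs
of the stable steady-state velocities at that cell's clamped drive.  For
an evolved solver of the reference class the four smooth extrema of the
SM environment become four discrete monostable regions of attraction
separated by bistable (history-dependent) territory.

**Sensorimotor coordination** (`rates_portrait()`,
`detect_limit_cycle()`, `classify_coordination()`).  A pattern counts as
an SM coordination when it is *reliable* (present in at least
`r_min = 0.9` of a trial battery) and *functional* (the trials showing it
succeed at the task).  The approach pattern is a limit cycle of the
*coupled* agent-environment system, detected by recurrence in the plane
of sensorimotor rates $(\mathrm{d}m/\mathrm{d}t, \mathrm{d}s/\mathrm{d}t)$;
the avoidance pattern is a reliable *transient* — contact without any
velocity reversal — which qualifies on the same definition.  Crucially,
the clamped internal system has fixed points only; the oscillation exists
only in closure with the environment, which is why the quasi-static
analysis alone cannot predict it.

**Sensorimotor strategy.**  The combined JSON report (`smc_report()`)
carries an `sm_strategy` slot that is deliberately empty: a strategy
analysis requires a normative comparison among several viable
coordination repertoires, and this one-shape-one-action task does not
offer enough behavioral degrees of freedom to support it.  The slot
documents the scope boundary rather than an unfinished feature.

## Evolution and the reference agent

`evolve_agents()` runs a generational real-valued GA over the 7-gene
genome (rank-proportional selection, elitism of one, uniform crossover at
rate 0.5, per-gene Gaussian mutation with $\sigma = 0.05$ reflected into
$[0,1]$).  Each genome is scored on a fixed battery of narrow and wide
trials (heights drawn once per run from $[0.5, 1]$, start offsets cycled
through $\{\pm 6, \pm 8, \pm 10\}$): narrow trials score
$1 - \min(1, d_{final}/d_{start})$, wide trials
$\min(1, d_{final}/(L/2 - d_{start}))$.  Holding the battery fixed within
a run makes fitness deterministic per genome, so elitism guarantees a
non-decreasing best-so-far trace and every run is exactly reproducible
from its seed.

The shipped reference agent (`reference_agent()`) is the product of such
runs, *selected* — not tuned — among independently evolved solvers for
matching the qualitative solution class the analyses target: oscillatory
approach that settles near narrow peaks (45 velocity reversals per
canonical trial, a detected limit cycle with an offset-invariant
period), reversal-free transient avoidance of wide shapes, a four-region
attractor landscape, no stable attractor near zero velocity, and a
single categorical boundary along the width axis.  With no zero-velocity
attractor, the only way to stay near a peak is to oscillate between
opposite-sign attractors — exactly what the coordination analysis
displays.

One quantitative limitation of the evolved solutions deserves honesty.
On a circular track an avoider keeps moving forever, so where it sits at
the fixed trial end depends on its escape speed: an agent whose escape
attractor is slow (roughly $|v^*|$ in $0.06$–$0.18$ under these
conditions) ends far from the wide peak for *every* start offset, while
fast escapers lap the track and land at arbitrary phase.  The task's
fitness function cannot distinguish these regimes — its wide-trial score
saturates before the avoidance-label threshold ($4w$) is reached from
the farthest start — so evolution reliably produces either fast-both
solvers (oscillatory, correct in kind, but landing mid-track on some
held-out wide trials) or slow "parking" solvers that develop a
zero-velocity attractor and stop oscillating altogether.  Across ~50
independent runs no solver combined the oscillatory class with uniformly
label-correct held-out avoidance; the shipped agent is of the
oscillatory class, and its held-out label success (about 0.75, driven
entirely by wide trials approached from one side) is reported as-is by
the acceptance suite rather than patched over.

## Numerical choices

- **Integrator.** Forward Euler at `dt = 0.01` is the field's standard
  for CTRNN agents; over the whole evolution box the dynamics are
  contractive enough that states stay bounded over 100 time units (tested
  over 1,000 random parameter draws).  A half-step run changes the final
  position of a reference approach trial by under 0.05 world units.
- **Sensor derivative.** $\Delta s$ is computed analytically as
  $v\,\partial s/\partial p$ (exact for a static field).  A
  finite-difference mode `(s_t - s_{t-dt})/dt` exists as a cross-check.
  When *validating* the analytic coupling against differencing of the
  stored series, the like-for-like comparison for an Euler path is the
  midpoint rule (`trajectory_ds_fd(scheme = "midpoint")`): the change in
  `s` across a step against `v_k * grad(p_k + dt v_k/2)`, which agrees to
  second order; sample-centred differences carry a first-order bias from
  the piecewise-linear body path and are provided for completeness.
- **Root finding.** Clamped fixed points come from a dense sign-change
  scan (step $10^{-3}$ over $[-|I|-20, |I|+20]$, a bound that follows
  from $|y_1^*| \le |I| + |w_{11}|$) refined by bisection to $10^{-12}$;
  stability is the sign of $F'$, with near-tangent roots
  ($|F'| < 10^{-8}$) conservatively flagged non-stable.  The landscape
  uses an equivalent branch-inversion method (interpolating the monotone
  branches of $y_1 - w_{11}\sigma(y_1+\theta_1)$) because solving
  cell-by-cell would be wasteful; consistency with the scanning solver is
  tested on random cells.
- **Extrema and regions.** Strict inequalities on the 8-neighbourhood for
  surface extrema (so plateaus yield nothing); 4-connectivity for
  landscape region counting; classes are stable under grid refinement
  except within one cell of a class boundary.
- **Cycle detection.** Recurrence into a tolerance ball (5% of the
  post-transient maximal radius) around a reference point, counting only
  entries with a consistent crossing direction; detection requires at
  least 3 returns, inter-return times within 10% of their median, and no
  outward drift.  The transient cut is the later of 30% of the trial and
  first contact ($s > 0.05$).  The reference is the farthest-from-origin
  point of the *third quarter* of the post-transient orbit: the scanning
  oscillation settles with decreasing amplitude, so a reference taken on
  the early, still-shrinking part of the orbit would sit strictly outside
  the settled cycle and its recurrence ball would never be revisited —
  anchoring on the settled part is what lets the test see exactly the
  settled pattern the behavioral claim is about, and capping the search
  at 75% leaves at least a quarter of the orbit for returns to be
  observed in, while the strict regularity and no-drift conditions still
  reject decaying transients.
- **Degenerate inputs.** Empty worlds are legal everywhere (flat surface,
  no extrema, uniform landscape); a state started exactly on a basin
  boundary is flagged rather than silently assigned; worlds whose objects
  overlap (pairwise wrapped separation below $6 \max w$) warn that
  single-shape analyses do not apply.

## Symmetry grids

Floating-point grids built by naive `seq()` calls are not exactly
mirror-symmetric, which would turn an exact symmetry into a $10^{-15}$
residual.  `symmetric_grid()` constructs grids from a single offset
vector and its negation, so mirror pairs are exact bitwise negations and
the surface symmetry residual of an isolated shape is exactly 0.

## What the generator does and does not emulate

Synthetic worlds reproduce the study conditions: single Gaussian shapes
(or a narrow/wide pair for demonstrations), heights in $[0.5, 1]$,
canonical start offsets, no within-trial environmental dynamics, no
noise.  Passing tests therefore demonstrate correctness of the *analyses*
on this model class — they do not speak to sensor noise, non-Gaussian
stimuli, moving objects, or multi-sensor embodiment, all of which are out
of scope.  Problem sizes used in the tests (default surface grids of
601 × 201 cells, landscape grids of 121 × 101, batteries of 10–40 trials,
evolution demo runs of population 10) are chosen to exercise every code
path at interactive speed; the full evolution default (population 60, 300
generations) is what produced the shipped reference agent.

## Known limitations

- The quasi-static account assumes the clamped internal system has only
  fixed points, true for this one-dimensional interneuron but not for
  larger controllers; `bifurcation_diagram()` would need continuation of
  periodic branches for those.
- Outcome labels depend on thresholds (approach within $2w$, avoidance
  beyond $4w$, final 20% of the trial) that are operational choices; the
  underlying task only fixes the qualitative labels.
- On a circular track, trial duration, circumference and escape speed
  interact (see above); avoidance labels for agents far outside the
  reference class should be interpreted with that in mind.
- The GA is a plain generational recipe meant to produce solvers, not a
  study of evolutionary dynamics.
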