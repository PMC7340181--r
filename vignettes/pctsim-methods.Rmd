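---
title: "Models and methods behind pctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pctsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctsim)
```

`pctsim` simulates perceptual control theory (PCT) models: negative
feedback loops that act on the world so that a perceived quantity tracks
an internal reference value. This vignette records the model equations,
the default parameters and why they were chosen, the numerical decisions,
and what the bundled synthetic scenarios do and do not establish.

## The control unit

Each unit is updated once per iteration with the discrete dynamics

$$p_t = K_i\,Q_{i,t-1-d}, \qquad e_t = r - p_t, \qquad
Q_{o,t} = Q_{o,t-1} + \tfrac{1}{S}\bigl(K_o e_t - Q_{o,t-1}\bigr),$$

after which the environment closes the loop,
$Q_{i,t} = K_f Q_{o,t} + D_t$. The output function is an amplifier
($K_o$) inside a leaky integrator with time constant $S$ iterations. Two
conventions exist for where the gain sits relative to the integrator;
they share the same fixed point and differ only in transient shape, and
the gain-inside form above is used throughout. The iteration length
`dt` (default 0.016 s, a 16 ms refresh typical of real-time simulation)
is bookkeeping only: all dynamics are expressed per iteration, and `dt`
merely labels the time axis.

**Steady state and stability.** For constant $r$ and $D$ the loop has
the fixed point

$$e^\* = \frac{r - K_i D}{1 + K_i K_f K_o},$$

implemented as `analytic_steady_state()` and used as the oracle for the
simulator. The scalar recursion contracts exactly when
$\lvert 1 - (1 + G)/S\rvert < 1$ with loop gain $G = K_i K_f K_o$, i.e.
when $S > (1 + G)/2$; transport delay tightens this further. "Stable
parameter set" in the tests means positive loop gain plus this slowing
condition with margin. Any signal exceeding $10^9$ in magnitude aborts
the run with an instability error naming the step and unit, so genuine
divergence is distinguished from legitimate oscillation.

**Delay.** A unit's single `transport_delay` is applied wholly on the
perceptual path (the unit perceives $Q_i$ as it was $d$ iterations ago).
A pure delay contributes the same loop lag wherever it is placed along
the loop, so one placement keeps the contract simple and testable. Delay
buffers start at zero.

## Hierarchies

Units are grouped into levels. All units update synchronously from
previous-step values (double buffering, mimicking parallel neural
processing), so for every non-top unit
$r_i(t) = \sum_j w_{j\to i}\,Q_{o,j}(t-1)$ holds exactly, where the sum
runs over the superiors one level up. Reference combination is additive
- connection strengths weight each superior's contribution - rather than
averaged, matching the idea of relative connection strengths. Perceptual
ascent mirrors this: a level-$l$ unit perceives a weighted sum of
level-$l{-}1$ perceptions (defaulting to their mean), and level-1 units
perceive their own environmental quantity.

The three-level conflict architecture has one low-level unit closed
through the environment, two mid-level units that share the low-level
perception and jointly set its reference, and one top-level unit whose
two output weights set the mid-level references. With mid-level
references $r_A \ne r_B$ the shared perception settles near the
gain-weighted compromise
$(g_A r_A + g_B r_B)/(1 + g_A + g_B)$, leaving both mid units in chronic
error: the conflict signature.

**Default unit parameters** (chosen once so that an isolated low-level
loop controls well and higher levels are progressively slower, the
standard recipe for stable cascade control): low level $K_o = 20$,
$S = 25$; mid level $K_o = 2$, $S = 50$; top level $K_o = 2$, $S = 100$;
all $K_i = K_f = 1$, top reference 5.

**Random agents.** `build_three_level_conflict()` draws the four
connection strengths uniformly from `weight_range` with a dead zone of
0.1 around zero so no agent starts with a vacuous connection. The
default range is $[0.5, 5]$, positive strengths only: disagreement in
the *magnitudes* of positive weights already produces genuine,
stable conflict (the two mid references disagree whenever the top-level
weights differ), whereas negative weights place the affected loop in
positive feedback, which diverges rather than conflicts. Negative
weights remain available - and are exercised in the tests - for
demonstrating sustained error from opposed connections; agents that
diverge under any condition are flagged and excluded from medians.

## Reorganization

Reorganization perturbs designated parameters (connection strengths, or
optionally mid-level gains) while control is poor. Error is accumulated
as the sum of squared errors across all units over a window of
`window` iterations (default 200, about two settling times of the
slowest unit, so each decision sees a roughly equilibrated system); one
decision is taken per window:

* error increased: draw a fresh uniformly random unit direction over the
  target parameters and set the step size to
  `step_coefficient * increase`, capped at `max_step` (tumble);
* error decreased or unchanged: keep the previous direction and step
  size (run);
* error at or below `error_tolerance`: leave parameters untouched.

The tumble-on-worsening / run-on-improving pair is the classic
bacterial-chemotaxis search scheme. The cap (`max_step`, default 0.3)
exists because the very first window's error increase is measured
against an empty history and can be enormous; without the cap a single
spike flings the weights into unstable territory. Perturbed parameters
are also clipped to $\pm 100$, with clipping logged. Step-size defaults
(`step_coefficient = 0.005`, `max_step = 0.3`) were calibrated once, in
exploratory sweeps during design, to give reliable learning across
random agents without destabilizing them, then frozen.

**WMRSE.** Control quality is summarized by the window mean root squared
error: squared errors across all units are averaged over ten iteration
cycles and the square root is taken. The sliding (stride 1) variant is
the default for test granularity; a strided variant (stride = window) is
available since either granularity is defensible for plotting.

## The three bundled experiments

**Conflict resolution.** `run_conflict_reorg_experiment()` draws
`n_agents` random three-level agents and simulates each under three
conditions with the same architecture, disturbance and paired seeds: no
reorganization, reorganization of the mid-level (mid-to-low) weights,
and reorganization of the top-level (top-to-mid) weights. Only the top
level can actually dissolve the conflict - mid-level changes rebalance
which goal wins, but a single shared perception cannot satisfy two
different references, whereas the top level can make the two references
agree - so the expected ordering of final WMRSE medians is top < mid <
none. The demo default is 20 agents; statistical claims are made at 200
agents with one-sided paired sign tests, a size at which the ordering is
stable across seeds. Runs use 8000 iterations (40 reorganization
decisions), enough for top-level learning to approach its floor while
keeping a 600-run experiment around a minute of compute.

**Therapy cohort.** `simulate_therapy_cohort()` treats each case's
symptom score (0-40 scale, as for the ten-item CORE outcome measure) as
its error signal: the reference for symptoms is zero, severity carries
over between sessions, and between sessions a random change occurs with
probability `min(1, error/scale_max)` and magnitude drawn from a
zero-mean normal with SD `0.5 * error`. No single step is guaranteed to
help; improvement emerges because large errors both invite change and
produce large moves, while near-zero error is quiescent - an absorbing
region at the healthy end of the scale. This yields the negatively
decelerating cohort mean curve, and individual trajectories show abrupt
stable drops (sudden gains) and early responses. Baseline severities are
drawn from a synthetic truncated normal (mean 20, SD 7 on [0, 40]),
standing in for a primary-care severity distribution of moderate
average severity; the clinical source distribution is not published. An
optional `biased_step` variant adds a small downward drift for
sensitivity analyses. Detector defaults: a sudden gain is a
between-session drop of at least 6 points (a reliable-change-sized drop
on this scale) that does not rebound above half the drop within 2
sessions; an early response is a 6-point improvement from baseline by
session 3. Both criteria are deliberately explicit configuration, not
inferences.

**Approach-avoidance.** Two systems with integrating outputs hold
opposing references for one perceived distance (defensive distance
`r_safe`, approach distance `r_approach`). The distance settles at the
virtual reference $(g_s r_s + g_a r_a)/(g_s + g_a)$ - the compromise is
closer to the defensive distance when the defensive gain is higher. The
integration rate must satisfy `eta * (g_safe + g_approach) < 2` for the
discrete update to converge.

**Two-agent demo.** A one-dimensional rendering of gain-dependent
conflict between a goal-seeking agent A (position goal plus a
personal-space system with radius 6) and a pursuing agent B (preferred
following distance 6). Outputs are saturating velocities (`v_max = 20`)
and each agent reacts to the configuration 5 iterations in the past (a
reaction time). The references are compatible, so at low gains both
agents succeed; with only B's gain high, B's underdamped pursuit
repeatedly overshoots into A's personal space and displaces it from its
goal (blocked); with both gains high the delay-plus-saturation loop
produces a wide bounded limit cycle (oscillation). Classification uses
documented thresholds: goals met when both final errors are below 5% of
the goal separation; oscillation when the late-half variance of A's
position exceeds 10% of the squared separation; blocked otherwise.
These dynamics were fixed once at design time; the demo is qualitative
and deterministic given its seed.

## Tracking-model fitting

`generate_tracking_data()` simulates a known controller tracking either
a sinusoid (predictable) or smoothed uniform noise (a 20-iteration
moving average - less predictable), optionally adding Gaussian
observation noise, and records the ground truth. Two architectures are
provided: one-level position control (cursor position is the leaky,
amplified output of a proximity controller; defaults gain 4, slowing 8,
delay 2) and two-level velocity control (a proximity controller sets the
reference for a velocity controller whose output is integrated into
position).

`fit_unit()` minimizes cursor RMSE with Nelder-Mead over log-transformed
gain and slowing (slowing constrained above 1), with 8 deterministic
multistarts per value of the transport delay, which is searched over the
integer grid 0-4; the objective is simulation-defined and non-smooth in
the delay, hence the derivative-free, gridded strategy. Unstable
candidate parameters return a large finite penalty so the simplex
retreats. Both RMSE and the model-data correlation are reported, since
either is a defensible fit statistic for tracking models. Noiseless
round trips recover one-level parameters essentially exactly; under
observation noise, gain and slowing trade off along a shallow ridge, so
recovery accuracy is assessed in the median over seeds. The two-level
model's continuous parameters are not globally identifiable from a
single trajectory (gain products trade off), so two-level checks are
stated in terms of fit quality, not parameter recovery.

## What the synthetic scenarios do and do not show

The generators emulate the *structure* of the target phenomena -
conflicted hierarchies, error-tuned stochastic change, compromise
equilibria, gain-dependent conflict regimes - under clean, stationary
conditions with known ground truth. They do not emulate measurement
error in clinical scales, dropout, therapist effects, non-stationary
disturbances, or individual differences beyond the randomized connection
strengths and baselines. Passing tests therefore establish internal
validity (the algorithms do what their definitions say, and the
qualitative orderings hold under the stated conditions), not that any
particular clinical dataset is generated by these mechanisms.

## Numerical choices, reproducibility, degenerate inputs

* All exported stochastic functions take a seed and restore the caller's
  RNG state; scenario runners derive per-agent and per-condition
  child seeds from one base seed, so reruns are byte-identical.
* The exponential-versus-linear comparison of cohort mean curves
  profiles the decay rate over a log grid with the linear coefficients
  solved exactly, then refines the rate by golden-section search; an
  all-constant cohort is reported with both RMSEs zero and a degeneracy
  flag rather than an error.
* WMRSE is computed by direct windowed summation (via convolution
  filtering), which matches a naive double-loop evaluation to within
  $10^{-12}$ on moderate magnitudes.
* Ties in the two-agent direction function (`sign(x_A - x_B)` at exact
  coincidence) resolve to the positive direction; a small seeded
  positional jitter breaks persistent symmetry.
* Empty windows, out-of-range slowing, unknown configuration keys and
  malformed networks raise classed configuration errors naming the
  offending field; divergence raises a classed instability error naming
  the step.

## Known limitations

* The simulation is a fixed-step synchronous scheme; no continuous-time
  integration and no nonlinear input functions.
* Hierarchies beyond three levels are supported by the data model but
  ship without bundled scenarios.
* The conflict-experiment fast path is specialized to the four-unit
  architecture (an equivalence test pins it to the generic engine).
* Reorganization targets whole weight groups; per-parameter gating and
  annealing schedules are out of scope, as are associative or
  reinforcement-learning baselines.
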