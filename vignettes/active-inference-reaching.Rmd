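---
title: "Cued sequential reaching under active inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cued sequential reaching under active inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affsim)
```

# The problem

A simulated agent points at one of four targets whenever it lights up. The
cues follow a clockwise order for the first half of the run and then reverse.
An agent that has learned the clockwise contingency can anticipate the next
cue — its reaction times shorten — but pays for that anticipation when the
contingency changes, until it infers that the context has switched from
"sequential" to "random". `affsim` simulates this loop end to end: a hidden
world process produces proprioceptive, visual and salience input; a
hierarchical generative model is inverted on-line by generalized filtering;
and action closes the loop by fulfilling proprioceptive predictions through
a simulated reflex arc. Precision (inverse variance) parameters on the
prediction-error streams play the role of tonic dopamine: lowering them at
different sites reproduces set-switching failure, bradykinesia and
perseveration.

# Generalized filtering

Every time-varying quantity is represented in *generalized coordinates of
motion*: its value plus temporal derivatives up to an embedding order
(`shift_operator()` maps a generalized vector onto its motion). Conditional
expectations evolve as

$$\dot{\tilde\mu} = D\tilde\mu - \partial_{\tilde\mu} F,$$

where $F$ is the free energy: one half the precision-weighted sum of squared
prediction errors over all streams, plus constants under fixed precisions.
For a two-level model the errors are: sensory errors
$\tilde s - \tilde g^{(1)}(\tilde x^{(1)}, \tilde v^{(1)})$ per stream, the
cause error $\tilde v^{(1)} - \tilde g^{(2)}(\tilde x^{(2)}, \tilde v^{(2)})$
linking the levels, the top-level prior error, and state-motion errors
$D\tilde x^{(i)} - \tilde f^{(i)}$ per level. Each stream's generalized
precision is its base precision $e^{\lambda}$ extended across derivative
orders by the inverse correlation matrix implied by a Gaussian
autocorrelation of the assumed smoothness (`generalized_precision()`).

Generalized predictions truncate the chain rule at first order: block
$k \ge 1$ of $\tilde g$ is $J_x x_k + J_v v_k$, with the Jacobians evaluated
at order 0. The free-energy *gradient*, however, differentiates these errors
exactly — including the curvature of the order-0 Jacobians — so that the
analytic gradient agrees with finite differences of the implemented $F$ to
round-off (each model level supplies Jacobians and curvature contractions;
for the reaching model these are closed forms in the softmax, tangent and
exponential maps). The Gauss–Newton Hessian $J^\top \Pi J$ (curvature-times-
error terms dropped) supplies the integrator Jacobian and the marginal
variances reported as 90% credible intervals.

Action descends the same objective through the only path available to it,
the world:

$$\dot a = -\left(\partial_a \tilde s\right)^\top \xi_s,$$

with $\partial_a \tilde s$ obtained by differentiating the world process
(the standard assumption for this scheme). Only the order-1 blocks of the
proprioceptive and visual streams depend on action, which is the
mathematical form of a reflex arc: action cancels the mismatch between the
sensed and the predicted rate of change of the arm.

# The generative model of cued reaching

**Level 1.** Hidden states are the two arm joint angles and four affordance
states, one per target. Observations: proprioception is the arm state,
vision its elementwise tangent (intrinsic-to-extrinsic map), and salience is
predicted as `exp` of the affordances — salience is log-transformed in the
model so it can be positive or negative while remaining positive in
expectation. The prior flow draws the arm toward
`afforded_target()` — the softmax-weighted combination of target angles — and
runs the affordances through a winnerless competition (generalized
Lotka–Volterra flow, `wlc_flow()`): each state excites its cyclic successor
and suppresses the rest through the transition matrix
`A = excite * C - inhibit * (J - I)`. The speed of this itinerant cycle is
the first component of the level-1 hidden cause.

**Level 2.** Two hidden states encode the context (sequential vs. random);
their softmax is the predicted level-1 cause, so a confident "sequential"
context drives the affordance cycle at full speed while a "random" context
stalls it and leaves pointing purely cue-driven. The level-2 flow is the
same winnerless-competition family at one eighth the rate (the spec of the
slow set: leak eight times slower, drive and coupling eight times smaller).

**Set switching.** When the cue order reverses, the cue-driven motion of the
affordances conflicts with the clockwise prior flow. That conflict is a
state-motion prediction error whose precision-weighted projection onto the
speed cause drags the inferred speed down — a large downward deflection of
the level-1 cause expectation — and the ensuing cause error pushes the slow
context states toward "random". The package distinguishes the two readouts:
`speed_cause()` (fast, deflection-carrying) and `context_cause()` (the
softmax of the slow context states — the agent's settled belief, used by
`switch_latency()`).

# The world process

`world_flow()` implements the hidden dynamics: the arm velocity is
`tanh(action_gain * action) - arm / tau_arm` and the salience of each
location is a leaky integration of exogenous Gaussian bumps
(`cue_causes()`). Sensory samples add smooth (analytic) noise with log
precision 16 on both state motion and input, generated together with its
derivative by `sample_smooth_noise()` so the world can be handled in
generalized coordinates without numerical differentiation.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| embedding orders | 6 states / 2 causes | — | generalized-filtering convention; ≥4 orders needed to filter smooth noise |
| smoothness | 0.5 | bins | near-white fluctuations that remain analytic |
| log precisions | 4 (all streams) | nats | nominal "dopamine" level; world noise log precision 16 |
| cue interval / count | 12 bins / 10 cues | 64 ms bins | five clockwise then five reversed presentations over 128 bins |
| cue bump width / amplitude | 2 bins / 10 | — | see "calibration" below |
| bump peak lag | 3 bins | bins | illumination begins at onset instead of acausally before it |
| fast attractor | excite 1.2, inhibit 1.1, decay 8, drive 0.3 | — | sustained 4-cycle, free period ≈ 48 bins = 4 cue intervals, losers ≈ −5 |
| slow attractor | decay 64, drive 0.032, speed 0.061 | — | same family ≈ 8× slower; context equilibria ≈ ±2 so evidence can flip them |
| tau_reach | 2 | bins | prior reach completes well inside one cue interval |
| tau_arm / tau_sal | 4 / 2 | bins | arm decays to rest; salience pulses near-disjoint |
| action_gain | 0.3 | — | makes the motor plant the rate-limiting stage (see below) |
| capture radius | 0.25 | extrinsic | 1/8 of the inter-target distance |

All of these were calibrated once (the pass is reproduced by
`scripts/tune_attractor.R`) and then frozen; they are config-overridable
through `reaching_config()`, `cue_schedule()` and `world_params()` or a
YAML/JSON file via `load_run_config()`.

## Calibration choices worth explaining

**Cue brightness and width.** The agent predicts salience as
`exp(affordance)`. For the softmax readout to saturate on the cued target,
the log-salience of a lit cue must sit *above* the attractor's resting
range, and the losers well below it. Dim cues (amplitude near 1) put the
cued log-salience at about −0.4 — *below* the losers' equilibrium — and the
arm can then never leave the convex-hull interior far enough to reach a
target. The shipped amplitude (10, peak log-salience ≈ +2) matches the
attractor's winner level; width 2 bins gives the evidence a finite
accumulation time, which is what makes the switch take about two trials
rather than resolving within one.

**Causal bumps.** A Gaussian bump centred on its onset is half-on before the
cue "appears". The bump peak therefore lags the onset by 1.5 widths. Besides
causality, this gives the prior a short window after each onset in which it
alone drives the arm — which is exactly where perseverative initial
movements (toward the clockwise-anticipated target) become measurable.

**Reflex gain.** If the arm responded to action at unit gain, the motor
plant would never be rate-limiting: every reach would complete within a bin
or two no matter what the precisions are, and no lesion could produce
bradykinesia. With `action_gain = 0.3` the within-bin action loop (whose
rate is set by the precision-weighted sensitivity
$\partial_a\tilde s^\top \Pi\, \partial_a\tilde s$) becomes the bottleneck,
so depleting the precision of the arm's state-motion errors slows movements
— without touching set switching, which runs over the salience/affordance
pathway.

# Numerics

* **Integrator.** One local-linearization step per substep advances the
  *joint* system — world state, expectations and action — with the full
  cross-Jacobians of the active-inference loop. Integrating the world
  separately (a one-bin reflex delay) makes the action loop oscillate and
  diverge. Default 4 substeps per 64-ms bin; a proposed update larger than
  1.5 in any coordinate triggers recursive step halving (depth ≤ 8).
* **Matrix exponential.** The increment is $h\,\varphi_1(Jh)f$ with
  $\varphi_1(z) = (e^z - 1)/z$, evaluated through the eigendecomposition of
  $J$. Padé scaling-and-squaring loses all accuracy on the very stiff
  Jacobians that log-precision-4 streams produce (eigenvalues below
  $-10^4$/bin); the spectral form is exact for the linearized system at any
  stiffness. An A-stable trapezoidal rule is the fallback when the
  eigenvector basis is unusable.
* **Fixed-step cross-check.** `solver = "rk4"` integrates the same flow with
  classical Runge–Kutta. It agrees with local linearization on
  mild-precision models but is outside its stability region at the nominal
  precisions — which is why the exponential integrator is the default, and
  why the cross-check test uses a mild fixture.
* **Descent.** Free energy is *not* a Lyapunov function of the full update:
  the generalized-motion term $D\tilde\mu$ is rotational, and transient
  increases of order $10^{-3}$ occur even for linear models. The
  static-inference limit (`filtering_step(static = TRUE)`, which drops $D$)
  is a pure free-energy descent and is monotone to numerical precision;
  that is the setting in which the descent property is asserted.
* **Degenerate inputs.** Softmax is computed shift-invariantly; the
  derivative-order correlation matrix is inverted at unit smoothness and
  rescaled afterwards (the direct inverse is numerically singular for rough
  noise at high orders); ties in the context softmax (exactly 0.5/0.5 at
  initialisation) are left to noise and evidence to break.

# Design decisions on genuinely open points

* **A two-state winnerless competition cannot cycle.** For `n = 2` the
  transition matrix of this family is symmetric, the sum coordinate relaxes,
  and the difference coordinate follows a one-dimensional autonomous flow
  $\dot y = -\textrm{speed}\,(e - i)\,\sigma'(y)y - y/\tau + \dots$ — a
  gradient flow, which cannot oscillate. The context level therefore keeps
  its two states (they are a *switch*, entrained by evidence, with an
  eightfold-slower relaxation), and the "eight times slower" claim is
  checked by running the slow parameter set on the four-state member of the
  same family, where a free-running period exists.
* **Speed and period.** Speed scales only the transition matrix. In
  sustained cycles whose winner/loser equilibria scale with speed, the
  leak sets the clock and the period is almost speed-invariant — the shipped
  defaults are deliberately in that regime, with the period pinned near the
  cue interval. Period-halving under speed-doubling holds in
  coupling-dominated parameterizations (strong excitation, weak leak), and
  that is where the property is tested.
* **Context readout.** `switch_latency()` reads the softmax of the
  second-level *state* expectations. The level-1 cause expectation also
  crosses 0.5 after a reversal, but it does so within the first reversed
  trial at any precision — it carries the evidence, not the settled
  inference.
* **Site → stream mapping.** Lesion sites follow the anatomy used for
  illustration: superior colliculus = salience sensory stream, parietal =
  visual stream, motor cortex = arm state-motion errors, premotor =
  affordance state-motion errors, striatum/prefrontal = level-2 cause and
  state errors. The alternative reading of the motor-cortex site (the
  proprioceptive *sensory* stream) remains selectable via
  `lesion("proprio_sensory", ...)`.

# Behavioural metrics

Reaction time is the time from cue onset to the first bin with the extrinsic
pointing position within the capture radius (0.25 = 1/8 of the inter-target
distance) of the target; `NA` if the target is not reached before the next
onset. Accuracy is the salience-bump-weighted mean of inverse distance to
target (guard `delta = 0.01`). Switch latency counts complete cue
presentations after the first order-violating cue until the random-context
belief exceeds 0.5 for at least half a cue interval. Perseveration counts
post-reversal trials (after the first reversed cue, where persistence of the
old rule is first observable — four scorable trials in the default protocol)
whose initial movement direction, over the first three bins after onset, is
closer to the clockwise successor of the previous target than to the true
target.

# What the synthetic world does and does not emulate

The world process reproduces the structure of the benchmark simulations: a
first-order arm with saturating drive, leaky salience driven by scheduled
bumps, and smooth low-amplitude noise (log precision 16). It does not model
multi-joint kinematics, visual occlusion, target jitter, trial-to-trial
variability of real subjects, or learning of the sequence prior (precisions
and priors are fixed throughout). Passing tests therefore demonstrate the
internal consistency of the inference scheme and the qualitative lesion
phenomenology under these idealised conditions — not quantitative agreement
with human data.

# Problem sizes used by the test suite

The default experiment is 128 bins (10 cues); the lesion suite is three
sites at six depletion levels each, one run per cell, plus five seeds of the
nominal run. A single run takes a few seconds; the full suite and the
acceptance script each complete in a few minutes on one CPU.

# Known limitations

* The fixed-step solver is a cross-check only; at nominal precisions the
  stiff Jacobians demand the exponential integrator.
* Conditional covariances come from the local curvature at each bin, not
  from dynamic propagation; the 90% intervals are therefore instantaneous
  Laplace approximations.
* Precisions are fixed within a run (tonic neuromodulation); state-dependent
  (phasic) precision control and learning of the attractor priors are out
  of scope.
* The behavioural operating point (switch in about two trials) was
  calibrated once at the shipped constants; far outside them (much brighter
  or dimmer cues, different interval) the evidence flux changes and the
  latency with it.
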