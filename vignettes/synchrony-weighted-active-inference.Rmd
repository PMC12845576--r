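---
title: "Synchrony-weighted active inference for dyadic category agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchrony-weighted active inference for dyadic category agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadinfer)
```

## The problem

Two agents face a stream of objects and must each decide, trial by trial,
whether an object belongs to "their" category and touch it if so. Easy
objects are unambiguous; Hard objects are deliberately ambiguous, so the
only route to consistent joint behavior is to learn what the partner will
do and converge on a shared judgment. `dyadinfer` models this convergence
as active inference: an agent maintains beliefs about its partner's
touch/no-touch behavior, scores its own candidate actions by a free-energy
objective, and weights the pull toward agreement by how strongly the two
partners' gaze is synchronized — gaze synchrony being read as a marker of
joint attention, not as an outcome.

## The model

### Two belief layers

Actions are binary: `a = 1` touch, `a = 0` no touch. The belief about the
partner is conditioned on the agent's own action and held twice:

* **First layer (counting).** Two conjugate Beta–Bernoulli posteriors
  `P(A_p = 1 | A_s = a) ~ Beta(alpha_a1, beta_a1)`, one per self-action
  condition. Observing `(a_s, a_p)` increments exactly one pseudo-count of
  the conditional matching `a_s`: alpha if the partner touched, beta
  otherwise (`update_single_bayes()`). Predictions use the posterior mean
  `alpha / (alpha + beta)` (`point_estimate()`) — the conjugate choice,
  well defined already at the uniform prior, preferred here over the mode
  (undefined at `Beta(1,1)`) or a posterior draw (which would make the
  deterministic trace stochastic).
* **Second layer (recency).** An exponential moving average per condition,
  `q <- ema_alpha * a_p + (1 - ema_alpha) * q`, updated only when the
  trial's `a_s` matches the condition (`update_double_bayes()`). Where the
  counting layer weighs all history equally, the EMA tracks where the
  partner's behavior is *heading*.

Both layers start at maximal uncertainty: pseudo-counts `(1, 1)` and
`q = 0.5`. The EMA's starting value is a free choice; 0.5 is used because
it equals the uniform-prior mean, so at trial 1 the two layers agree
exactly and the free energy is zero.

Beliefs are conditioned on the self action only, not per object. With 24
trials and 24 stimuli, per-object conditionals would receive about one
observation each and never leave the prior; the action-conditioned model
is the one that can actually learn at this scale.

### Free energy and action selection

For each candidate action `a`, with `q(a)` the EMA prediction and `p(a)`
the counting-layer mean,

    G(a) = kappa * d / (1 + d)  +  lambda0 * gamma_t * (2 q(a) - 1),
    d    = KL( Bern(q(a)) || Bern(p(a)) ),

computed in nats with both probabilities clipped to
`[epsilon, 1 - epsilon]` before the logarithms (`bernoulli_kl()`). The
compression `d / (1 + d)` maps the divergence into `[0, 1)` so the two
terms stay commensurable. The second term couples the agent to its
partner: its magnitude grows with the expected decisiveness of the
partner's behavior and its weight `gamma_t` with the dyad's measured gaze
synchrony. The functional form is implemented exactly as written — the
term can be read either as a risk charged to expected disagreement or as
a pull toward expected agreement; the code takes no side, and with
`gamma_t = 0` the model reduces to the pure two-layer comparison.

Action selection is the deterministic argmin of `G` (`select_action()`),
with exact ties going to "no touch" by default (`tie_break` in
`model_config()`) — the conservative reading of a tie, and configurable.
The softmax `pi(a) = exp(-G(a)/tau) / sum exp(-G/tau)` is reported for
evaluation only, computed with the max-subtraction trick so extreme
energies cannot overflow.

### The session loop

`run_session()` walks a time-ordered trial log with a strict
predict-then-update discipline: the partner prediction (first-layer mean
conditioned on the trial's observed self action — the agent knows its own
action when anticipating the partner) and the model's own action choice
are emitted from beliefs accumulated over *earlier* trials only; then both
layers absorb the trial. Trials without gaze data get `gamma_t = 0`,
disabling the agreement term for that trial alone. A trial with no touch
by either agent enters the updates as `a_p = 0`: "did not touch" is
treated as an observed no-touch, since the log cannot distinguish it from
a missing observation.

```{r}
trials <- data.frame(a_s = c(1, 1, 0, 1), a_p = c(0, 1, 1, 1))
run_session(trials, sync = rep(0.5, 4), config = model_config(gamma0 = 0.5))
```

### Parameters

| parameter     | meaning                                   | default | notes |
|---------------|-------------------------------------------|---------|-------|
| `kappa`       | scale of the compressed KL term           | 0.1     | keeps the divergence term an order below the agreement term |
| `lambda0`     | base agreement/risk weight                | 1.0     | |
| `tau`         | softmax temperature                       | 1.0     | affects reported probabilities only; selection is argmin |
| `ema_alpha`   | EMA weight on the newest observation      | 0.8     | strongly recency-weighted second layer |
| `gamma0`      | base synchrony weight, in [0, 1]          | 0.5     | studied grid: 0, 0.1, 0.5, 0.9 |
| `epsilon`     | probability clipping                      | 1e-12   | numerical guard only |
| `prior_alpha`, `prior_beta` | Beta prior pseudo-counts    | 1, 1    | uniform prior |
| `q_init`      | EMA starting probability                  | 0.5     | matches the prior mean |

The four model constants (`kappa`, `lambda0`, `tau`, `ema_alpha`) are
fixed, not fitted; only `gamma0` is swept over its grid.

## Gaze synchrony

The synchrony pipeline (`session_synchrony()`) turns paired raw
pupil-position streams into the per-trial weight `gamma_t`:

1. **Clean and align** (`clean_and_align()`): samples with missing
   coordinates are dropped, then both streams are linearly interpolated
   onto a shared 0.02 s grid spanning their temporal overlap — the two
   headsets sample at variable (~80 Hz) rates and must be made
   sample-commensurable.
2. **Velocity** (`compute_velocity()`): per-axis first differences over
   timestamp differences. Velocities, not positions, carry the
   synchrony signal; they are also what makes the index insensitive to
   each participant's idiosyncratic resting pupil position.
3. **DTW distance** (`dtw_distance()`): classic dynamic programming with
   absolute-difference local cost, steps (i-1,j), (i,j-1), (i-1,j-1),
   no warping window, boundary-anchored — the textbook definition, since
   no variant is singled out. The three axis distances are averaged into
   one per-trial distance (`velocity_dtw()`); the combination rule across
   axes is a package choice.
4. **Normalization** (`normalize_sync()`): distances are negated and
   min–max scaled *within one session of one pair*, so `dtw_norm = 1`
   marks that session's most synchronous trial. Session-scoped
   normalization makes trials comparable where the model consumes them —
   along one session's trajectory — at the price of not being comparable
   across pairs. If every trial ties (degenerate range), all trials get
   0.5 rather than asserting either extreme.
5. **Weight** (`gamma_weight()`): `gamma_t = gamma0 * dtw_norm`, bounded
   by `gamma0`.

Zero-lag Pearson correlation of the aligned velocities
(`cross_correlation()`) is carried alongside as the instantaneous
counterpart of the shape-based DTW index; constant series yield `NA`
rather than a fabricated zero. Lag-searching correlation is out of scope.
The pipeline is unit-agnostic: headset position units cancel in the
min–max normalization.

## The simulator

`simulate_session()` regenerates the experiment's structure so the whole
loop runs without recorded data: 24 trials per session (8 in practice)
drawn from 12 objects — three per category (Kitchen/Garage) × difficulty
(Easy/Hard) cell — in both handle orientations, presented in a seeded
random order balanced 12/12 in category and difficulty. The bot partner
is deterministic: correct on every Easy object, incorrect on every Hard
object. Human-like agents follow the category rule on Easy trials with a
lapse probability and touch Hard objects with a configurable probability
(default 0.5 — no pre-convergence distribution for Hard items is known,
so maximal ambiguity is the neutral choice).
When both agents intend to touch, each draws a latent reaction time
(log-normal, median ≈ 0.9 s, capped below the 3 s response window) and
only the earlier touch is recorded, ties going to self — the log encodes
a single first touch, so `(a_s, a_p) = (1, 1)` can never occur. For
human-pair sessions `agent = "model"` instead couples two
active-inference agents that choose their Hard-trial actions by
free-energy argmin over beliefs about each other, a sandbox for
bidirectional adaptation.

`synthesize_gaze_pair()` emulates the gaze streams: per axis, participant
A follows a smooth latent trajectory (low-pass-filtered Gaussian noise —
a smoothness assumption standing in for real oculomotor structure, which
is not otherwise characterized); participant B mixes that latent with an
independent smooth trajectory at weight `rho`, plus sensor jitter,
timestamp jitter, optional lag and optional missingness. `rho` is the
synchrony dial: `rho = 1` (noise-free) duplicates the stream, `rho = 0`
decouples the pair, and mean DTW distance decreases monotonically in
`rho` — a property the test suite checks across seeds. Simulator defaults
place human pairs at `rho = 0.7` and bot pairs at `rho = 0.3`, encoding
the qualitative finding that human–human dyads coordinate gaze more
strongly than human–bot dyads.

What the simulator does *not* emulate: reaction-time structure beyond
tie-breaking (no handle/Simon congruency effects), saccade/fixation
micro-structure, gaze-on-object semantics, or any drift in agent policy
within a session. Tests passing on simulated sessions therefore certify
the model's mechanics and the pipeline's correctness, not empirical
claims about human data.

## Evaluation

`evaluate_trace()` aggregates traces into: partner-prediction accuracy
(first-layer probability thresholded at ≥ 0.5 — 0.5 itself predicts a
touch, which also makes the accuracy invariant to monotone score
transforms preserving the threshold side), self-prediction accuracy
(chosen action vs observed action), and a classification suite for the
thresholded partner prediction with the partner's touch as the positive
class: precision, recall, F1 (harmonic mean; 0 when precision and recall
are both 0), Matthews correlation, and rank-based AUC with ties counted
half (the Mann–Whitney convention). Undefined cases — no predicted
positives, a single observed class — are reported as `NA`, never as 0.
`trajectory_summary()` averages accuracy and the per-trial minimum free
energy `min(G(0), G(1))` across sessions by trial position, optionally
restricted to the 12 Hard trials (re-indexed 1..12), and
`plot_trajectories()` draws the learning curves. `ztest_power()` supplies
the closed-form post hoc power of a z-test from a noncentrality parameter
and its standard deviation.

```{r}
sess <- simulate_session(session_spec("bot_pair", seed = 7),
                         gaze_duration = 1.5)
sync <- session_synchrony(sess$gaze$a, sess$gaze$b, gamma0 = 0.9)
trace <- run_session(sess$trials, sync = sync,
                     config = model_config(gamma0 = 0.9))
unlist(evaluate_trace(trace)[c("acc_partner", "acc_self", "f1", "auc")])
```

## Numerical and scale choices

* All logarithms are natural; divergences are in nats.
* Probability clipping at `epsilon = 1e-12` is the only guard the KL
  needs; no special-casing of 0/1 beliefs.
* The softmax subtracts the minimum energy before exponentiating.
* Degenerate synchrony normalization (all-equal distances, single trial)
  maps to 0.5.
* Test and example workloads run at desk scale by design: 6–7 simulated
  sessions, 1.5 s gaze windows for DTW-heavy checks, 25–50 Monte Carlo
  seeds. These sizes exercise every code path; nothing in the
  implementation changes at larger scale.

## Limitations

The model is exactly the binary-action, two-conditional architecture
described above — no per-object beliefs, no continuous states, no POMDP
machinery, and no fitting of the fixed constants. The synchrony index is
session-relative, so `gamma_t` values are not comparable across pairs.
The simulator's agents are intentionally simple; in particular the
human-pair default (`agent = "table"`) has no within-session learning, so
convergence dynamics in simulated human pairs come entirely from the
model side unless the coupled `agent = "model"` mode is used. Absolute
prediction-accuracy levels reported for the original participants cannot
be reproduced without their (non-deposited) behavioral and gaze records;
the package's simulated loop reproduces the qualitative signatures —
free energy falling across trials and partner-prediction accuracy rising
toward the final trials — which its test suite computes and asserts.
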