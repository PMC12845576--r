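# dyadinfer

Synchrony-weighted active inference for dyadic category agreement.

When two agents must converge on a shared judgment about ambiguous
categories — touch the object if it is "yours", where only joint
experience can settle whose it is — each agent has to learn a model of
its partner while acting. `dyadinfer` implements a computational account
of this process for cognitive scientists and human–robot-interaction
researchers: a dual-layer Bayesian partner model, free-energy action
selection with an agreement term weighted by measured gaze synchrony,
the gaze-synchrony pipeline itself (dynamic time warping over paired
pupil-velocity streams), and a simulator of the underlying VR
categorization experiment so the full model–data loop runs end to end
without any recorded data.

## The model

Actions are binary (touch / no touch). The belief about the partner is
conditioned on the self action and held in two layers:

* **Counting layer**: `P(A_p = 1 | A_s = a) ~ Beta(α_a1, β_a1)`, updated
  by pseudo-count increments from each observed action pair; predictions
  are posterior means.
* **Recency layer**: an exponential moving average per condition,
  `Q ← α·a_p + (1−α)·Q`, updated only when the trial's self action
  matches the condition.

Each candidate self action `a` is scored by

```
G(a) = κ · d/(1+d) + λ₀ · γ_t · (2 Q(a) − 1),   d = KL(Bern(Q(a)) ‖ Bern(P(a)))
```

and the agent takes the argmin (softmax probabilities
`π(a) ∝ exp(−G(a)/τ)` are reported for evaluation). The per-trial weight
`γ_t = γ₀ · DTW_norm` comes from gaze: dynamic-time-warping distances
between the dyad's pupil-velocity streams, negated and min–max
normalized within the session, scale the base weight `γ₀ ∈ [0, 1]`.
Defaults: `κ = 0.1`, `λ₀ = 1`, `τ = 1`, `α = 0.8`, uniform Beta priors,
`γ₀` studied on the grid {0, 0.1, 0.5, 0.9}.

## Worked example

Simulate one session with a bot partner (correct on Easy objects,
always wrong on Hard ones), extract per-trial gaze synchrony, run the
model at `γ₀ = 0.9`, and evaluate:

```r
library(dyadinfer)

sess  <- simulate_session(session_spec("bot_pair", seed = 7), gaze_duration = 1.5)
sync  <- session_synchrony(sess$gaze$a, sess$gaze$b, gamma0 = 0.9)
trace <- run_session(sess$trials, sync = sync, config = model_config(gamma0 = 0.9))

head(sync, 3)
#>   trial_id   dtw_raw  dtw_norm     xcorr   gamma_t
#> 1        1 -328.2534 0.5186157 0.4365725 0.4667541
#> 2        2 -322.2569 0.5927489 0.2963961 0.5334740
#> 3        3 -312.8541 0.7089929 0.4180787 0.6380936

round(unlist(evaluate_trace(trace)[c("acc_partner", "acc_self",
                                     "precision", "recall",
                                     "f1", "auc", "mcc")]), 3)
#> acc_partner    acc_self   precision      recall          f1         auc         mcc
#>       0.875       0.458       0.786       1.000       0.880       0.871       0.777
```

`dtw_raw` is the negated DTW distance for the trial, `dtw_norm` its
min–max position within the session (1 = the session's most synchronous
trial), and `gamma_t = 0.9 · dtw_norm` the weight the agreement term
receives on that trial. The evaluation row says the model anticipated
the bot's action on 87.5% of trials (every predicted touch that scored
≥ 0.5 was counted as a touch prediction), while self-action accuracy is
near chance — the simulated participant decides Hard trials by a coin
flip, which no partner model can predict. The free-energy trajectory
over the 12 Hard trials falls as the partner model absorbs the bot's
deterministic policy:

```r
round(trajectory_summary(trace, hard_only = TRUE)$fe_min_mean, 3)
#>  [1]  0.000  0.000 -0.228 -0.461 -0.325 -0.578 -0.545 -0.093 -0.435 -0.196
#> [11] -0.323 -0.465
```

A command-line wrapper over the same functions is installed at
`inst/cli/dyadinfer` (subcommands `simulate`, `sync`, `run`,
`evaluate`), e.g.

```sh
Rscript inst/cli/dyadinfer simulate --session bot_pair --seed 7 --out-dir out/
```

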