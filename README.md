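# twostepeeg

Simulation and analysis of a modified two-stage, one-decision Markov task
with interleaved **predictable** (75/25 common vs. rare transitions) and
**random** (50/50) stimulus sets sharing an identical 70/30 reward
structure (±3 ct), together with the full model-based EEG analysis chain
that this design supports: a hybrid model-free/model-based
reinforcement-learning agent, hierarchical Bayesian fitting, synthetic
feedback-locked EEG with known ground truth, ERP and time-frequency
component quantification, and single-trial coupling between model-derived
reward prediction errors (RPEs) and component amplitudes.

It is aimed at computational cognitive neuroscientists who want a tested,
fully synthetic re-implementation of this analysis style — every input the
pipeline consumes is generated by the package itself, so every claim the
test suite makes is checkable against ground truth.

## The model

Stage-2 stimulus values follow temporal-difference learning,

    Q_S2(p) <- Q_S2(p) + α [r − Q_S2(p)],

the bracketed term being the RPE. Stage-1 action values update through an
eligibility trace, `Q_S1(a) <- Q_S1(a) + α [Q_S2(p) − Q_S1(a)] +
α λ [r − Q_S2(p)]`, with both deltas referencing the pre-update stage-2
value; unvisited values decay by (1 − α). An internal model counts
set-specific transitions, tags the set with the larger absolute
common-minus-rare counter difference as predictable (0.75/0.25 beliefs,
oriented by the sign; 0.5/0.5 otherwise), and evaluates actions by the
one-step Bellman equation. Choice is softmax over
`Q_net = ω Q_MB + (1 − ω) Q_MF` with inverse temperature β and
perseveration ρ. The five parameters (α, λ, β, ω, ρ) are fitted by MAP per
subject or hierarchically by MCMC (Gaussian group distributions on
transformed scales, split-Rhat diagnostics, WAIC model comparison).

## Worked example

```r
library(twostepeeg)

p <- agent_params(alpha = 0.21, lam = 0.96, beta = 1.95,
                  omega = 0.33, rho = 0.73)
trials <- simulate_agent(p, task_config(), seed = 42)

# recover the parameters from the simulated choices
fit <- fit_subject(trials, seed = 1)
round(unlist(fit$params), 3)
#> alpha   lam  beta omega   rho
#> 0.305 0.796 2.190 0.243 0.699
```

One 400-trial session recovers the generating values only roughly — the
likelihood has a ridge trading α against β and ω, and λ is weakly
identified; this is a property of the design size that the recovery tests
assert as calibration, not pinpoint accuracy.

Stay probabilities across a 30-agent cohort at these parameters show the
signature mixture of model-free and model-based control in the
predictable condition (rows: previous loss/win; columns: rare/common):

```r
#>     tra
#> rew     -1     1
#>   -1 0.680 0.616
#>   1  0.736 0.749
```

with a strong previous-reward main effect (per-subject logistic
regression: estimate 0.24, p < 1e-4) and a positive reward × transition
interaction (0.074) — stays are likeliest after common-transition wins.

The EEG arm turns model RPEs into synthetic epochs and measures them
back:

```r
rpes   <- derive_rpes(fit$params, trials)
epochs <- baseline_correct(generate_epochs(trials, rpes))
feats  <- trial_features(epochs)   # FRN, P3, theta, delta per trial
round(colMeans(feats[, c("frn_p2p", "p3_mean", "theta_db", "delta_db")]), 2)
#>  frn_p2p  p3_mean theta_db delta_db
#>   -15.95     8.11     1.07     0.84
```

(peak-to-peak FRN in µV at FCz — single-trial peak picking on 10 µV-RMS
noise biases it strongly negative, which is why inference runs on
correlations and cell means; P3 mean amplitude in µV at Pz; theta/delta
band power in dB). `rpe_regression()` and `group_inference()` then give
the per-subject standardized |RPE| slopes and the group-level t-tests and
sign × condition ANOVA; with the default generator, a 29-subject cohort
reproduces the built-in dissociation — the condition × expectancy
interaction and the |RPE| coupling appear on P3 in the predictable
condition only, while FRN effects are condition-blind.

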