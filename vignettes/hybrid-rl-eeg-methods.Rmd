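---
title: "Hybrid reinforcement learning and feedback-locked EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid reinforcement learning and feedback-locked EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepeeg)
```

## The task

`twostepeeg` simulates and analyses a modified two-stage Markov decision
task with a single decision per trial. On each trial one of two stimulus
sets is presented: in the *predictable* set, each first-stage action leads
to one of two second-stage pictures with probability 0.75 (common
transition) and to the other with 0.25 (rare); in the *random* set both
transition probabilities are 0.5. The reward structure is identical in both
conditions and fixed over time: one second-stage picture yields a win
(+3 ct) with probability 0.7, the other a loss (−3 ct) with probability
0.7. Sessions comprise 4 blocks of 100 trials, 50 per condition, randomly
interleaved with at most 3 consecutive trials of one condition. Because the
reward structure is shared, outcome *expectancy* (the 70% cells: wins after
the high-reward picture, losses after the low-reward picture) is defined
identically in both conditions — the conditions differ only in how useful
an internal model of the transitions is.

Interleaving uses rejection-free sequential sampling: at each position a
label is drawn uniformly from those that keep the remaining counts
arrangeable under the run cap (counts $n_1, n_2$ are arrangeable with cap
$m$ iff $n_1 \le m(n_2+1)$ and vice versa). This is deterministic under a
seed and never backtracks. Direction maps (which action commonly leads to
which picture) and the high-reward picture of each set are re-randomised
per block, mirroring the per-block re-assignment of sets. Missed responses
are not modelled: the agent always responds, because no lapse model is
part of the design.

## The hybrid agent

The agent combines model-free temporal-difference learning with
counter-based model-based evaluation. Stage-2 values update as

$$Q_{S2}(p_x) \leftarrow Q_{S2}(p_x) + \alpha\,[r - Q_{S2}(p_x)],$$

where the bracketed term is the reward prediction error (RPE). Stage-1
action values update with an eligibility trace,

$$Q_{S1}(a) \leftarrow Q_{S1}(a) + \alpha\,[Q_{S2}(p_x) - Q_{S1}(a)]
  + \alpha\lambda\,[r - Q_{S2}(p_x)],$$

with both deltas referencing the stage-2 value *before* its own update on
the same trial. We use the standard SARSA($\lambda$) orientation of the
first delta (stage-1 values move *toward* stage-2 values); the reversed
sign would drive stage-1 values away from their targets and diverges, so
it cannot be the intended rule. All values of non-chosen actions and
unpresented pictures — in both sets — decay by $(1-\alpha)$ each trial
(forgetting). Rewards are unit-coded ($r \in \{+1,-1\}$) inside the model;
$\beta$ absorbs the scale, and ct payoffs are kept for bonus accounting
only.

The internal model is a transition counter: for each set,
$d = (n_{a_A \to p_A} + n_{a_B \to p_B}) - (n_{a_A \to p_B} + n_{a_B \to p_A})$.
The set with the larger $|d|$ is tagged predictable and assigned 0.75/0.25
beliefs oriented by $\mathrm{sign}(d)$; the other set — and both sets on an
$|d|$ tie (including the all-zero start), or when $d = 0$ within the
identified set — hold 0.5/0.5 beliefs. Ties resolve to chance rather than
randomly so the likelihood is deterministic. Model-based values follow the
one-step Bellman equation $Q_{MB}(a) = \sum_p P(p\,|\,a)\,Q_{S2}(p)$, and
choice uses the softmax over
$Q_{net}(a) = \omega Q_{MB}(a) + (1-\omega) Q_{S1}(a)$ with inverse
temperature $\beta$ and a perseveration bonus $\rho$ for repeating the last
same-set choice.

Q-values, counters and last actions reset at block boundaries, because
sets are re-assigned per block; counters therefore do not persist across
blocks. Forgetting deliberately spans both sets (a literal reading of
"non-chosen or unpresented"), which we adopt as one consistent choice; the
alternative (active set only) changes little at the default $\alpha$
because cross-set presentations interleave tightly.

The five parameters and their bounds: learning rate $\alpha \in [0,1]$,
eligibility trace $\lambda \in [0,1]$, inverse temperature $\beta \ge 0$,
model-basedness $\omega \in [0,1]$, perseveration $\rho \in \mathbb{R}$.
Defaults ($\alpha=0.21$, $\lambda=0.96$, $\beta=1.95$, $\omega=0.33$,
$\rho=0.73$) are group-mean values typical for this task family and serve
as the generating truth in recovery studies.

The same C++ state recursion drives both simulation and likelihood replay,
so the likelihood is exactly the probability model of the simulator; a
test verifies that replaying a simulated session recovers its stored
per-trial choice probabilities to below 1e-10, and that an independent
composition of the exported R primitives matches the C++ path.

## Fitting

Bounded parameters are fitted on transformed scales (logit for the unit
interval, log for $\beta$, identity for $\rho$). `fit_subject()` provides
penalised maximum-likelihood point estimates (best of `n_restarts` BFGS
runs; the MAP penalty is Normal(0, 1.5) on the transformed scale — priors
are a design choice here, chosen weakly informative because nothing in the
data pins the scale of, e.g., extreme $\beta$).

`fit_hierarchical()` places a Gaussian group distribution per parameter on
the transformed scale, with Normal(0, 1.5) hyperpriors on locations and
half-Normal(0, 1.5) on scales. The sampler is Metropolis-within-Gibbs:
per-coordinate random-walk updates of unit-level parameters (proposal
scales adapted towards 44% acceptance during warm-up only), conjugate
Gibbs for group means, log-scale random walks for group scales, and an
interleaved non-centred move that jointly shifts a parameter's location
and scale while holding the standardized unit effects fixed. The
non-centred interleaving (ASIS) is what makes the location–scale funnel
mix; without it, split-Rhat of the group scales hovers above 1.1 at
realistic run lengths. Convergence is assessed with split-Rhat (each chain
halved) and a crude autocorrelation-based effective sample size; the
conventional bound is split-Rhat ≤ 1.1 at 4 chains × 2,000 iterations
(1,000 warm-up).

Units can be subjects or subject × set combinations. The set
factorisation is exact: the counter/belief recursion depends only on the
observed transitions, never on parameters, so each set's choice likelihood
depends only on that set's parameter vector. Model comparison uses WAIC
with the pointwise variance penalty (pWAIC2), computed from thinned
posterior draws.

At the design size of 4 × 100 trials, $\alpha$, $\beta$ and $\omega$ are
recoverable but noisy (the likelihood has a ridge trading $\alpha$ against
$\beta$ and $\omega$); $\lambda$ and $\rho$ are weakly identified. This is
a property of the design, not of the optimiser, and the recovery tests
assert calibration (truth inside the recovery distribution), not pinpoint
accuracy.

## Behavioural analyses

Stay/switch analysis links every trial to the preceding trial *of the same
condition within the same block* (the preceding trial of the experiment is
usually a different condition). Predictors are coded +1/−1 (reward:
win/loss; transition: common/rare) and stay 0/1. The hierarchical mode
fits `lme4::glmer` with all within-subject terms as random effects; a
per-subject mode (per-subject logistic fits, one-sample t-tests on
coefficients) is provided for small or separated data sets. Model-free
control appears as a reward main effect, model-based control as a
reward × transition interaction; the random condition omits transition
terms.

Performance metrics are the bonus (summed payoffs, ct → €) per condition
and block, and a learning curve over ten 5-trial subblocks of the 50
predictable trials per block, where a correct choice is the action whose
common transition leads to the high-reward picture. Under the symmetric
payoff structure the expected random-condition payoff of a random policy
is exactly zero (`chance_level_payoff()`), which anchors the bonus scale.
Blocks with a failed (synthetic) set-identity judgment can be excluded
with `filter_valid_blocks()`.

## Synthetic EEG

`generate_epochs()` builds feedback-locked epochs (−1000..+1500 ms at
512 Hz, channels FCz and Pz) as 1/f background noise plus four ground-truth
components: Gaussian ERP deflections (FRN: negative, fronto-central,
270 ms, 35 ms width; P3: positive, parietal, 400 ms, 60 ms width) and
amplitude-modulated sinusoidal bursts (theta: 6 Hz at FCz; delta: 2.5 Hz at
Pz) with per-trial random phase (20% of trials phase-locked by default, so
evoked and induced measures can dissociate). Each component's per-trial
amplitude is a linear function of valence, expectancy, condition and the
trial's |RPE|; the injected amplitudes are returned as a ledger so
downstream measures can be validated against ground truth.

The default coupling structure encodes the dissociation the pipeline is
designed to detect: FRN and theta carry expectancy and |RPE| signal in
*both* conditions (condition-blind, unsigned-RPE correlates), while P3 and
delta carry them in the predictable condition only. Default effect sizes
(1.5–3 µV against 10 µV RMS noise) are in the range typical of
feedback-locked ERP components; the noise is 1/f (periodogram slope −1.0,
generated by a calibrated filter cascade) rather than white so that
decibel baselining is exercised against a realistic spectrum.

What the generator does *not* emulate: volume-conducted topographies
beyond two channels, ocular artifacts (gross artifacts are injected as
square pulses for testing the ±300 µV rejection rule), latency jitter of
components, and autocorrelated single-trial amplitude fluctuations.
Passing the end-to-end tests therefore shows that the measurement and
inference chain recovers a known generative structure — not that real EEG
obeys that structure.

## Component quantification

All measures follow the averaged-data conventions exactly, at single-trial
level as well. FRN: 15 Hz second-order Butterworth low-pass (zero-phase,
forward–backward, so peak latencies do not shift), then the most negative
genuine local minimum in 200–350 ms minus the mean of the flanking maxima
in 100 ms windows before/after the peak. A flank window whose maximum sits
on its outer edge is widened outward in 10 ms steps up to 300 ms total
width; widening only grows outward so the two flanks can never swallow the
FRN peak. A waveform without a negative-going local extremum in the search
window falls back to the window minimum and is flagged. Peaks are genuine
extrema (no greater than both neighbours, strictly less than at least
one), with plateau ties resolved to the earliest sample for determinism.
P3 is the plain 300–500 ms mean at Pz.

Time-frequency power uses complex Morlet wavelets
$e^{-i 2\pi t f}\, e^{-t^2/2\sigma^2}$ with $\sigma = 4/(2\pi f)$ over 50
logarithmically spaced frequencies from 1 to 50 Hz, FFT convolution, and
decibel baselining $10\log_{10}(P/P_{base})$ with baseline −300..−200 ms.
The baseline pools power across trials per channel × frequency before
normalising each trial: single-trial baselines are unstable at 1–4 Hz
(a 100 ms window is a fraction of a delta cycle), and the pooled baseline
keeps the dB transform monotone per trial. Samples within half a wavelet
support of the epoch edges are flagged per frequency, not dropped. Theta
is 4–8 Hz × 200–400 ms at FCz; delta 1–4 Hz × 300–500 ms at Pz. Windows
are closed intervals in ms with time 0 at feedback onset.

Cell-level inference uses within-subject factorial ANOVAs
(condition × expectancy × valence) computed from per-subject cell means,
each effect tested against its subject-by-effect stratum; the
implementation is cross-checked in the tests against brute-force contrast
enumeration (every effect in a two-level within design is a squared paired
t).

## RPE coupling

Single-trial amplitudes are regressed on |RPE| separately per subject,
condition and RPE sign (positive RPEs arise from wins, negative from
losses), after z-scoring both variables within the regression cell — the
standardized slope is then the Pearson correlation, invariant to affine
rescaling of either variable. Splitting by sign while regressing on
magnitude is what lets signed and unsigned coding dissociate: unsigned
coupling gives same-sign slopes in both splits. Cells with fewer than 8
trials are dropped (unexpected cells are the small ones; a lower floor
makes single-cell correlations too noisy to average). Group inference is
one-sample t-tests of mean slopes against zero (overall, per condition,
per cell) plus a within-subject sign × condition ANOVA.

## Problem sizes and numerical choices

The test suite exercises the pipeline at the full design size where that
is cheap (sessions of 4 × 100 trials; cohorts of 29 synthetic subjects for
the end-to-end dissociation, 100 replicates) and at reduced sizes where
the full Bayesian machinery is involved (hierarchical convergence is
checked on 8 subjects; the acceptance script runs the full
4 × 2,000-iteration schedule). Likelihood evaluations clamp choice
probabilities at 1e-12 before the log. Monte-Carlo frequency checks use
three binomial standard errors at n = 20,000–100,000. All measurement
paths are deterministic given their input; every stochastic step
(sequence generation, agent simulation, EEG synthesis, MCMC) is
reproducible under a seed.

## Known limitations

Reaction times, missed responses and alternative arbitration schemes
(e.g., reliability-weighted $\omega$) are out of scope, as are source
topographies and ICA-style artifact correction. $\lambda$ and $\rho$ are
weakly identified at the design size and their recovery is documented,
not enforced. The WAIC comparison implemented here contrasts the full
5-parameter model with a collapsed uniform-choice reference; a full
ablation family is straightforward to add through `fit_hierarchical()`'s
unit mechanism but is not part of the shipped tests.
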