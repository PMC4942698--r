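---
title: "Detecting fast spontaneous state sequences in sensor-level MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fast spontaneous state sequences in sensor-level MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sequenceness)
```

# The problem

Rodent hippocampal recordings show that neural populations spontaneously
play out fast, temporally compressed sequences of state representations --
replay within sharp-wave ripples, theta sequences during movement. This
package implements an analysis pipeline for asking the analogous question
non-invasively in humans: do sensor-level MEG recordings, taken while a
person is quietly planning in a learned six-state task, contain fast
sequences of decodable state representations that follow the task's
transition structure?

The pipeline has five stages, each an exported module:

1. **Task model** (`task_graph`, `generate_session`, `evaluate_plan`, the
   behavioral models): a six-state maze with two deterministic actions per
   state, drifting rewards, and "neg" states that flip the sign of the
   running reward total.
2. **Synthetic MEG** (`synth_config`, `simulate_localizer`,
   `simulate_planning`): a generator that emulates the statistical
   structure the analysis assumes, with ground-truth logs.
3. **Preprocessing** (`downsample`, `highpass`): anti-aliased decimation to
   100 Hz and a 0.5 Hz first-order IIR high-pass.
4. **Decoding** (`train_state_classifiers`, `predict_state_probabilities`,
   `crossval_report`): per-state lasso logistic models trained on the
   single sample 200 ms after stimulus onset, applied independently to
   every 10 ms bin of planning data to give a time-by-state probability
   matrix `X`.
5. **Sequenceness** (`sequenceness_curve`, `permutation_thresholds`,
   `length_n_curve`) and **group statistics** (`mixed_intercept_fit`,
   `pair_anova`, `tuple_contrast`): the lagged statistic, its permutation
   nulls, and random-intercept inference.

# The sequenceness statistic

Let `X` be the decoded probability matrix (rows: 10 ms bins; columns: the
six states) and `T` the task's row-stochastic transition matrix with 0.5 on
each of the two out-edges of a state. Projecting one step through the
transitions, `X^F = X T`, makes column *j* of `X^F` the aggregated evidence
that a *predecessor* of state *j* was active. Forward sequenceness at lag
$\Delta$ is

$$f(\Delta) = \frac{1}{6}\sum_{j=1}^{6}
  \mathrm{corr}\!\left(X^F_j(t),\; X_j(t+\Delta)\right),$$

the mean Pearson correlation over states between predecessor evidence at
*t* and the state's own probability at $t+\Delta$. Reverse sequenceness
$r(\Delta)$ uses `X^R = X T'`, and the reported statistic is
$d(\Delta) = f(\Delta) - r(\Delta)$. Correlations use the truncated overlap
of the two series (no padding), and a zero-variance column contributes 0.

Two conventions are worth stating because the definition is directionally
ambiguous on paper:

* **Sign.** The shift is applied so that data containing an explicit
  forward pair (state *a* at *t*, a successor of *a* at $t+\Delta$) yield
  *positive* forward sequenceness. A unit test pins this orientation.
* **Aggregation.** Curves are computed per trial and averaged unweighted;
  trial-level values feed the group statistics. Trial weighting is not
  specified by the source analysis; unweighted averaging is the simplest
  defensible choice and is applied identically to observed and shuffled
  statistics.

`brute_force_sequenceness()` recomputes $d(\Delta)$ with explicit scalar
loops (no matrix algebra, no `cor()`); the matrix implementation and the
compiled fast paths used by the permutation machinery are all pinned to it
in the test suite to $10^{-10}$.

## Length-n sequences

`length_n_curve()` generalizes the statistic to chains of *n* states: per
state and lag it sums the product of `X` projected $n-1, \dots, 0$ steps,
taken at staggered shifts $0, \Delta, \dots, (n-1)\Delta$. The values are
un-normalized sums, so magnitudes are not comparable across *n*; only
reliabilities (e.g. mixed-model z or p values) should be compared.

# Inference

## State-identity permutations

The null model permutes *state labels*, not time samples: each relabeling
$\sigma$ induces a permuted transition matrix $T_\sigma[a,b] =
T[\sigma(a),\sigma(b)]$ and the statistic is recomputed under $T_\sigma$.
`enumerate_label_classes()` groups the 720 relabelings of six states by the
matrix they induce. For the default maze (see below) this yields exactly
30 distinct matrices, of which one is the identity and one is the full
reversal (the relabeling mapping `T` onto its transpose); the other 28
serve as exchangeable shuffles. The threshold is maximal-statistic: per
shuffle, take the peak of `|d|` over all lags; the global threshold is the
maximum over shuffles, giving a familywise two-tailed level of
$1/28 \approx 0.036$ over the whole lag grid.

## Why not shuffle time samples

Sensor-level MEG is strongly autocorrelated. Shuffling sample order
destroys that autocorrelation, so shuffled null curves are far flatter than
any statistic computed on intact data, and the test rejects at many times
its nominal level. `sample_order_thresholds()` implements this null
deliberately, and the acceptance suite demonstrates the inflation on AR(1)
null data (observed rejection rate at least three times nominal, versus a
state-identity null inside its binomial band). Use
`permutation_thresholds()` for inference.

## Group-level model

`mixed_intercept_fit()` fits $y_i = \beta + b_k + \varepsilon_i$ with
subject-level Gaussian intercepts $b_k$ by maximum likelihood (lme4,
`REML = FALSE`) and reports a Wald normal two-tailed p for $\beta$. The
Wald choice follows the design decision to keep the estimator simple and
fast; with a single observation per subject the variance components are
confounded and the function deliberately collapses to a one-sample t-test
(with a warning). An optional covariate adds one fixed slope -- this is the
estimator used for trial-wise regressions of sequenceness on earnings or
planning time.

# The task graph

The maze has six states and two actions ("up", "down"); every action leads
deterministically to a different state, with no self-loops. The published
description constrains but does not fully specify the edge layout. The
default here is the circulant layout `up: i -> i+1`, `down: i -> i+4`
(mod 6), which satisfies every textual constraint (S1 leads to S2 and S5;
S4 -> S5; S5 -> S6 are edges). Enumeration shows its transition matrix has
an automorphism group of order 24, so the state relabelings collapse to
exactly 30 classes with both the identity and the reversal present -- the
same counts the original analysis reports. The layout is overridable via
`task_graph(edges = ...)`, and `enumerate_label_classes()` lets any
candidate layout's symmetry be checked.

Reward accounting follows the task rules: entering a state adds its current
reward (integer pence in $[-5, 5]$) to the running total, and entering a
neg state then flips the sign of the total (a pre-flip $-9$ becomes $+9$).
The start state's own reward is not collected: only entered states
contribute. Rewards drift by $-1/0/+1$ with equal probability between
trials and are clamped to the permitted range; the clamp is our choice, as
boundary behavior is unspecified.

## Behavioral models

Four choice models are implemented (`choice_model_probs`,
`fit_and_compare`): **Plan** (softmax over the earnings of all 16
four-move plans), **Greedy** (per-move softmax over local one-step return,
including the neg flip of the running total -- an assumption, flagged,
since the source text does not say whether the local evaluation accounts
for it), **Qfirst** (structure-free Q-table over the 12 state-action
pairs, updated only for the first move toward realized earnings), and
**Qall** (structure-aware Q-table, all four visited pairs updated). All
four are expressed as distributions over the 16 plans; for Qfirst the
moves after the first are uniform, since without structure knowledge the
agent cannot track its state during feedback-free pre-entry. The
functional forms (softmax, single learning rate, update target equal to
realized trial earnings) are defaults exposed as parameters: the source
describes the models only at the level quoted above. BIC uses the number
of trials as the sample size, and comparisons include a zero-parameter
uniform baseline.

# The synthetic world

The generator's defaults are a *stated world*: they were chosen once,
before the acceptance thresholds were evaluated, to emulate the features
of real sensor data the analysis relies on, and are not tuned afterwards.

| Parameter | Default | Why |
|---|---|---|
| `n_sensors` | 134 | the real montage's sensor count |
| `fs` | 100 Hz | 10 ms analysis bins |
| `evoked_peak_latency_ms` | 200 | decoders train at this latency |
| `evoked_halfwidth_ms` | 100 | smooth evoked transient, support 100-300 ms |
| `activation_width_ms` | 30 | brief reactivation transient; waveform unreported, raised cosine assumed |
| `lag_ms` | 40 | the state-to-state lag at which replay is reported |
| `event_rate` | 1.5 /s | sparse but detectable replay during planning |
| `direction_mix` | 1 (reverse) | reverse replay is what was observed |
| `length_dist` | uniform on 2-4 | sequences of up to four states |
| `snr` | 3.5 | localizer decoding around 50% (chance 16.7%), decoded baseline ~0.06 |
| `ar_coeff` | 0.8 | strong 1/f-like autocorrelation; what breaks sample shuffles |
| `planning_duration_s` | 10-60 | planning periods up to 60 s |

Spatial patterns are *focal*: each state's topography lives on a random
15% of sensors (`make_state_patterns`). This matters -- with dense random
patterns the per-sensor signal is $\approx 0.17$ noise SD and a lasso
decoder is at chance; real evoked topographies concentrate signal on a
modest set of posterior sensors, which is precisely why a sparsity-seeking
decoder works. Noise is stationary AR(1) per sensor with unit marginal
variance.

What the generator does **not** emulate: realistic MEG spectra, sensor
covariance from volume conduction, artifacts (blinks, cardiac), amplitude
or lag jitter of replay events, and any relationship between behavior and
replay content. A green pipeline test therefore establishes that the
implementation detects the structure it claims to detect under the stated
assumptions -- not that those assumptions exhaust real data.

# Decoding

One-vs-rest lasso logistic models (glmnet, `alpha = 1`,
`standardize = FALSE`, convergence threshold $10^{-8}$) are trained per
state on the single 200 ms sample; the L1 penalty applies to the 134
sensor slopes only, leaving the intercept free, so each model is a weight
vector of length 135 and the large-penalty limit predicts the class base
rate. The 1:5 class imbalance is absorbed by the intercept, with no
reweighting. Cross-validation uses the constrained balanced partition:
every class keeps `min(class counts) - 1` training trials, every class has
at least one left-out trial, and the number of left-out trials is minimal
given the other two constraints. Shuffle nulls re-run the identical
procedure with permuted labels and use maximal statistics (max mean
probability over states and times; max accuracy over times) at the 95th
percentile.

The lasso penalty is selected per subject by leave-one-subject-out
(`select_penalty`): for each held-out subject, the penalty maximizing the
*absolute* group-mean sequenceness at its extremal lag among the other
subjects. The absolute extremum is our resolution of an ambiguity (the
source does not state signed versus absolute, nor which lag); it avoids
assuming the effect's direction. The default grid spans $[10^{-4},
10^{-1}]$ logarithmically, bracketing the 0.006 group mode reported for
the real data; the pipeline default penalty is that mode.

# Numerical choices and degenerate inputs

* Correlations on the truncated overlap; zero-variance columns contribute
  0 rather than NA, so a flat decoder output yields a curve of zeros, not
  a failure.
* The high-pass filter is applied forward-backward by default (documented
  prominently: lagged statistics are phase-sensitive, and a causal
  single-pass option exists for matching acquisition-style filtering; the
  original analysis does not state which was used).
* Decimation uses a linear-phase windowed-sinc FIR at 0.8 x the new
  Nyquist with reflective padding, so constants pass unchanged and 45 Hz
  content is suppressed by more than 20 dB after 600 to 100 Hz decimation.
* Optimization: behavioral fits run a coarse grid then Nelder-Mead/Brent
  on transformed scales (`log beta`, `logit alpha`); glmnet is given a
  decreasing penalty path ending at the target to keep warm starts.
* Determinism: every generator consumes the R RNG stream; the pipeline
  expands one seed into independent per-stage streams, so a rerun with the
  same configuration is byte-identical.
* Compiled kernels (`src/seqness.cpp`) restate the per-lag correlations in
  terms of segment moments for the permutation and sample-order nulls;
  they are pinned to the R reference implementation and to the loop oracle
  in the tests.

# Length-n sequences: a known limitation

With only 4-chains planted, the acceptance suite asks for length-3 and
length-4 reverse sequenceness to be reliable and length-5 to be
unreliable, mirroring the qualitative pattern reported for real data. In
this generator the first two hold robustly, but the length-5 clause fails
*for a real reason*: the length-5 statistic multiplies five staggered
probability columns, and a planted 4-chain contributes four matched
factors plus one *baseline* factor ($\approx 0.06$), producing a small but
systematic forward/reverse asymmetry. With noise-free 40 ms lags and
synthetic statistical power, the mixed model detects this partial-chain
leak (the length-5 effect is ~40x smaller than length-3, but reliably
nonzero). In real data the same leak presumably exists but is buried in
noise at the available power. We keep the assertion as specified -- it
fails honestly -- rather than weaken the criterion or inject lag jitter
after the fact to suppress the leak.

# Interfaces

Sensor time series, localizer epochs and trained classifiers serialize to
HDF5 (`write_sensor_h5`, `write_localizer_h5`, `write_classifiers_h5`);
sessions, choices, decoded probabilities and curves export as tidy CSV;
configurations are YAML (`write_config`); fit reports are JSON. The CLI
(`seqness_cli`, installed at `inst/cli/seqness`) exposes `simulate`,
`decode`, `seqness`, `permtest`, `behavior`, `report` and `run-all`
subcommands over a shared YAML configuration.
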