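---
title: "Input-driven GLM-HMMs: model, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input-driven GLM-HMMs: model, fitting, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmhmm)
```

## The model

`glmhmm` models trial-by-trial binary choices in a two-alternative
forced-choice task as emissions of a hidden Markov chain over K discrete
behavioral states, with generalized linear models on both layers.

**Emissions.** In state $k$ the choice $y_t \in \{0, 1\}$ (left/right) is
Bernoulli with
$$p(y_t = 1 \mid z_t = k, x_t^{ob}) = \frac{1}{1 + e^{-w_k^{ob} \cdot x_t^{ob}}},$$
where $x_t^{ob}$ contains the normalized signed stimulus contrast, the
previous choice coded $\pm 1$, the previously rewarded side (the product of
the $\pm1$ previous choice and the $\pm1$ previous reward — the unique
$\pm1$ covariate encoding "stay after reward, switch after failure"), and a
constant bias of 1. Engaged states have large stimulus weights and small
biases; disengaged states the reverse.

**Transitions.** The probability of entering state $j$ from state $i$ at
trial $t$ is a multinomial (softmax) GLM
$$P(z_t = j \mid z_{t-1} = i, x_t^{tr}) \propto
  \exp\!\big(B_{ij} + w_j^{tr} \cdot x_t^{tr}\big),$$
with a learned baseline logit matrix $B$ and one covariate filter per
*destination* state, shared across origins. Sharing destination filters is a
deliberate restriction: it separates "what drives the system toward state
$j$" (the filters) from "how sticky each state is" (the baseline logits),
and it keeps the parameter count linear in K.

**Transition covariates.** $x_t^{tr}$ holds exponentially filtered versions
of the $\pm1$ choice, rewarded-side and reward series, plus warm-up basis
functions:

- *Exponential filter.* $f_1 = 0$, $f_t = e^{-1/\tau} f_{t-1} + s_{t-1}$,
  with $\tau$ in trials (default 4, the scale selected by held-out
  log-likelihood in the motivating analyses). The filter is strictly causal
  (row $t$ uses only trials before $t$) and resets at session boundaries,
  so transition probabilities never condition on the current trial's
  outcome. We chose the unnormalized form (no $1-e^{-1/\tau}$ factor); the
  Gaussian prior on the weights absorbs the resulting scale, and a
  normalized filter would only rescale the fitted filter weights.
- *Warm-up bases.* Three non-overlapping raised-cosine bumps tiling trials
  1–100 of each session, peak-normalized to 1 and exactly zero afterwards.
  Only the count, span, and linear independence are structurally important;
  non-overlapping smooth bumps make the basis trivially independent and the
  fitted basis weights directly interpretable as an early/middle/late
  session effect. They let transition probabilities differ while the animal
  "warms up" without contaminating the stationary filters.

**First-trial padding.** History covariates are set to 0 (the neutral point
of a $\pm1$ code) at each session's first trial rather than dropping the
trial, preserving session length for the forward–backward recursions.

## Priors and the identifiability mechanism

All weights carry independent zero-mean Gaussian priors: $\sigma_{ob}$ on
$W^{ob}$ and $\sigma_{tr}$ on both $W^{tr}$ and $B$ (default 4 each, the
value a σ ∈ {0.25, 0.5, 1, 2, 4, 8, 16} grid search selects on held-out
data in the motivating analyses; `grid_search_sigma()` reruns the search).
The initial state distribution has a symmetric Dirichlet prior with
$\gamma_\pi = 1$.

The softmax is invariant to adding a constant vector to every destination
filter (and to every row of $B$): the likelihood alone cannot identify that
direction. We deliberately impose no hard constraint (no pinned reference
state); the Gaussian prior resolves the degeneracy by selecting the
minimum-norm representative, which is also why $B$ must be included in the
prior. The package keeps the priors' normalizing constants, so log-posterior
values are comparable across prior widths; because of those constants the
log-prior of small weights is *not* monotone in σ — only weights larger
than σ are meaningfully penalized.

A practical consequence for interpreting fits: only *between-destination
differences* of transition filters are likelihood-identified. Sign analyses
in the package's tests therefore examine
$w^{tr}_{j} - w^{tr}_{j'}$ between destination states rather than raw
entries.

## Fitting

MAP estimation uses expectation–maximization:

- **E-step.** Scaled (normalized-message) forward–backward recursions per
  session, each re-seeded with $\pi$ and with per-trial transition matrices;
  per-trial scale factors are accumulated so the marginal log-likelihood is
  exact. Emissions are max-subtracted per trial before exponentiation; no
  probability clipping occurs inside the recursion. The recursions are
  implemented in C++ (they run once per EM iteration over every trial) and
  are verified in the test suite against exhaustive enumeration over all
  $K^T$ latent paths for small instances, and against a plainly written
  textbook forward–backward when the transition model is static.
- **M-step.** The expected complete-data log-likelihood plus the Gaussian
  log-prior is maximized jointly over $\{W^{ob}, W^{tr}, B\}$ by L-BFGS-B
  with analytic gradients (standard exponential-family forms, checked
  against finite differences in the tests); $\pi$ has the closed-form
  Dirichlet-regularized update $\pi_k \propto \max(0, \sum_s \phi_{1,k}^{(s)}
  + \gamma_\pi - 1)$. The M-step runs L-BFGS-B to (default) moderate
  precision each iteration — a generalized-EM scheme; full maximization can
  be requested via `mstep_control`.
- **Stopping.** EM stops when the log-posterior improves by less than `tol`
  (default 1e-4) or the M-step no longer moves the weights; a decrease
  beyond 1e-6 is treated as a hard error, because with an exact E-step it
  can only indicate a gradient bug. The default iteration cap is 300.
- **Initialization and restarts.** Observation weights start from a
  penalized one-state Bernoulli GLM on the pooled trials plus Gaussian
  noise (scale 0.2 per state — the value is not structurally important, it
  only breaks symmetry, and it is configurable); transition filters start
  at zero; $B$ starts at zero with a +1.5 diagonal (a sticky start, since
  behavioral states persist for many trials); $\pi$ uniform. `glmhmm()`
  runs 50 restarts by default and keeps the best final log-posterior.
  Warm-starting from a pooled fit (`warm_start`) implements the
  pooled-then-individual protocol and keeps state labels aligned across
  groups without post-hoc permutation.
- **Uncertainty.** `posterior_sd_weights()` builds the Hessian of the
  negative log-posterior by central differences of the exact
  (Fisher-identity) gradient of the marginal log-posterior — the E-step
  surrogate gradient recomputed at perturbed parameters equals the marginal
  gradient, so no second differentiation layer is needed. A
  non-positive-definite Hessian raises a diagnostic error listing the
  near-null directions instead of being pseudo-inverted; with the priors
  disabled the softmax shift direction is exactly such a null direction.

## Evaluation

Cross-validation assigns whole sessions to folds (never splitting a
session; 5 folds by default). Test sessions are scored by a single forward
pass with training-fitted parameters *and* the training-fitted contrast
normalizer. The score is bits per trial,
$L_{bpt} = (L_t - L_0) / (T_t \log 2)$, against a baseline $L_0$: the
log-likelihood of the test choices under a single Bernoulli rate fitted on
the training set. A constant-rate Bernoulli is the minimal "model of
observed data only" and the conventional reference; a fixed 0.5 rate is
available by argument. `likelihood_ratio_factor(bpt, n)` converts a
per-trial difference into the factor $2^{bpt \cdot n}$ by which the data
are more probable under the better model — small per-trial differences
compound into enormous factors at realistic trial counts.

`compare_transition_models()` fits the full model and a static-transition
ablation ($W^{tr}$ pinned at zero, $B$ free) on identical folds and seeds,
so the paired difference isolates the transition GLM's contribution, with a
percentile bootstrap over folds for its confidence interval.

## The task simulator

`generate_task()` emulates the standard mouse 2AFC stimulus-prior task:
each session opens with 90 unbiased trials, then right-stimulus probability
alternates between 0.8 and 0.2 in uncued blocks. Block lengths follow a
shifted truncated geometric law: after a 20-trial minimum a constant
per-trial switch hazard applies, truncated at 100 trials. The hazard is
solved numerically (by `uniroot` on the truncated-geometric mean) so that
the mean block length equals the 50-trial target; solving, rather than
using the untruncated hazard `1/(mean − min)`, is necessary because
truncation at 100 would otherwise drag the realized mean about three trials
low. Contrast magnitudes are uniform over {0, 6.25, 12.5, 25, 50, 100}%.

`simulate_agent()` plays a ground-truth GLM-HMM forward through the task,
recursively updating its filtered history covariates from its *own*
simulated choices and rewards. The covariate recursion is exactly the one
the design builders implement — a test asserts the simulator's internal
covariates and `build_transition_design()` agree to machine precision on
the simulated table. On zero-contrast trials the rewarded side is drawn
from the block's stimulus prior (the task's convention for zero-evidence
trials); for nonzero contrast, reward is +1 iff the choice matches the
stimulus side.

The shipped generator templates (`example_glmhmm_params()`, K = 2 and
K = 4) are *synthetic*: they reproduce the qualitative structure of fitted
mouse models — engaged states with stimulus weight ≈ 3 and small bias,
disengaged states with bias ≈ ±2.5 and small stimulus weight, sticky
baseline logits (diagonal ≈ 2.5–3, dwell ≈ 12–20 trials), side filters
signed by the destination's side bias and reward filters positive into
disengaged states — but they are not fitted values from any dataset.

### What the simulator does and does not emulate

Simulated data share the real task's block structure, contrast marginals,
and the model's own generative assumptions. They do not contain: learning
or slow nonstationarity in the weights themselves, response-time dynamics
(RTs can be attached per state for testing the RT analyses, but are
log-normal by construction), lapses not expressible as state mixtures, or
between-animal heterogeneity. Passing recovery and ablation tests on these
data therefore demonstrates correctness of the estimator under the model's
assumptions — not that real mouse behavior satisfies those assumptions.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen as the
smallest at which each property is statistically clean: oracle checks use
$T \le 8$, $K \le 3$ (exhaustive enumeration); EM monotonicity uses 20
restarts on a 4-session dataset; parameter recovery uses 40 sessions × 500
trials (≈ the per-animal data volume of a typical chronic study); the
ablation benchmark uses 24 sessions × 500 trials with 4 folds — at smaller
sizes the static arm shows a visible overfitting cost of the unused
transition filters relative to its fold-to-fold noise, which vanishes at
realistic data volumes. Dwell-time checks drop each session's final state
run, which is censored by the session end.

Degenerate inputs are errors, not warnings: zero contrast variance with a
fitted normalizer, non-binary choices with a row reference, k exceeding the
session count, a non-stochastic transition matrix. Exact posterior ties in
MAP labeling break to the lowest state index, deterministically. An
all-zero forward message (possible only with emission probabilities
underflowing to zero for every state) is an error naming the trial.

## Known limitations

- A single shared filter time constant τ; per-covariate constants and
  learnable τ are out of scope (matching the one-dimensional τ search the
  design mirrors).
- No Viterbi decoding: states are labeled by per-trial posterior argmax,
  which is the definition used by the analyses this package supports.
- No stochastic/minibatch EM or fully Bayesian posteriors; uncertainty is
  local (inverse Hessian at the MAP).
- The first trial's history covariates are padded, not marginalized; with
  typical session lengths (hundreds of trials) the effect is negligible.
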