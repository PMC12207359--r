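---
title: "Deep kernel GP meta-learning for few-shot reaction outcomes: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep kernel GP meta-learning: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why the
pieces look the way they do. It covers the probabilistic model, the
four trainers and their objectives, the featurization and task
protocols, the synthetic data generator and what passing tests on it do
and do not establish, the numerical choices, and known limitations.

## The prediction problem

Given a reaction record — olefin, ligand and solvent structures, the
metal, an additive flag, and temperature / pressure / catalyst loading —
predict whether the reaction is highly enantioselective (percent
enantiomeric excess strictly above a threshold, default 80; values at
the threshold fall in the low class so the rule has no ambiguous
boundary). Literature corpora for asymmetric olefin hydrogenation are
heterogeneous: a few substrate/ligand families dominate, and a new
project typically resembles a *sparsely populated* corner of the data.
We therefore treat prediction as few-shot meta-learning: the model is
trained on many related tasks and judged by how well it adapts to an
unseen task from a small support set.

## Deep kernel Gaussian processes

All Bayesian methods here share one building block. A feed-forward
network `f(x; θ_NN)` (tanh hidden layers, linear output) maps the
1544-dimensional reaction representation to a low-dimensional latent
`z`; a stationary base kernel with hyperparameters
`θ_GP = (log ℓ, log s², log σ_n²)` acts on the latents:

    k(x, x') = k'( f(x), f(x') | θ_GP ).

Binary labels are regressed as targets −1/+1 under a Gaussian
likelihood. This is a deliberate modelling choice: it keeps the
marginal likelihood

    NLML(X, y) = −log N(y | 0, K + σ_n² I)

and the joint predictive density `log p(y_Q | y_S)` in closed form,
which is exactly what the meta-learning objectives differentiate. A
Laplace or EP classification likelihood would break that closure for no
benefit at the scales targeted here. Class probabilities come from
squashing the predictive moments, `p = logistic(μ / √(1 + σ²))`, which
is monotone in the mean, symmetric (μ = 0 gives p = 0.5), and shrinks
confident means toward 0.5 when the variance is large. Scores of this
form are all that AUPRC evaluation consumes.

The base kernel is RBF by default; Matérn-5/2 is available via
`meta_config(kernel = "matern52")`. Both are implemented through one
scalar shape function of `u = d²/ℓ²` so hyperparameter and embedding
gradients share a code path, and both gradients are verified against
finite differences in the test suite.

## The four trainers

**DKL (single-task baseline).** `train_dkl` minimizes the NLML of one
dataset jointly over `(θ_NN, θ_GP)` with Adam, mini-batched above 512
rows. With `identity_extractor = TRUE` it reduces to plain GP
hyperparameter estimation; the test suite uses that mode to confirm
that known lengthscale and noise values are recovered from
GP-simulated data (n = 512) within 20% and 30% respectively.

**DKT.** One shared `(θ_NN, θ_GP)` minimizes the *expected* NLML over
episodes: each outer iteration samples a batch of 5 tasks, draws a
support/query episode per task, and averages the NLML of the pooled
episode rows. No adaptation happens at meta-test time; the shared deep
kernel simply conditions on the support set. An ambiguity worth
recording: the expected-NLML objective could be read as "per-task NLML
on all task data" or "NLML on the sampled episode"; we use the pooled
support∪query rows of the sampled episode, which coincides with the
former in expectation and with the single-task DKL objective when all
tasks are identical (a reduction the tests check exactly).

**ADKF.** A bilevel scheme. Inner loop: `adapt_gp` minimizes the
support-set NLML over `θ_GP` only (gradient descent with backtracking,
50 steps by default, early stop when the improvement falls below 1e−5).
Outer loop: `θ_NN` is meta-learned by minimizing
`−log p(y_Q | y_S)` at the adapted `θ_GP*`, computed through the chain
rule `log p(y_Q|y_S) = log p(y_{S∪Q}) − log p(y_S)` so one NLML
gradient routine serves everything. Outer gradients are **first-order**:
the inner solution is treated as a constant. An implicit-function-
theorem correction is a documented possibility we chose not to
implement: at the network sizes used here the first-order estimator is
stable and cheap, and the exact Hessian solves it would require grow
quadratically in the weight count. The inner loop's `θ_GP`
initialization is a fixed configuration value (`theta_gp_init`), not a
meta-learned quantity — the simplest reading of the method, and the one
that keeps ADKF's meta-parameters to `θ_NN` alone.

**ADKF-prior.** The extractor gets a Gaussian prior
`θ_NN ~ N(φ, σ² I)` with isotropic, scalar `σ²` learned in log-space.
The inner loop is MAP adaptation of the *whole* deep kernel:

    minimize over (θ_GP, θ_NN):  NLML(S) + ‖θ_NN − φ‖² / (2σ²).

We optimize in the **non-centred parameterization** `θ_NN = φ + σu`
with penalty `‖u‖²/2`, starting at `u = 0`. This has two virtues. It
makes the σ² → 0 limit exact rather than approximate: the `u`
coordinates freeze and the optimization collapses to `adapt_gp` at
`θ_NN = φ` step-for-step (a reduction the tests assert to 1e−4 on query
loss). And it gives the outer loop honest first-order gradients for
*both* meta-parameters through `θ_NN* = φ + σu*`: holding the inner
solution `(θ_GP*, u*)` fixed,

    ∂loss/∂φ = g,   ∂loss/∂log σ² = (σ/2) · u*ᵀ g,

where `g` is the query-loss gradient with respect to the adapted
extractor weights. The σ² gradient has the right fixed-point behaviour:
it grows the prior variance while extractor adaptation keeps helping
the query loss and shrinks it when adaptation starts to hurt
(overfitting). `log σ²` is clamped to [−12, 3] as a guard rail. The
prior mean φ is freshly initialized by default; `init_nn` accepts a
warm start (e.g. a trained ADKF extractor) for staged training.

**Prototypical network.** The metric-based baseline: class prototypes
are the mean support embeddings per class, queries are classified by a
softmax over negative squared Euclidean distances (the convention of
the original method; the distance is a genuine choice since only
"nearest prototype" is specified). Training is episodic cross-entropy;
support draws are stratified so both prototypes always exist.

**Meta-testing.** `meta_test` repeats, per support size: sample a
support/query episode, adapt according to the method (DKT/DKL none,
ADKF `adapt_gp`, ADKF-prior `adapt_prior`, protonet prototypes), score
the query set, compute AUPRC. Support draws are stratified by class by
default — with supports as small as 5 an unstratified draw is often
single-class, which would make GP adaptation degenerate and prototype
computation impossible; the evaluation protocol in the field leaves
this unstated, so stratification is our recorded choice.

## Featurization

Each reaction maps to a fixed 1544-vector:

| block | width | content |
|---|---|---|
| olefin, ligand, solvent fingerprints | 3 × 512 | circular (radius-2) fingerprints |
| metal one-hot | 3 | Ir, Rh, Ru |
| additive one-hot | 2 | absent / present |
| conditions | 3 | temperature (°C), pressure (bar), loading (mol%) |

The 3 + 2 + 3 decomposition of the eight non-fingerprint dimensions is
a reconstruction — only the total is fixed — and unknown metal
categories are rejected rather than bucketed, so featurization failures
are loud. Circular fingerprints are computed by OpenBabel (ECFP4,
radius 2) on canonicalized SMILES and folded from the native 4096 bits
to 512 by OR-ing bit `i` into slot `i mod 512`; MACCS keys come from
the same backend, truncated from the padded 256-bit register to the
canonical 166. The test suite validates popcounts and Tanimoto
similarities against the independent `obabel` command-line tool.
Condition scalars are z-standardized with statistics fit on training
rows only (`fit_condition_scaler`): raw bar/°C magnitudes would
otherwise dominate every distance computed on the binary blocks.
Whether the original protocol scaled them is unrecorded; leaving them
raw is available by passing `scaler = NULL`.

## Task protocols

*Random splits*: rows are shuffled 80:20 into train/test pools, each
pool chunked into disjoint tasks of a target size (the last chunk
absorbs the remainder so every row is used exactly once); 10% of the
training tasks become validation tasks. *Substrate splits*: unique
substrates (deduplicated by fingerprint) are embedded from Jaccard
dissimilarities of their MACCS keys into 2-D and k-means clustered
(six clusters by default); a leave-one-cluster-out plan holds each
cluster out once, so test substrates never occur in training. The 2-D
embedding is nonmetric multidimensional scaling — the nonlinear
manifold embedding available in the R ecosystem used here; principal
coordinates (`method = "pcoa"`) is the deterministic fallback. The
embedding step is stochastic, its seed is fixed, the fitted coordinates
are attached to the labels for audit, and reproducing any particular
published clustering is explicitly not a goal. *Time splits*: train on
rows up to 2020, test on rows from 2023 onward, with the gap rows
excluded and counted.

Meta-training episodes default to support 512 / query 64 in batches of
five tasks; meta-testing uses small supports (5–128) with query 128 and
10–30 resampling repeats. The train/test size mismatch is deliberate
and mirrors the evaluation protocol this package implements.

## The synthetic task generator

`generate_tasks` emulates the statistical skeleton the meta-learners
assume: sparse binary fingerprint-like features (Bernoulli on-rate 0.1)
plus three standard-normal condition columns; a shared weight vector
`w` with per-task perturbations `w_t = w + shift·ε_t` so tasks are
related but not identical; labels drawn through a logistic link of the
standardized per-task score with the intercept solved so the expected
positive fraction hits the target prevalence (0.65/0.35 by default,
the imbalance of the motivating corpus). `noise_scale` is the logistic
temperature: 0 makes labels a deterministic threshold of the latent
score (the true weights then achieve AUPRC 1, a generator sanity check
in the tests), larger values make tasks noisier. Tasks that draw a
single class are re-balanced by flipping the most extreme example so
every task supports stratified adaptation.

What the generator does *not* emulate: real fingerprint bit
correlations (substructures co-occur; Bernoulli bits don't), the
clustered substrate topology that makes leave-one-cluster-out splits
hard, label noise that correlates with reaction families, and the
long-tailed frequency of olefin–ligand combinations. Tests passing on
this suite therefore establish that the algorithms optimize what they
claim to optimize and that adaptation extracts task-specific signal —
they do not certify performance numbers on any real reaction corpus.

The bundled study conditions for the acceptance checks are 13 tasks ×
300 rows with 48 binary + 3 condition features (8 train / 2 validation
/ 3 test tasks) and meta-training episodes of support 64 / query 32 —
a scaled-down instance of the full protocol chosen so the whole
training-plus-evaluation cycle completes in about a minute; the
extractor is 24 hidden units to an 8-dimensional latent accordingly.

## Numerical choices

- **Cholesky everywhere**: solves and log-determinants go through one
  factorization; `log p(y_Q|y_S)` is also computed directly from the
  conditional mean/covariance, and the chain-rule identity against two
  NLML evaluations is asserted to 1e−8 over random instances.
- **Jitter escalation**: when a covariance fails to factor, a jitter of
  1e−6 × signal variance is added to the diagonal and escalated ×10 at
  most three times before a conditioning diagnostic aborts.
- **Inner loops**: plain gradient descent with backtracking halving
  (never accepts an increase, so adapted loss ≤ initial loss is an
  invariant, not a hope), early stop on improvement < 1e−5, step regrown
  ×2 after acceptance up to its initial value.
- **Outer loops**: Adam with per-task-batch averaged gradients; losses
  are normalized per data point (DKT) or per query point (ADKF,
  ADKF-prior) so learning rates transfer across episode sizes.
- **Degenerate inputs**: single-class supports are permitted for GP
  adaptation (regression on a constant vector) but flagged; stratified
  samplers refuse single-class tasks; empty supports fall back to the
  GP prior; AUPRC refuses label vectors without positives; predictive
  variances are floored at 1e−12.
- **Determinism**: every stochastic routine takes a seed and restores
  the caller's RNG state; trainers derive distinct child seeds for
  initialization and episode sampling, and repeated runs are asserted
  bit-identical in the tests.

## Known limitations

- GP costs are cubic in episode size; the implementation is dense and
  aimed at episodes up to a few hundred points, not at sparse or
  inducing-point approximations.
- First-order outer gradients bias the meta-update when the inner loop
  is far from converged; we mitigate with backtracking and early
  stopping rather than implementing the implicit-function-theorem
  correction.
- On the bundled synthetic suite, ADKF-prior does **not** reproduce a
  few-shot advantage over ADKF at support size 5 (the paired comparison
  the acceptance suite runs): with a well-calibrated small prior
  variance (σ² ≈ 0.01 after training) the extractor barely moves on
  five support points, so the two methods nearly coincide there, and
  the generator's between-task differences — weight-vector
  perturbations — are not estimable from five examples anyway.
  ADKF-prior does outperform ADKF on validation-size episodes in the
  same runs, so the machinery itself trains correctly; the few-shot
  claim is simply a property this synthetic world does not exhibit.
- The two fingerprint backends in circulation (OpenBabel here, RDKit
  elsewhere) implement the same circular-fingerprint idea with
  different hashing, so absolute bit patterns — and models trained on
  them — are backend-specific even though both are internally
  deterministic and spelling-invariant.
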