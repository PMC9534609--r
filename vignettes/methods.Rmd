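---
title: "Squirrel-search feature selection and hybrid CNN-LSTM classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Squirrel-search feature selection and hybrid CNN-LSTM classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiofs` implements a complete wrapper feature-selection and
classification pipeline for clinical tabular data of the Cleveland
heart-disease shape: an n x d numeric table with a binary
presence/absence outcome, missing cells, and a minority of genuinely
informative features. This vignette explains the models and procedures,
the parameters that matter, the numerical choices made where the design
was open, and what the synthetic-data experiments do and do not show.

## Preprocessing

Three steps, in order:

1. **Imputation.** Missing cells are replaced by the per-feature median
   of the observed cells (mean available via
   `preprocess_config(missing_strategy = "mean")`). The median is the
   default because it is robust to the same outliers the next step
   hunts, and because a single statistic per feature keeps the step
   label-blind. A feature with no observed cells is an error, not a
   guess.
2. **Studentized-residual noise repair.** For each feature j we regress
   feature j on the remaining features by least squares and compute
   externally studentized residuals (`stats::rstudent`). Cells with
   |residual| above the threshold (default 3.0, a conventional cutoff
   for externally studentized residuals) are replaced by the feature
   median. We repair cells rather than delete rows so the sample size
   is preserved and pooled confusion matrices always cover all n
   instances. When a regression design is singular (e.g. duplicated
   features) the residual falls back to the robust
   (value − median)/MAD form, with a logged notice.
3. **Min-max normalization** onto [0, 1] per feature; constant features
   map to 0. The unit interval matches the optimizer's search box, so
   positions and feature values live on the same scale. The fitted
   per-feature minima/maxima are retained
   (`attr(x, "norm_params")`) and can be applied to held-out data with
   `apply_normalization()`; the evaluation harness refits them on
   training folds only, so no information leaks from test folds.

All three steps ignore the labels; permuting the outcome leaves the
transformed feature matrix unchanged (this is tested).

## The squirrel search optimizer

The squirrel search algorithm (SSA) is a continuous population
metaheuristic. N squirrels hold positions in a bounded box; after each
fitness evaluation the best individual is assigned to the *hickory*
tree, the next `n_acorn` (default 3) to *acorn* trees, and the rest are
*normal*. Acorn squirrels glide toward the hickory squirrel and normal
squirrels toward a uniformly chosen acorn squirrel:

    x <- x + dg * G_c * (target - x)        with probability 1 - P_dp
    x <- uniform in bounds                   otherwise (predator met)

`G_c = 1.9` is the gliding constant and `P_dp = 0.1` the predator
probability. The gliding distance `dg = hg / (tan(phi) * sf)` with
`tan(phi) = C_D / C_L`; with `hg = 8`, `sf = 18`, `C_D = 0.6` and `C_L`
uniform in [0.675, 1.5], `dg` always lies in [0.5, 1.1111] — the
aerodynamic constants (air density, speed, surface) cancel out of the
drag/lift ratio. Because `dg * G_c` can exceed 1 (up to 2.11), glides
can overshoot the target, which is what gives the method its
exploration; out-of-bounds coordinates are clamped to the box.

**Seasonal monitoring.** Each iteration starts in winter. For every
acorn squirrel we compute the seasonal constant — the *squared*
Euclidean distance to the hickory squirrel, exactly as the update
equations print it (a square-root variant is available via
`sc_sqrt = TRUE`) — and compare it with the decaying threshold

    S_min(t) = 1e-5 / 365^(t / (T/2.5)).

The printed form of this threshold is typographically garbled in the
literature this follows; the implementation uses the reading above
(the original SSA formula), isolated in `seasonal_threshold()` so it
can be swapped. When all seasonal constants fall below the threshold,
winter ends: every normal squirrel that did not meet a predator this
iteration is relocated by a Lévy flight,
`lower + levy * (upper - lower)`, clamped. Lévy steps use Mantegna's
algorithm at stability exponent 1.5, where
`sigma(1.5) ≈ 0.6966`; the resulting heavy tails make occasional long
jumps that help leave local basins. The season returns to winter at the
start of the next iteration.

Only the two printed update rules (acorn→hickory, normal→acorn) are
active by default; the original SSA's third rule (a random half of the
normal squirrels gliding straight to the hickory tree) can be enabled
with `include_normal_to_hickory = TRUE`.

**Elitism.** The best-so-far position and cost are tracked outside the
population, so the reported trace is non-increasing by construction
even though individual squirrels routinely get worse.

## Elite opposition-based learning (EOBL)

Once per iteration — after the gliding updates, before roles are
re-ranked — the current best individual `x_e` is reflected through the
population's dynamic per-dimension bounds `[da_j, db_j]`
(the min/max coordinate over the current population):

    opp[i, j] = eta * (da_j + db_j) - x_e[j]

One `eta ~ U(0, 1)` is drawn per individual per dimension. The
reflection depends only on the elite and the bounds, so without
per-draw coefficients all opposition individuals would collapse onto a
single point; the per-cell draw keeps the opposition population
diverse, which is the operator's purpose. Coordinates that leave the
dynamic box are reset uniformly inside it. The union of the current and
opposition populations is then greedily truncated back to N by fitness.
Greedy union selection means EOBL can never worsen the population best;
the paired sphere experiment in the test suite confirms it helps on
average. `eobl_config(enabled = FALSE)` gives the plain SSA for
ablation.

## Wrapper feature selection

Feature selection runs the EO-SSA over `[0, 1]^d`. A position is
decoded by the threshold rule *select feature j iff coordinate j >
0.5*; if nothing clears the threshold the largest coordinate is
selected (lowest index on ties), so subsets are never empty. The cost
of a subset Y out of d features is

    cost(Y) = alpha * err(Y) + (1 - alpha) * |Y| / d

where `err(Y)` is the pooled misclassification rate of a k-nearest-
neighbour classifier (k = 5) under stratified 10-fold cross-validation
on the masked feature matrix. Both terms lie in [0, 1], so the cost
does too. `alpha = 0.99` keeps the error term dominant and the subset
size a tie-breaker, the dominant convention for this fitness form; at
`alpha = 0` the optimizer provably drives the subset to a single
feature. k-NN is the search-time wrapper because the fitness is
evaluated thousands of times; the trained deep classifier is applied
once, after selection. The fold assignment is frozen from the fitness
seed, so the cost is a deterministic function of the mask, and costs
are memoized per mask (many continuous positions decode to the same
subset). For d ≤ 20, `best_subset_exhaustive()` enumerates all
non-empty subsets and serves as the oracle the optimizer is tested
against.

## The four-channel attention CNN-LSTM

For tabular input the "sequence" is the list of m selected features:
feature value `x_j` is linearly embedded as
`x_j * w_j + b_j ∈ R^16`, giving an m-step sequence of embeddings. Four
parallel channels process it; channel k concatenates, along the feature
axis,

* a 1-D convolution (kernel size 2/3/4/5 by channel, 32 filters, same
  padding, ReLU), and
* the hidden-state sequence of an LSTM (hidden size 32) with the
  standard gate equations: candidate `z = tanh(·)`, input/forget/output
  gates sigmoid, `c_t = f * c_{t-1} + i * z`, `h_t = o * tanh(c_t)`.

The two small-kernel channels are convolution-dominant and the two
large-kernel channels context-dominant; each channel's per-step output
is max-pooled over the m steps and the four pooled vectors are
concatenated into the hidden representation h. A soft attention runs
over the first channel's per-step states `h_i = [h'_t; c_t]`: scores
`e_i = v_a' tanh(W_r h_i + b)`, weights by softmax (weights are tested
to lie on the simplex), context = weighted sum. The head is
`softmax(dense([h, context]))`. Channel composition is parallel
throughout, never serial. Two points were genuinely open and are
resolved as follows: the per-step attention state is the concatenation
of hidden and cell state, and the attention context *augments* (is
concatenated with) the pooled channel representation rather than
replacing it.

Everything — batched forward pass, backpropagation through the
attention, the max-pool routing, the convolutions and the LSTM
recurrence, and the Adam optimizer — is implemented in base R with
BLAS-backed matrix operations. The analytic gradients are verified
against central finite differences on a small model (tolerance 1e-4)
in the test suite.

**Training protocol** (none is prescribed by the model itself; these
are field defaults, all configurable): cross-entropy loss, Adam at
learning rate 1e-3, minibatches of 32, at most 200 epochs, dropout 0.2
on the merged representation (inverted dropout, so inference is
deterministic), early stopping on a 15% validation split with patience
20, and — once the epoch count is chosen — a refit from scratch on the
full training data for that many epochs, so no training data is wasted
on the monitor split. All randomness is seeded; identical seeds
reproduce the final parameters bit-exactly.

## Evaluation harness

`confusion()` counts with positive = presence of disease.  `metrics()`
derives sensitivity, specificity, precision, accuracy, F-score and the
Matthews correlation coefficient, reported as percentages; report
rendering rounds half-up to 2 decimals (R's `round()` rounds half to
even, which is not how the reference tables are rendered; the half-up
rule is isolated in one function). Denominator-zero metrics are
returned as `NA` and flagged rather than silently zeroed. The rank AUC
uses the Mann–Whitney midrank formula and is cross-checked against an
all-pairs oracle and against pROC.

`run_iterations()` reads the repeated evaluation protocol as *ten
repeated stratified 10-fold cross-validations with pooled fold
predictions*: each round uses a distinct seed, pools the fold
predictions into one confusion matrix covering all n instances, and
derives one metric row; the report appends the arithmetic mean of each
column, rounded half-up to 2 decimals. The pooled reading is an
interpretation — it is chosen because each reference confusion matrix
covers the full 303 instances, which only pooling reproduces. The fold
classifier is pluggable: k-NN by default (fast, adequate for the metric
machinery), `acnn_lstm_fold_classifier()` for the full deep model.

## The synthetic generator

`generate_clinical()` emulates the Cleveland table's *shape*: n = 303
samples, d = 13 features, binary labels with positive fraction 139/303,
2% missing cells, and k = 4 informative features shifted by 1.5 noise
standard deviations between classes (all configurable). Features are
Gaussian for analytic tractability of the recovery experiments; an
optional categorical mode discretizes a subset of noise features into
small integer codes to mimic the real table's categorical columns. The
planted informative indices are returned for recovery testing, and the
writer emits the same CSV dialect (`"?"` for missing cells) that
`read_cleveland()` parses, so the full pipeline round-trips without any
download.

What passing on this generator shows: the optimizer finds
minimum-cost subsets, recovers planted signal under realistic
signal-to-noise, and the classifier separates what is separable. What
it does not show: behaviour under the real table's mixed
categorical/continuous distributions, its feature correlations (the
generator's features are independent), or its missingness mechanism
(uniform here, structured in practice). Results on real clinical data
therefore need their own validation.

## Problem sizes and numerical choices

The shipped experiments use population 20 with 30–50 iterations for
feature selection (costs are memoized per mask, so the effective
number of wrapper evaluations is the number of distinct masks
visited), 10 seeded repetitions for every stochastic claim, and
classifier training on n = 600 with early stopping; these sizes were
chosen so the full suite runs comfortably on a single CPU while
keeping every stochastic assertion at 10 repetitions. Ties in the
binarization threshold resolve to the lowest index; out-of-bounds
positions clamp; the degenerate all-constant objective, single-step
attention, empty populations, all-missing features and single-class
folds all raise errors or return documented values rather than
propagating NaNs.

## Known limitations

* The optimizer treats the feature-selection problem as continuous and
  thresholds at 0.5; no binary transfer function family is provided.
* Only one opposition variant (elite opposition) is implemented.
* The deep classifier is CPU-only and deliberately compact; it is not
  a general-purpose deep-learning framework.
* `run_iterations()` with the deep classifier trains one model per
  fold per round (100 trainings at the default protocol) and is
  correspondingly slow; the k-NN default exists for exactly that
  reason.
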