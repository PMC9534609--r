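# cardiofs

Wrapper feature selection and hybrid deep classification for clinical
tabular data, built around the Cleveland heart-disease table shape
(303 samples, 13 numeric predictors, a binary presence/absence
outcome, `"?"`-coded missing cells).

The package is for biostatisticians and ML practitioners who want a
complete, reproducible pipeline of this family — preprocessing, subset
search, classification, repeated evaluation — with every component
testable offline against synthetic data.

## What it implements

**EO-SSA feature selection.** The squirrel search algorithm (SSA) is a
continuous population metaheuristic: the best individual occupies the
*hickory* tree, the next three *acorn* trees; acorn squirrels glide
toward the hickory squirrel and normal squirrels toward a random acorn
squirrel,

    x ← x + dg · G_c · (F_h − x),   dg = hg / (tan φ · sf),  tan φ = C_D / C_L,

with relocation to a uniform random position when a predator appears
(probability `P_dp = 0.1`), Lévy-flight relocation at the
winter→summer transition, and elite opposition-based learning (EOBL):
each iteration the elite is reflected through the population's dynamic
bounds, `x̃_j = η(da_j + db_j) − x_e,j`, and the best N of the union
survive. Feature subsets are decoded from `[0,1]^d` positions by a 0.5
threshold and scored with the wrapper fitness

    cost(Y) = α · err(Y) + (1 − α) · |Y| / d,   α = 0.99,

where `err` is the stratified 10-fold CV error of a k-NN wrapper.

**ACNN-LSTM classification.** A four-channel attention CNN-LSTM for
the selected features: each feature value is linearly embedded, four
parallel channels concatenate a 1-D convolution (kernel sizes 2/3/4/5)
with an LSTM hidden sequence, channel outputs are max-pooled and
merged, and a softmax attention over per-step `[hidden; cell]` states
contributes a context vector to the dense softmax head. Forward pass,
backpropagation and Adam are implemented in base R and
finite-difference verified.

**Evaluation.** Pooled-fold confusion matrices, the six standard
metrics (sensitivity, specificity, precision, accuracy, F-score,
Matthews correlation), rank-based AUC, and a repeated stratified-CV
harness producing per-round rows plus their average.

**Synthetic data.** A Cleveland-shaped generator (planted informative
features, injected missingness, the same CSV dialect) so everything
above is testable without downloads, plus the sphere/Rastrigin/
Rosenbrock benchmark objectives for the optimizer.

See `vignettes/methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(cardiofs)

tab <- generate_clinical(synth_config(seed = 42))   # 303 x 13, 4 informative
attr(tab, "informative")
#> [1] 1 6 8 9

proc <- preprocess(tab)   # impute -> studentized repair -> min-max

sel <- select_features(proc,
  ssa_config(n_pop = 20, dim = proc$d, n_iter = 30, seed = 1),
  eobl_config(), fitness_config(seed = 1))
sel$subset
#> feature_subset: 7 of 13 features (indices 1, 2, 3, 6, 7, 8, 9)
round(sel$cost, 4)
#> [1] 0.0805

rep <- run_iterations(proc, subset = sel$subset, n_iterations = 3, seed = 1)
rep$rows
#>             sensitivity specificity precision accuracy f_score   mcc
#> iteration_1       89.63       94.05     92.37    92.08   90.98 83.95
#> iteration_2       92.59       91.07     89.29    91.75   90.91 83.41
#> iteration_3       88.89       94.05     92.31    91.75   90.57 83.29
rep$average
#>   sensitivity specificity precision accuracy f_score   mcc
#> 1       90.37       93.06     91.32    91.86   90.82 83.55
```

The selected subset contains all four planted informative features
(1, 6, 8, 9); the cost 0.0805 combines the wrapper CV error with the
7/13 subset-size penalty. Each evaluation row comes from one stratified
10-fold CV whose fold predictions are pooled into a single confusion
matrix over all 303 instances; the final row is the column mean. For
the deep classifier instead of the default k-NN fold model, pass
`classifier = acnn_lstm_fold_classifier()`.

A thin command-line interface over the same functions ships in
`inst/cli/fshdl.R` (commands `preprocess`, `synth`, `select-features`,
`train-eval`, `bench-optimizer`).

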