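# locodann

Cross-species locomotion feature discovery with an attention-based
domain-adversarial neural network, in pure R.

## The problem

Dopamine deficiency changes how animals move — in humans with Parkinson's
disease, in 6-OHDA-lesioned mice, in *dop-3* mutant worms. The changes are
hidden in locomotion micro-structure, and the species differ by ~100x in
spatial scale and by sampling rate, so no conventional statistic compares
them directly. `locodann` trains a 1D-convolutional classifier on normalized
speed time-series to separate affected (class 1) from unaffected (class 0)
animals pooled from **two species (domains)**, while two domain predictors
behind gradient reversal layers push the learned features and the attention
computation to be species-blind. An attention mechanism

    a = softmax(W_a2 · tanh(W_a1 · Zᵀ))

marks which timesteps drive the classification; surrogate CART trees turn the
attended segments into an if-then rule over interpretable rolling-window
features (rolling min of speed, skewness, ...); and the resulting hypothesis
is tested as an ordinary two-sample comparison (Welch's t or Brunner–Munzel,
selected by a Shapiro–Wilk normality gate) on a derived per-animal statistic.

Training iterates three phases per epoch (class + per-timestep domain
adversary; series-level domain adversary; class + series-level adversary)
with the reversal strength μ ramped from 0 to L over epochs
T₁ = epochs/10 … T₂ = epochs/1.2. Everything — forward pass, backprop through
convolutions, attention, gradient reversal, Adam — is implemented in base R
on BLAS matrix products; there is no torch dependency.

A seeded synthetic cohort generator (two-state speed bout process, planted
class signatures such as speed dips inside high-speed bouts, 100x domain
scale gap plus a genuine bout-duration domain signal) makes the entire
pipeline testable without animal data.

## Worked example

```r
library(locodann)

spec   <- cohort_spec(n_per_cell = 40, seed = 1)   # 160 series, l = 599
cohort <- generate_cohort(spec)
series <- cohort_series(cohort)                    # speed -> resample -> z-score
sp     <- split_dataset(series, 0.2, seed = 1)

fit <- train_dann(sp$train,
                  dann_config(input_len = 599, n_filters = 8,
                              hidden = 16, attn_hidden = 16),
                  train_config(epochs = 60, seed = 1))
ev <- evaluate_dann(fit$model, sp$test)
round(c(class = ev$acc_class, dom1 = ev$acc_dom1, dom2 = ev$acc_dom2), 3)
#> class  dom1  dom2
#> 1.000 0.500 0.534
```

Class is recovered perfectly on held-out series while both domain predictors
sit near chance (0.5): the features that separate affected from unaffected
animals carry almost no species information. Explanation and validation:

```r
labels <- unlist(lapply(seq_along(sp$test), function(i)
  as.character(label_attention(ev$attention[, i]))))
feats  <- do.call(rbind, lapply(sp$test, extract_window_features))
tree_root(fit_attention_tree(feats, labels))
#> $feature
#> [1] "accel"
#>
#> $threshold
#> [1] 0.638572

tree_root(fit_classification_tree(sp$test, ev$attention))
#> $feature
#> [1] "speed_std_w5"
#>
#> $threshold
#> [1] 0.2901688

# bout-scale window (20 steps): it must exceed the planted dip spacing, or
# the dipped windows drop out of the top-20% mean-speed selection
v   <- vapply(sp$test, min_speed_during_high_speed, 0, window = 20)
cls <- vapply(sp$test, function(s) s$class_label, 0L)
select_and_test(v[cls == 0], v[cls == 1])
#> Welch t: stat=6.444, df=22.36, p=1.62e-06, effect=0.806, n=16/16
```

On this run attention mass sits at 0.95 inside the planted fast bouts
(uniform baseline 0.54); the classification tree's root is the rolling
standard deviation of speed — the planted within-bout instability — and the
derived statistic "minimum speed while fast" separates the groups at
p ≈ 2e-6, affected animals lower. Tree roots vary between runs among the
features that express the planted effect (rolling std, skewness, rolling
minimum of speed).

## Command line

```sh
inst/cli/locodann simulate   --config spec.txt --out sim/
inst/cli/locodann preprocess --manifest sim/manifest.tsv --config prep.txt --out series/
inst/cli/locodann train      --series series/ --config train.txt --out run/
inst/cli/locodann explain    --checkpoint run/model.rds --series series/ --out explained/
```

Configs are flat `key: value` text; every command is deterministic given
`--seed`, exits 0/1/2 (ok / runtime failure / usage error), and writes plain
delimited text plus an RDS checkpoint.

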