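# dhtppi

Sequence-based prediction of protein–protein interactions (PPIs) from
evolutionary profiles. `dhtppi` is aimed at computational biologists who
want a self-contained, reproducible R implementation of the
profile → transform → ensemble pipeline that underlies a family of
sequence-only PPI predictors:

1. **PSSM representation.** Each protein is an L × 20 position-specific
   scoring matrix Φ = (φ(m, n)), m = 1…L positions, n = 1…20 amino-acid
   channels, read from PSI-BLAST ASCII output (`parse_psiblast_pssm()`) or
   built as a substitution-matrix pseudo-profile (`pseudo_pssm()`) when no
   PSI-BLAST run is available.
2. **Discrete Hilbert transform (DHT) descriptor.** The 1-D DHT multiplies
   each DFT component by −j·sgn(Ω) (zero at DC and Nyquist), turning
   cosines into sines; the 2-D transform applies it separably along both
   axes of the PSSM. A protein's descriptor is the magnitude spectrum of
   the transformed, zero-padded PSSM restricted to the 10 lowest
   sequence-frequency bins × 20 residue channels (200 values); a pair is
   the 400-dimensional concatenation (`pair_descriptor()`,
   `extract_features()`).
3. **Rotation Forest (RoF) classification.** Each of L trees sees the data
   rotated by its own block-diagonal matrix R, assembled from per-subset
   PCA bases fitted on 75 % bootstrap samples (K random feature subsets,
   all components retained, so RᵀR = I). Class confidence is the mean of
   the tree posteriors, λ(x) = (1/L) Σᵢ dᵢ(x Rᵢ)
   (`rotation_forest()`, `predict_confidence()`).
4. **Evaluation.** Stratified five-fold cross-validation reporting ACC,
   Sen, Spec, PR, MCC (percent convention) and rank-based ROC/AUC per fold
   with mean ± sd (`cv_rotation_forest()`, `write_cv_report()`).

A planted-signal synthetic generator (`gen_ppi_dataset()`) emulates the
balanced benchmark construction — positive pairs share an injected
conservation motif in PSSM space — so the entire pipeline is testable with
a known, tunable effect size and no external databases.

## Worked example

Generate a weak-signal benchmark (50 interacting and 50 non-interacting
pairs, motif strength 0.5, noise sd 1), featurize it, and cross-validate:

```r
library(dhtppi)

spec <- synthetic_spec(n_pos = 50, n_neg = 50,
                       signal_strength = 0.5, noise_sd = 1, seed = 7)
dataset  <- gen_ppi_dataset(spec)
features <- extract_features(dataset$pairs, dataset$pssms)
dim(features)
#> [1] 100 403        # id_a, id_b, label + 400 descriptor columns

cv <- cv_rotation_forest(features, k = 5, trees = 30, subsets = 20, seed = 7)
cv
#> <ppi_cv> 5-fold cross-validation, n = 100, 30 trees, seed 7
#>   ACC 73.00 +/- 2.74%  Sen 72.00%  Spec 74.00%  PR 74.58%  MCC 46.75%  AUC 0.7940

tidy(cv)[, c("fold", "tp", "fp", "tn", "fn", "acc", "mcc_pct", "auc")]
#> # A tibble: 5 × 8
#>    fold    tp    fp    tn    fn   acc mcc_pct   auc
#>   <int> <int> <int> <int> <int> <dbl>   <dbl> <dbl>
#> 1     1     7     2     8     3    75    50.3 0.765
#> 2     2     7     3     7     3    70    40   0.765
#> 3     3     8     4     6     2    70    40.8 0.735
#> 4     4     6     1     9     4    75    52.4 0.865
#> 5     5     8     3     7     2    75    50.3 0.84
```

Each fold row is the held-out confusion table (class 1 = interacting) with
its derived metrics: at this signal strength the descriptor separates the
classes well above chance (AUC ≈ 0.79) but far from perfectly. Raising
`signal_strength` to the benchmark default of 3 drives the same pipeline
to AUC ≈ 1.0, and setting it to 0 collapses performance to chance
(AUC ≈ 0.49) — the planted-signal control. `autoplot(cv)` draws the
per-fold ROC curves; `glance(cv)` returns the mean ± sd summary row;
`write_cv_report(cv, dir)` writes the fold table and ROC points with a
config/seed stamp.

A thin command-line interface over the same functions is installed at
`exec/dhtppi` (`synth`, `extract`, `train`, `predict`, `cv` subcommands)
for shell pipelines.

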