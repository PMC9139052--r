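---
title: "Hilbert-transform PSSM descriptors and Rotation Forests for PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hilbert-transform PSSM descriptors and Rotation Forests for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhtppi)
```

`dhtppi` predicts whether two proteins interact using nothing but their
sequences. This vignette is the package's account of the method: the model
at each stage, the assumptions it makes, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic benchmark does
and does not establish.

## The modelling problem

High-throughput experimental PPI screens are expensive and noisy, so
sequence-only classifiers are used to triage candidate pairs. The pipeline
here has three stages: an evolutionary profile per protein, a fixed-length
spectral descriptor per pair, and an ensemble classifier with
cross-validated evaluation.

## Stage 1: PSSM profiles

A protein of length $L$ is represented by a position-specific scoring
matrix $\Phi \in \mathbb{R}^{L \times 20}$: $\phi(m, n)$ scores amino acid
$n$ at position $m$, with large values marking evolutionarily conserved
positions. Profiles are normally produced by PSI-BLAST (three iterations,
e-value 0.001 is the conventional setting for this task; the database
version is the user's choice and should be recorded). The parser
(`parse_psiblast_pssm()`) takes the **first** 20-column block of the ASCII
output — the integer log-odds scores, the field convention — and reorders
columns from the file's header order to the fixed alphabet
`ARNDCQEGHILKMFPSTWYV` so all downstream linear algebra is order-stable.

Because a PSI-BLAST run is heavyweight, `pseudo_pssm()` offers a fallback:
row $m$ is the BLOSUM62 (or PAM250) substitution row of the residue at
position $m$. It encodes residue identity, not alignment-derived
conservation, and is what the synthetic generator builds on. Non-standard
residues (X, B, Z, U) get an all-zero row — no information is invented;
rows parsed from files are kept as written. Scores are used raw by
default; an optional elementwise logistic squashing
$1/(1 + e^{-x})$ (`squash_pssm()`) is available but off, since the
transform downstream is linear and scale-equivariant either way.

The standard benchmark constructions drop fragments shorter than 50
residues; `filter_min_length()` applies that filter (redundancy removal at
40 % identity is an external CD-HIT step, out of scope here).

## Stage 2: the discrete Hilbert transform descriptor

The 1-D discrete Hilbert transform of a length-$N$ signal multiplies its
DFT by $-j\,\mathrm{sgn}(\Omega)$: $+1$ on positive-frequency bins, $-1$
on negative ones, $0$ at DC and (even $N$) at Nyquist — the
analytic-signal convention. It maps cosines to sines, annihilates
constants, and applied twice negates any DC/Nyquist-free signal. Two
numerical conventions are enforced rather than assumed:

* the real part is taken only after checking the imaginary residue of the
  inverse DFT is below $10^{-10}$ (relative); anything larger aborts
  instead of being silently dropped;
* the equivalent spatial form — circular convolution with the inverse DFT
  of the multiplier, the discrete periodic analogue of the classical odd
  $1/(a\pi)$-type kernel — is kept as an independent test oracle, never as
  the production path.

The 2-D transform is defined **separably**: the 1-D transform along each
row, then each column (`dht_2d(mode = "total")`; the two orders commute).
A single-formula 2-D frequency mask is sometimes written for this
transform, but its region bounds are not internally consistent in the
sources that print it, whereas the separable form follows directly from
the 1-D theory and admits an exact convolution oracle — so the separable
form is normative here.

**Fixed-length reduction.** Proteins vary in length, classifiers need
fixed dimension. The PSSM is zero-padded along the sequence axis to
`pad_len = 512` rows (longer sequences are truncated there; 512 covers the
bulk of benchmark proteins), transformed, and the modulus of its 2-D DFT
is taken. The descriptor keeps the `block_rows = 10` lowest
sequence-frequency bins across all 20 residue channels — 200 values per
protein, 400 per pair (protein A first; swapping the pair swaps the
halves). Low-order spectral magnitudes summarize the global conservation
profile while being insensitive to *where* along the sequence a conserved
stretch sits, the same rationale as the discrete-cosine-transform
descriptors used elsewhere in this literature. Magnitudes (not signed or
complex coefficients) are used so the descriptor is invariant to circular
shifts introduced by padding; the choice of 10 × 20 is the smallest block
that reproduces the conventional 400-dimensional pair descriptor.

## Stage 3: Rotation Forest

Rotation Forest builds diversity by giving each of $L$ CART trees its own
axis rotation. For tree $i$: the $n$ features are randomly partitioned
into $K$ subsets (sizes $\lfloor n/K \rfloor$, remainder absorbed by the
last); per subset, a bootstrap of $\lceil 0.75 N \rceil$ rows (with
replacement) is drawn and PCA is fitted on those rows restricted to the
subset's columns; **all** components are retained, so each block is a full
orthonormal basis and the assembled block-diagonal matrix $R_i$ satisfies
$R_i^\top R_i = I$ — the rotation re-expresses, never discards,
information. Blocks are rearranged to the original feature order
(the block matrix lives in the permuted basis). Prediction uses mean
combination, $\lambda(x) = \frac{1}{L} \sum_i d_i(x R_i)$, and the class
with the highest confidence; an exact tie goes to the first listed class
(class 0 for 0/1 labels) — documented and tested.

Implementation decisions worth recording:

* **PCA via eigendecomposition of the covariance matrix**, not SVD of the
  data: it always yields a full orthonormal basis even when some
  directions in the bootstrap are degenerate; an entirely constant block
  falls back to the identity with a message, never a failure.
* **Sign convention**: each component's largest-magnitude loading is made
  positive, so rotations (and therefore models and predictions) are
  reproducible across runs and platforms.
* **`bootstrap_frac = 1` means the full sample, unresampled.** This gives
  a well-defined deterministic limit in which the $K = 1$ rotation is
  exactly the full-data principal-axes matrix — used as a test oracle
  against an independent SVD route.
* **Base learner**: CART with Gini impurity via `rpart`, grown to purity
  (`minsplit = 2`, `cp = 0`), the standard choice when the ensemble, not
  the tree, provides regularization.
* **Plain object bootstrap.** The original Rotation Forest also eliminates
  a random subset of classes before sampling; with two classes that step
  is degenerate, so it is omitted.
* **Defaults $L = 30$, $K = 20$**: these parameters require tuning in
  general and published tables rarely pin them down; $K = 20$ divides the
  400-feature descriptor into even subsets of 20 and $L = 30$ is past the
  point where held-out AUC plateaus on the synthetic benchmark. Both are
  arguments everywhere, including the CLI.

## Evaluation protocol

`cv_rotation_forest()` uses stratified $k$-fold cross-validation
(default $k = 5$): within each class a random permutation is dealt
round-robin into folds, so both classes appear in every training split —
a guarantee the plain "random split" description does not give, and
harmless for balanced designs. Per fold it reports ACC, Sen, Spec, PR
(percent), MCC (both the natural $[-1, 1]$ value and the ×100 convention
used in PPI benchmark tables, labelled `mcc` / `mcc_pct`), and rank-based
AUC (midranks for ties; equal to trapezoidal integration of the ROC
curve, and to the probability a random positive outscores a random
negative). The MCC denominator is the standard
$\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}$. Any $0/0$ metric is reported as
`NA`, never silently 0. The summary row is the across-fold mean with the
sample ($n-1$) standard deviation. Reports (`write_cv_report()`) mirror
the conventional fold-table layout with an `Average  mean ± sd` row, and
every artifact embeds the seed and a hash of the configuration.

## The synthetic benchmark: what it shows and what it does not

`gen_ppi_dataset()` emulates the balanced benchmark construction with a
plantable effect: one dataset-level *motif* (20 i.i.d. standard-normal
channel offsets) is added, scaled by `signal_strength`, over a contiguous
window of `motif_len = 20` PSSM rows in **both** members of every positive
pair; negative-pair proteins carry no motif; i.i.d. Gaussian noise
(`noise_sd`, default 1) is added everywhere. Each protein appears in
exactly one pair. Choices made once, on domain grounds:

* the signal is planted in **PSSM space**, not sequence space, because
  that is where the discriminative evolutionary information enters this
  pipeline — it directly exercises whether the DHT reduction carries
  conservation signal;
* the motif window is placed **uniformly at random per protein**, so only
  a position-robust descriptor (the low-frequency magnitude block) can
  recover it — a deliberately adversarial placement for the reduction;
* motif entries are unit-scale normals and the window is 20 rows, so
  `signal_strength` is interpretable as a per-entry signal-to-noise ratio
  against `noise_sd = 1`;
* sequence lengths are uniform on [50, 150] — above the benchmark fragment
  filter, around the scale of small globular proteins, and cheap to
  simulate.

At the benchmark conditions (500 + 500 pairs, strength 3, noise 1) the
full pipeline reaches five-fold CV AUC ≈ 1.0; at strength 0 the classes
are exchangeable by construction and AUC sits at chance (≈ 0.49 at these
sizes). The test suite checks both, plus monotonicity of class separation
in signal strength and the ensemble-versus-single-tree comparison, at
problem sizes (1000 pairs for the benchmark, tens of pairs for plumbing
checks) chosen to keep the default suite fast.

What passing these tests does **not** show: real PPI data has homology
structure between proteins, unbalanced and false-negative-contaminated
negative sets, length- and composition-dependent PSSM statistics, and
interaction signals that are not a single shared additive motif. Synthetic
recovery establishes that the implementation is correct and that the
descriptor can transmit a conservation-shaped signal through to the
classifier — not that any particular accuracy will be achieved on DIP-,
HPRD- or PRIN-derived datasets, which additionally require PSI-BLAST
profile generation against an external database.

## Degenerate inputs and edge conventions

* PSSMs must have ≥ 2 positions for the transform; length-1 signals are
  rejected.
* An all-zero PSSM yields an all-zero descriptor (the transform is
  linear).
* Parsed PSSM rows with fewer than 20 scores abort with the line number.
* `partition_features(n, K)` requires $K \le n$; $K = 1$ is the identity
  partition.
* Single-class training labels abort; prediction on mismatched feature
  dimension aborts naming both dimensions.
* One seed controls everything: sequence generation, motif placement,
  noise, partitions, bootstraps and fold splits; per-fold fits derive
  independent sub-seeds so any single fold can be reproduced in isolation.
  Two runs with the same configuration are byte-identical down to the
  written artifacts.

## Known limitations

* The pseudo-PSSM is a profile *stand-in*: it cannot exceed the
  information content of the raw sequence, and results with it should be
  read as pipeline checks, not biological predictions.
* Sequences longer than `pad_len` (512) are truncated; raise `pad_len`
  (any value ≥ the longest protein; powers of two are marginally faster)
  for long multidomain proteins.
* The classifier is strictly binary; multiclass rotation forests,
  probability calibration, and baseline classifier comparisons are out of
  scope.
* `rpart` trees grown to purity on 400 correlated features are the
  runtime bottleneck; fitting 30 trees on 800 × 400 data takes a few
  seconds per fold on one CPU.
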