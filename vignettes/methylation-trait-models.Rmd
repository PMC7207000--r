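---
title: "Modelling plant traits from CpG methylomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plant traits from CpG methylomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`epitrait` implements an epigenome-based trait-estimation pipeline for
whole-genome bisulphite sequencing (WGBS) data: per-cytosine CpG reports are
filtered and assembled into a sample × CpG intensity matrix; differentially
methylated cytosines are selected by per-site Welch tests with
Benjamini–Hochberg false-discovery-rate control; regularized two-hidden-layer
feed-forward neural networks are trained under sevenfold cross-validation to
classify categorical attributes (tissue of origin, provenance) or estimate
quantitative traits (biomass, wood properties); and fitted models are
interpreted through weight-based variable importance, backward feature
elimination and methylation-response curves. A synthetic methylome generator
with planted effects makes every stage testable without sequencing data.

This vignette documents the statistical model behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable convention exists.

# From cytosine reports to the intensity matrix

The input dialect is the Bismark-style cytosine report: a headerless TSV of
chromosome, 1-based position, strand, methylated read count, unmethylated
read count, context and trinucleotide. Only CpG-context cytosines are
modelled. Because the CpG dyad is palindromic, calls from the plus-strand
cytosine at position *p* and the minus-strand cytosine at *p + 1* interrogate
the same site; `merge_strand_symmetric()` sums their counts into one record
addressed by the plus-strand coordinate (the `Chr05.8103103` naming style).
Merging makes every input to the network comparable — strand-specific CpG
would otherwise carry half the coverage of symmetric ones.

Methylation intensity is the percentage of reads calling methylated,
`100 * meth / (meth + unmeth)`. Sites covered by fewer than 10 reads within a
sample are treated as missing (`min_coverage = 10`; a site with exactly 10
reads is kept). The matrix is assembled over the **union** of positions across
samples, so a site absent from one methylome remains in the universe and is
simply missing there — mirroring real data where a few percent of a fixed CpG
universe is unobserved per sample.

Missing entries are imputed as the mean of the observed intensities at the
same position, and — critically — training and test sets are imputed by
**separate** calls so that no test-set statistic reaches the training data.
The same discipline applies to feature selection and input standardization;
the pipeline records the sample set behind every statistic in an audit log
that `leakage_audit()` checks mechanically.

# Differential methylation and feature selection

Per-CpG group differences are tested with Welch's unequal-variance *t*
statistic with Welch–Satterthwaite degrees of freedom, vectorized across
columns, and adjusted by the Benjamini–Hochberg step-up procedure (via
`stats::p.adjust`). Sites with zero variance in both groups have an undefined
statistic; they are skipped with a warning and excluded from the FDR family,
whose size is reported.

Selection strategies mirror practice:

* `select_by_significance()` keeps sites with `p <= alpha` (default 0.01) and
  `q` below a cutoff, ordered by ascending `q`, then `p`, then position id
  (a deterministic tie-break).
* `select_to_count()` searches the `q` cutoff so that a target count of
  sites (e.g. "8000 ± 100") is selected; the cutoff found is reported. With
  heavily tied `q` values an exact target may be unattainable, in which case
  the error names the nearest achievable counts.
* `pooled_selection()` unions the top-k sites of several tests (e.g. 500
  from a one-vs-rest comparison plus 100 from a pairwise one), dropping
  duplicates.
* `random_selection()` draws control features uniformly; control models are
  the package's negative baseline.
* For quantitative traits, training **trees** are dichotomized at the mean
  trait value and the high/low methylome groups are compared. Values exactly
  at the mean join the low group, because the high group is defined by
  strictly exceeding the mean.

# The network model

All models are feed-forward networks with exactly two fully connected hidden
layers. Inputs are standardized per feature (zero mean, unit variance, fitted
on the training portion only) since raw intensities span 0–100. The output
layer is softmax for classification and a single linear neuron for
regression. Supported hidden activations:

* `tanh`;
* `rectifier` (`max(0, z)`);
* `maxout`: each unit takes the maximum over two linear channels (channel
  count configurable); weights therefore carry a channel dimension.

Training minimizes mean cross-entropy (probabilities clipped at `1e-15`) or
mean squared error, plus `l1 * sum(|W|) + l2 * sum(W^2)` over all weight
matrices (biases unpenalized). Hyperparameter ranges enforced by
`network_spec()` are those a practical grid would cover: 4–400 neurons per
layer, `l1` in 0 or [5e-6, 5e-4], `l2` in 0 or [5e-7, 5e-5], dropout 0–50%
at the input and hidden layers, and 200–600 epochs.

Optimization is single-threaded minibatch SGD with Nesterov momentum
(look-ahead-free formulation) and a polynomially annealed learning rate
`rate / (1 + rate_annealing * t)`. A parallel asynchronous SGD would train
faster but is not reproducible run-to-run; determinism under a fixed seed is
a hard requirement for the test suite, so all stochastic stages (weight
initialization, minibatch order, dropout masks, fold assignment) derive from
the spec seed. Defaults (`rate = 0.02`, `rate_annealing = 1e-4`,
`momentum = 0.9`, `minibatch = 8`) were chosen once as values that solve the
package's reference problems (a separable toy, noiseless linear regression)
comfortably within the epoch budget; they are declared in the spec object,
not hidden constants. Dropout is *inverted* (mask scaled by `1/(1-p)` at
training time) so inference needs no rescaling. Training loss is recorded
once per epoch; a non-finite loss aborts with advice to lower the learning
rate.

Gradients are computed by backpropagation, including the L1 subgradient, the
L2 gradient, the dropout masks, and the argmax routing of maxout channels.
The test suite verifies them against central finite differences to a maximum
relative error below `1e-5` for every activation and both tasks.

## Cross-validation and grid search

Model quality is estimated by k-fold cross-validation (default sevenfold:
each model trains on ~86% of the training data and 14% is held out).
Classification folds are stratified; fold sizes differ by at most one (72
samples give folds of 10, 10, 10, 10, 10, 11, 11). Holdout predictions are
pooled and all metrics are computed on the pooled set, so they are exactly
recomputable from the stored predictions. `grid_search()` evaluates an
exhaustive, user-declared grid (optionally subsampled under a budget),
scores by cross-validated log loss (classification) or MSE (regression),
breaks ties toward smaller networks and then lexicographically, and refits
the winner on the full training set.

Reported metrics are misclassification rate, log loss, MSE, r², and adjusted
r². The adjustment uses one predictor (`1 - (1 - r2)(n - 1)/(n - 2)`): the
adjusted coefficient describes the prediction-versus-observation regression,
not the network's input count — with thousands of inputs an input-count
adjustment would be meaningless at n ≈ 70.

# Interpretation

**Variable importance** follows the two-hidden-layer magnitude formulation:
`P1[i,j] = |W1[i,j]| / sum_i' |W1[i',j]|`, `P2[j,k]` likewise, and the raw
importance of input *i* is `sum_jk P1[i,j] P2[j,k]`, normalized to sum to
one. Propagation stops at the second hidden layer by default (that is the
two-hidden-layer formulation); `through_output = TRUE` extends through the
output weights as a sensitivity check. For maxout, `|W|` is the channel-wise
maximum magnitude. The score is invariant to positive rescaling of any
layer's weights.

**Backward elimination** retrains a full hyperparameter search at every
schedule step and keeps the top-m inputs by the current best model's
importance — the search is repeated rather than reusing the previous winning
spec, because the best architecture at 8400 inputs need not be best at 14.
Both explicit schedules (8400, 4000, 1500, ..., 14, 12) and fractional rules
(5% per step via `elimination_schedule()`) are supported.

**Methylation-response curves** implement the Profile method of sensitivity
analysis: for each input CpG, its value is set to each of 99 empirical
quantiles (0.01–0.99) of its training distribution, while all background
inputs co-move jointly through their own 99 quantiles, giving
99 × 99 = 9801 input vectors per cytosine (137,214 for a 14-input model).
Joint background movement is forced by that arithmetic: independently
permuted backgrounds would yield 99^(p−1) settings, not 99. Quantiles use
the linear-interpolation definition (type 7) on raw percentages; vectors are
standardized inside the forward pass. Constant input columns collapse to a
single quantile; their curves are still produced and flagged.

# The synthetic methylome generator

The generator exists so that every downstream stage can be validated against
a known ground truth. It emulates the statistical structure of a two-garden
common-garden WGBS study:

* **Design**: `n_provenances` (default 9, named with the field study's
  three-letter codes) × `genotypes_per_provenance` (2) × two sites (IH, PA)
  × two tissues (X = xylem, L = leaf) — 72 methylomes by default, with
  sample names in the `POR12IHX` convention so that name parsing is
  exercised.
* **Baseline**: each CpG draws a latent methylation proportion from a
  two-component beta mixture (modes 5% and 85%, precision 20, 70% weight on
  the low mode) — the bimodal distribution characteristic of plant CpG
  methylation.
* **Planted effects**: disjoint CpG sets carry a tissue effect (default 25
  percentage points between tissues), a provenance effect (provenances
  ordered along a fixed sequence, 6 points per step — emulating the
  "ordered class sequence" phenomenon that classification models exploit),
  and a trait effect. Effects stated in points are converted to the logit
  offset equivalent to that shift at 50% methylation and applied on the
  logit of the baseline, with the result clipped to [0.001, 0.999]. This
  keeps proportions valid, at the cost that a shift planted on a CpG whose
  baseline sits near 0% or 100% is compressed by the unit interval — such
  CpG are genuinely harder to detect, which is why recovery tests require
  90% (not 100%) of planted sites to outrank the null background.
* **Trait model**: trees (genotype × site units) carry a latent factor
  `u ~ N(0,1)` that loads on the trait CpG (1.0 logit units by default);
  the quantitative trait is a linear combination of the tree-level causal
  latent methylation (0.4 trait units per percentage point around a baseline
  of 11.4) plus Gaussian noise (sd 1). Setting `trait_tissue = "X"`
  expresses the causal methylation only in xylem methylomes, which creates
  the tissue-specificity contrast used to probe cross-tissue transfer.
* **Biological noise**: every (sample, CpG) cell receives logit-normal
  jitter (`latent_noise_sd = 0.3`), representing between-tree methylation
  variation. Without tree-level variance no trait-associated CpG could be
  discovered by a group test, and null p-value distributions would be
  dominated by count discreteness.
* **Observation model**: coverage is Poisson (mean 30), methylated reads
  are binomial in the latent proportion, intensity is the read fraction.
  Cells under 10 reads or hit by uniform missingness (rate 0.031, matching
  the 3.1% missingness regime of real WGBS matrices) are missing. Poisson
  rather than negative binomial coverage is the simplest model consistent
  with binomial read sampling; overdispersion is deliberately not a default.
* **Determinism**: the full study is bit-identical given the seed, and
  count-level data are retained so cytosine reports can be written and
  re-imported as an exact round trip.

What the generator does **not** emulate: linkage or relatedness between
genotypes, spatially correlated methylation (DMRs), non-CpG contexts,
bisulphite conversion failure, and batch or lane effects. Passing tests
therefore demonstrate that the pipeline recovers planted marginal per-CpG
signal under realistic noise — not that it would overcome correlated
confounding in field data.

# Problem sizes and numerical choices

The reference validation experiment uses 72 methylomes × 20,000 CpG with 200
planted CpG per effect class, a ~200-CpG differential selection, a compact
hyperparameter grid and 200 training epochs; at this size a full
classification-plus-regression run with both random controls completes in
well under a minute, and ten-seed replications of the whole recovery
experiment remain comfortable on a single core. These sizes were chosen as
the smallest at which all planted-signal and control behaviours are stable
across seeds.

Numerical conventions fixed by design: probabilities are clipped at `1e-15`
before logs; per-feature standard deviations of zero are replaced by one
(constant features carry no gradient); weight initialization is uniform with
`sqrt(6 / (fan_in + fan_out))` scaling; sorting ties anywhere in selection
or ranking are broken by ascending p-value and then position id / input
index, so every ordered artifact is reproducible; values exactly at a trait
mean go to the low group; the coverage filter keeps sites at exactly the
threshold (a "fewer than 10 are excluded" reading — the boundary case is
ambiguous in common usage, and the inclusive reading is the one enforced
and tested).

# Known limitations

* Exhaustive grid search is the only tuning strategy; no early stopping or
  Bayesian optimization.
* The networks are exactly two hidden layers — that architecture is a
  premise of the importance computation, not a tunable.
* Importance is magnitude-based; gradient- or Shapley-based attribution is
  out of scope.
* Region-level (DMR) differential methylation, beta-binomial count models
  and covariate adjustment are out of scope; tests are per-CpG Welch only.
* Real WGBS studies carry confounding structure (population stratification,
  batch) that the synthetic validation cannot certify against.
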