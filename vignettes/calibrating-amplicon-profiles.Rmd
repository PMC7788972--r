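---
title: "Calibrating amplicon-predicted functional profiles: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating amplicon-predicted functional profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampcal)
```

## The calibration model

A sample's functional profile is a compositional vector
$K = \{k_1, \dots, k_p\}$ of relative abundances over $p$ molecular
functions (KO terms or any other opaque function identifiers — nothing
in the method depends on the annotation scheme). When the same
specimen is sequenced both by shotgun WGS and by 16S amplicon with
downstream functional prediction, the two profiles disagree
systematically. ampcal models the disagreement **per function** as an
affine map

$$k_i^{WGS} = a_i\, k_i^{16S} + b_i + \varepsilon_i,$$

treats the WGS profile as the gold standard, and estimates
$(a_i, b_i)$ by minimizing the total squared error
$E_i = \tfrac12 \sum_{j=1}^N (a_i x_{ij} + b_i - y_{ij})^2$ over the
$N$ training pairs. The estimate is the classical closed-form
least-squares solution; we compute it in centered form
($a_i = S_{xy}/S_{xx}$ on mean-centered data,
$b_i = \bar y - a_i \bar x$), which is algebraically identical to the
raw-moment formula but numerically stable when abundances span many
orders of magnitude.

Assumptions worth stating explicitly:

* **Linearity per function.** The distortion of each function is
  independent of every other function's abundance and affine in its
  own. This is the simplest model consistent with the strong linear
  correlation observed between platform-specific profiles, and it is
  what makes training with ~15 pairs possible (two parameters per
  function).
* **Protocol stability.** A model is specific to the experimental
  protocol (primer region, DNA extraction, prediction pipeline) of its
  training pairs; transplanting it across protocols is unsupported.
* **Gold standard.** WGS-derived profiles are taken as the target; the
  method corrects amplicon predictions *toward* WGS, it does not model
  WGS error.

## Degenerate functions and calibration edge rules

* **Zero-variance abscissae.** If a function's amplicon abundance is
  identical across all training pairs (almost always: absent from
  every training sample), the slope is unidentifiable. The fit falls
  back to the least-squares-optimal constant predictor — slope 0,
  intercept $\bar y$ — and is flagged `degenerate`. Degeneracy is
  defined as *exactly* zero sample variance; near-zero variance yields
  a legitimate but noisy regression, which is the honest answer.
* **Negative outputs.** An intercept below zero can push a calibrated
  abundance negative; relative abundances are non-negative, so outputs
  are clipped at 0 by default (`clip_negative = FALSE` for
  diagnostics).
* **Renormalization.** Calibrated samples are rescaled to sum to 1 by
  default so outputs stay compositional. Note that renormalization
  interacts with comparisons against *unnormalized* reference tables:
  a constant row-sum factor produces a constant Bray–Curtis offset,
  which is why the noise-free "calibrated distance is zero" identity
  is only exact with renormalization disabled on both sides.
* **Pass-through.** Functions present in a table but absent from the
  model are passed through unchanged and counted (dropping them would
  distort Bray–Curtis comparisons). Functions known to the model but
  absent from a table are never created: applying an intercept to a
  function a sample never exhibited would manufacture abundance from
  nothing.
* **Orientation.** Profile TSVs are accepted functions-as-rows (the
  common export convention, the default) or samples-as-rows, chosen by
  an explicit flag; orientation auto-detection is refused because a
  silently transposed table is a correctness hazard. Profiles are
  normalized on load by default (`normalize = FALSE` to disable).

## Evaluation machinery

* **Bray–Curtis** is implemented directly as
  $\sum_i |u_i - v_i| / \sum_i (u_i + v_i)$ with the degenerate case
  $BC(\mathbf 0, \mathbf 0) = 0$ defined (the test suite cross-checks
  against `vegan::vegdist`).
* **PCoA** is classical metric scaling: double-center $-\tfrac12 D^2$,
  eigendecompose, scale eigenvectors by root eigenvalues. Explained
  fractions are relative to the sum of *positive* eigenvalues. Each
  axis's sign is fixed so its largest-magnitude loading is positive,
  making ordinations deterministic.
* **PERMANOVA $R^2$** uses the standard distance-based partition
  ($SS_{total} = \sum_{i<j} d_{ij}^2 / N$; $SS_{within}$ per group with
  group-size divisors; $R^2 = 1 - SS_{within}/SS_{total}$), with a
  label-permutation p-value (999 permutations by default) under a
  caller-supplied seed. Cross-checked against `vegan::adonis2`.
* **Status classification** emulates search-against-database
  diagnosis with 1-nearest-neighbour under Bray–Curtis on the function
  profiles: each query takes the label of its closest database (WGS)
  profile, ties broken by lexicographically smallest database ID. This
  is an approximation of proprietary microbiome search engines by the
  semantics available from their published use (top-1 match). Derived
  metrics follow the standard confusion formulas; precision/recall are
  reported as `NA`, not 0, when their denominator is empty.
* **Summary spread** uses the sample standard deviation (divisor
  $N-1$) by default, with `sd_divisor = "n"` for the population
  convention.

## The synthetic generator

`simulate_paired_dataset()` emulates the regime in which such
calibration is used, with known ground truth:

1. a shared sparse backbone composition is drawn
   (Dirichlet, $\alpha = 0.4$ per function), so all groups overlap in
   their function universe, as real KO tables do;
2. each group's mean is drawn around the backbone
   (Dirichlet, concentration `group_mean_concentration`);
3. each sample's amplicon profile is drawn around its group mean
   (Dirichlet, concentration `concentration`);
4. one ground-truth $(a_i, b_i)$ per function is drawn
   ($a_i \sim U(\text{slope\_range})$,
   $b_i \sim U(0, \text{intercept\_scale})$) and the WGS profile is
   $a_i x_i + b_i + \mathcal N(0, \text{noise\_sd})$, clipped at 0 and
   (optionally) renormalized.

Distortion is generated amplicon→WGS so the trained model's ground
truth *is* the generating parameter set; generation-side
renormalization breaks exact affinity and is therefore off in recovery
tests and on in realism tests. Dirichlet draws below a detection floor
of $10^{-8}$ relative abundance are set to exactly zero — real
pipelines cannot report one read in $10^8$ either — which keeps every
retained abundance well inside double precision and makes "absent"
exactly zero.

Parameter defaults are the package's standing study conditions, chosen
to reproduce the scale of real paired human-microbiome comparisons:
300 functions; body-site groups gut 40 / oral 40 / skin 25 / vaginal
20 (125 pairs); `concentration = 1000` and
`group_mean_concentration = 50`, which give within-body-site WGS
Bray–Curtis distances around 0.15–0.16 and uncalibrated paired
distances around 0.17–0.20 — i.e. the platform artifact slightly
exceeds within-habitat biological variation, as observed in practice;
slopes $U(0.5, 2)$; intercepts $U(0, 0.001)$; noise sd $5\times10^{-4}$
(about one sixth of the mean abundance $1/300$).

For disease-status experiments the conditions change the way real data
do when moving from "body sites" to "healthy vs gingivitis at one body
site": two groups of 9 paired samples each (plus an unpaired cohort of
40 + 80), much more similar group means
(`group_mean_concentration = 10^5`), tighter clusters
(`concentration = 2\times10^4`), and stronger distortion
(`slope_range = (0.2, 5)`, noise sd $2\times10^{-4}$). Under these
conditions uncalibrated 1-NN classification collapses toward the
majority class (~60% accuracy) because the platform shift dominates
the subtle disease signal, and calibration restores ~95% — the
cross-platform diagnosis phenomenon, reproduced in silico.

`simulate_unpaired_cohort()` draws new amplicon-regime samples from
the same seed-pinned group means without WGS counterparts; relative to
the WGS regime they carry the inverse of the ground-truth distortion,
so calibration moves them toward the WGS regime.

What the generator does **not** emulate: count-level (multinomial)
sampling noise, PCR chimeras or primer bias mechanisms, taxonomic
structure underlying the functional profiles, or function–function
covariance beyond the compositional constraint. Passing tests
therefore demonstrate correctness of the estimator, the pipeline and
the evaluation machinery under the stated generative assumptions — not
that real amplicon data satisfy those assumptions.

## Numerical choices

* Degeneracy threshold: exact zero variance (see above); no epsilon.
* The experiment driver derives one sub-seed per (N, repeat) cell from
  the master seed, so results are reproducible and independent of
  evaluation order; all seeded operations restore the caller's RNG
  state.
* Stratified training selection uses rejection sampling (redraw until
  every group is represented), preserving uniformity conditional on
  coverage; it aborts after 100,000 attempts rather than silently
  biasing the draw.
* PCoA treats eigenvalues below $10^{-12}$ of the largest as zero and
  errors when no positive eigenvalue remains.
* Model files store parameters at 17 significant digits, which
  round-trips doubles exactly.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run the pipeline at the
default study conditions: recovery at 300 functions × 100 pairs, the
training-size curve at $N \in \{5, 10, 15, 20, 50, 100\}$ with 10
repeats on 125 pairs, and 100 seeded replicates of the 15-pair
reduction and of the two-group classification experiment. These sizes
match the regime the method targets (tens of pairs, hundreds of
functions, thousands of calibratable samples) while each experiment
completes in seconds.

## Known limitations

* The affine model cannot capture saturating or presence/absence
  distortions; functions absent from all training amplicons are
  uncorrectable (degenerate) by construction.
* With very few training pairs, rare functions yield extreme slopes;
  these are genuine OLS estimates, and users filtering for robustness
  should do so explicitly (e.g. by `n_train` or by training-abundance
  prevalence).
* Calibration models do not transfer across experimental protocols.
* The 1-NN classifier is a deliberate, documented stand-in for
  proprietary microbiome search engines; absolute accuracies depend on
  the database's coverage of the query regime.
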