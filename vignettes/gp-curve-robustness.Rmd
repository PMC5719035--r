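---
title: "Nonlinear genotype-phenotype maps and phenotypic robustness"
author: "gpcurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear genotype-phenotype maps and phenotypic robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcurve)
```

## The model

`gpcurve` studies how the *shape* of a genotype-phenotype (G-P) curve
controls phenotypic robustness. The developmental quantity is relative
expression of a dosage-manipulated gene, $\varepsilon$ (1 = wild type);
the phenotype is a one-dimensional shape score $z$ obtained from 3D
landmark data. The G-P curve is a saturating von Bertalanffy function

$$z = L_m - (L_m - L_0)\,e^{-k\varepsilon},$$

where $L_m$ is the asymptotic phenotype, $L_0$ the phenotype at zero
expression, and $k$ a rate constant: the slope $f'(\varepsilon) =
k(L_m-L_0)e^{-k\varepsilon}$ falls by a factor $e$ per $1/k$ units of
expression. Two fitted parameter sets are bundled as
`vb_params_e105()` (embryonic day 10.5) and `vb_params_p0()` (birth).

Within a genotype, expression varies between individuals. Because
expression cannot be negative, that variation is modelled as a normal
distribution truncated at zero, $p(\varepsilon)$, with genotype mean
$\bar\varepsilon$ and common SD $\sigma_\varepsilon$. The propagation
to phenotype follows the quantitative framework for nonlinear G-P
maps:

* mean phenotype $\bar z = \int f(\varepsilon)\,p(\varepsilon)\,
  d\varepsilon$ (`predicted_mean()`),
* mean sensitivity $\Phi = \int f'(\varepsilon)\,p(\varepsilon)\,
  d\varepsilon$ (`sensitivity_phi()`),
* phenotypic variance $\sigma_z^2 = \Phi^2\sigma_\varepsilon^2$
  (`predicted_variance(method = "first_order")`).

Every integral is evaluated twice — by adaptive quadrature over the
10-$\sigma$ window of the truncated density (absolute tolerance
$10^{-10}$) and in closed form through the truncated-normal moment
generating function $M(t)$, with
$\bar z = L_m - (L_m - L_0)M(-k)$ and $\Phi = k(L_m-L_0)M(-k)$ — and
the two routes must agree to $10^{-8}$ or the call errors. $M$ is
computed on the log scale (`pnorm(log.p = TRUE)`), since $M(-2k)$ for
the steep neonatal curve ($k \approx 13$) would otherwise overflow.

Two deliberate conventions:

* **Variance of the truncated distribution.** In
  $\sigma_z^2 = \Phi^2\sigma_\varepsilon^2$ we take
  $\sigma_\varepsilon^2$ as the variance of the *truncated*
  distribution, not the nominal parent SD. This makes the first-order
  formula exactly equal to the exact propagated variance
  ($\mathrm{Var}[f(\varepsilon)]$, available as `method = "exact"`)
  whenever $f$ is linear, which is the natural consistency requirement.
  `linear_map()` exists precisely to exercise that identity.
* **No extrapolation below zero.** The curve is never evaluated at
  negative expression; the truncation itself is what bends the
  variance response at low mean expression
  (`variance_response_surface()`).

The operational "threshold" of the curve is reported as the expression
level where the slope has decayed to a given fraction of its value at
zero, $\varepsilon^* = \ln(1/\text{fraction})/k$
(`threshold_expression()`; the default fraction 0.1 puts
$\varepsilon^*$ near 0.43 for the embryonic curve, matching the
apparent 40%-of-wild-type threshold in the disparity profile).

## Morphometrics

Landmark configurations ($K \times 3$) are superimposed by generalized
Procrustes analysis: translation to centroid origin, scaling to unit
centroid size, and iterative proper rotation to the evolving consensus
(tolerance $10^{-10}$, at most 100 sweeps; reflections excluded).
Because the converged orientation otherwise depends on which specimen
seeds the consensus, the final consensus is rotated to its principal
axes with signs fixed by the largest-magnitude coordinate (axis 3
forced right-handed), making the output independent of input order.
Tangent-space projection is omitted: all analyses here operate close
to the consensus, where the spherical-to-tangent distortion is far
below the effects of interest.

Downstream statistics operate on the flattened $n \times 3K$ aligned
coordinates:

* `remove_lab_offset()` subtracts the difference between each lab's
  wild-type mean and the reference lab's, the standard
  common-control correction for batch structure. It is applied after
  GPA and *before* stage standardization (the order is a package
  choice; the two stages commute up to the small interaction between
  lab offset and stage slope).
* `standardize_shapes()` regresses each coordinate on a stage
  covariate (tail-somite count for embryos) or on centroid size
  (neonates) and keeps residuals plus the grand mean.
* `shape_regression()` regresses shape on expression; its
  `regression_scores` — projections onto the unit coefficient vector —
  are the 1D phenotype fed to the curve fit (equivalent to the common
  allometric component in a pooled analysis).
* `procrustes_variance()` is the morphological disparity: mean squared
  deviation from the group mean, divisor $n$ (the population
  convention of the disparity literature; `divisor = "n-1"` is
  available).

### Permutation tests

`disparity_permutation_test()` compares Procrustes variances pairwise
with the statistic $|PV_a - PV_b|$ and add-one Monte Carlo P values.
The default null permutes raw specimens between the two groups, which
is exchangeable — hence exactly calibrated — when the groups share one
distribution. A residual-randomization variant (permuting each
specimen's squared distance from its own group mean) is provided for
pairs whose mean shapes differ strongly; it is slightly
anti-conservative (empirically ~0.06-0.07 at $\alpha = 0.05$) because
own-mean centering breaks exchangeability, and that trade-off is why
it is not the default. `mean_shape_permutation_test()` uses the
distance between group means, with an exhaustive-enumeration mode for
tiny groups. Both tests sort specimens canonically before drawing
seeded permutations, so a fixed seed yields identical P values
whatever order the specimens arrive in.

`variance_power_simulation()` estimates the power to detect a given
variance ratio between two groups of isotropic Gaussian shapes at a
given per-group sample size — the design tool behind statements like
"about ten specimens detect a doubling of variance".

## Expression statistics

`delta_delta_ct()` implements relative quantification: per sample
$\Delta C_t$ (target minus reference), normalized against the
*wild-type group mean* $\Delta C_t$ before exponentiation, so the
wild-type group averages near — but, by Jensen's inequality, slightly
above — 1. `levene_test()` (mean-centered, via `car`) and
`oneway_anova()` test variance homogeneity and mean differences of
expression across genotypes; degrees of freedom are reported as
(within, between).

Count matrices are normalized by the median-of-ratios size-factor
method (each sample's factor is the median, over genes expressed in
all samples, of the count over the gene's geometric mean). This is a
reimplementation of the standard estimator — it agrees with
`DESeq2::estimateSizeFactorsForMatrix` to $10^{-6}$ in the test suite
— kept in-package so the pipeline has no heavyweight dependency. Note
that factors are anchored to per-gene geometric means, so doubling one
sample doubles its factor *relative to the others* while all factors
shift by the common constant $2^{1/n}$.

The resampling statistics mirror a transcriptome analysis across an
allelic series:

* `foldchange_profile()` — per genotype, the mean absolute log2 fold
  change of a gene set versus wild type, with delta-method standard
  errors. Fold changes are on the log2 scale (the scale on which
  count ratios are approximately symmetric).
* `neighbor_bootstrap_test()` — adjacent genotypes compared on that
  profile. The default null *permutes* the pooled pair (exchangeable,
  calibrated at any group size whose split count allows rejection; at
  $n = 3$ per group, $C(6,3) = 20$ splits make $P \le 0.05$
  unattainable, so design accordingly). A pooled with-replacement
  bootstrap is retained as an option but is conservative at small
  $n$: pseudo-group means are overdispersed by roughly $\sqrt{1.5}$
  relative to real group means. Pairs containing the wild type
  recompute the reference from the pseudo-wild-type samples in each
  resample so the null statistic matches the observed one's structure.
* `within_genotype_concordance()` — Fisher-z-transformed pairwise
  correlations between individuals across a gene set (z capped at
  $\mathrm{atanh}(1-10^{-12})$), compared with wild type by a
  two-sided percentile bootstrap in which each group is resampled
  within itself and duplicate-individual pairs (correlation exactly 1)
  are excluded. Pearson correlations on $\log_2(\text{normalized}+1)$
  are the primary measure; correlation rather than covariance because
  it is scale-free across individuals.
* `geneset_fgf8_correlation_test()` — a set's mean gene-level
  correlation with measured expression of the perturbed gene, judged
  against the same statistic on random same-size gene sets drawn
  genome-wide (95% interval, two-sided resampling P); individual
  member genes are flagged against the genome-wide single-gene
  correlation band.

## The synthetic allelic series

`series_config()` encodes the generative model on which everything is
validated. The defaults describe an embryonic allelic series:

* **Nine genotypes**, means (1.0, 1.1, 0.72, 0.56, 0.47, 0.42, 0.30,
  0.22, 0.14) — spanning 0.14 to 1.1 of wild type, with three
  genotypes below the 40% threshold — paired with per-genotype sample
  sizes (27, 15, 30, 13, 16, 16, 19, 12, 8).
* **Common expression SD 0.1.** The within-genotype SD is not pinned
  down by summary statistics alone; 10% of the wild-type level is a
  realistic qPCR-scale biological variability, and at these group
  sizes a homogeneous SD keeps Levene's test comfortably
  non-significant while the means differ overwhelmingly by ANOVA.
* **Shape**: a fixed 10-landmark, unit-centroid-size 3D template; the
  effect of expression moves shape along a single unit direction
  constructed orthogonal to the similarity-transform tangent space
  (translations, scaling, infinitesimal rotations), so superimposition
  cannot absorb it. Per-coordinate Gaussian landmark noise
  (SD 0.0015) sets a disparity floor of about $5\times10^{-5}$ —
  small against the predicted variance of the below-threshold
  genotypes ($3\times10^{-4}$ to $10^{-3}$) and large against that of
  near-wild-type genotypes, which is what produces the flat-then-rising
  disparity profile.
* **Nuisance structure**: a fixed lab-offset vector for the second lab
  (wild types occur in both labs, so the offset is estimable), a mild
  stage allometry over a tail-somite-like covariate, and per-specimen
  random rotation, translation, and log-uniform scale in [0.5, 2]
  (proper rotations only — the superimposition is orientation-only).

`sample_counts()` adds negative-binomial RNA-seq counts (log-normal
library factors of about two-fold range) for gene classes that are
unresponsive, respond down a saturating or linear curve, or respond
*negatively* (compensatory). `sample_qpcr()` emits triplicate Ct
tables whose ddCt analysis recovers expression up to technical noise;
`sample_snp_panel()` emits near-isogenic SNP panels with tunable
within-line heterozygosity.

What the generator deliberately does **not** emulate: spatially
correlated landmark error, multi-direction shape responses, missing
landmarks, linkage structure in SNP panels, or read-level sequencing
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not
robustness to every pathology of real data.

## The pipeline

`run_pipeline()` chains the stages in a fixed order — GPA, lab-offset
removal, stage standardization, shape regression on expression, curve
fit, variance propagation, disparity — and returns per-genotype
observed disparity next to the predicted variance, plus the fitted
curve, threshold, Levene/ANOVA tables, and optional pairwise
disparity P values. The curve is fitted to per-individual
(expression, score) points by default (`curve_fit = "genotype_mean"`
switches to genotype means); per-genotype predictions use the
genotype's mean measured expression with the pooled within-genotype
SD.

One accuracy note: because GPA scales configurations to unit centroid
size, a shape displacement $f$ along the signal direction appears in
aligned coordinates as $f/\sqrt{1+f^2}$ — an $O(f^2)$ compression.
With the embryonic curve ($|f| \le 0.13$) the recovered curve
parameters differ from the generating ones by up to a few percent even
with noise-free landmarks; the acceptance-level parameter-recovery
experiments (`vb_recovery_experiment()`) therefore simulate scores
directly on the curve, where the fit is unbiased.

```{r example}
report <- run_pipeline(series_config(seed = 11), n_perm = 0)
report
```

## Numerical and design choices, in brief

* Curve fitting: Levenberg-Marquardt with starts $L_m = \max z$,
  $L_0 = \min z$ and $k \in \{0.5, 1, 5, 50\}$ (the SSQ surface is
  multimodal in $k$); best residual sum of squares wins; fits driven
  to the $k$ bounds are flagged `boundary` and not reported as
  converged. Linear-looking data therefore comes back flagged rather
  than silently fit.
* Test problem sizes: the validation suite runs its null-calibration
  experiments at 500 simulated datasets per test and its power grid at
  150 replicates per cell — enough for the binomial confidence bands
  asserted, small enough to keep the whole suite in a few minutes.
* P values: add-one convention throughout; never exactly zero.
* Degenerate inputs fail loudly and name the offender: collinear or
  coincident landmark configurations, constant covariates, labs with
  no wild types, samples missing the reference gene, matrices with no
  all-nonzero gene.

## Limitations

* The shape model is single-direction by construction; real allelic
  series may distribute dosage effects over several shape dimensions.
* The first-order variance formula ignores curvature within a
  genotype's expression range; the exact propagated variance is always
  reported alongside, and the two diverge visibly only below ~30%
  expression at SD 0.1.
* Permutation/bootstrap P values inherit Monte Carlo granularity; at
  three samples per group no permutation scheme can reach
  $P \le 0.05$.
* The SNP summaries assume unit allelic effects (relative, not
  absolute, genetic variance) and ignore linkage.
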