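# gpcurve

Phenotypic robustness from nonlinear genotype–phenotype maps.

Complex organisms buffer morphology against genetic and environmental
perturbation — but mutants are often *more variable* than wild types, and
the mechanisms behind such differences in robustness are mostly unknown.
`gpcurve` implements a quantitative explanation that requires no dedicated
buffering machinery: if a developmental quantity ε (here, relative
expression of a dosage-manipulated signaling gene; 1 = wild type) maps to
phenotype *z* through a saturating curve, then the *slope* of that curve at
a genotype's mean expression determines how much phenotypic variance a
fixed amount of expression variance produces. Genotypes on the flat part
of the curve are canalized; genotypes on the steep part are not.

The package is written for quantitative developmental biologists and
morphometricians who want to fit, test, and simulate this mechanism
end-to-end:

- **G–P curve**: von Bertalanffy form `z = L_m − (L_m − L_0) e^(−k ε)`,
  fit by multistart Levenberg–Marquardt nonlinear least squares
  (`fit_vb`), with the published embryonic (E10.5) and neonatal (P0)
  parameter sets bundled (`vb_params_e105()`, `vb_params_p0()`).
- **Variance propagation**: mean phenotype `z̄ = ∫ f(ε) p(ε) dε`,
  sensitivity `Φ = ∫ f′(ε) p(ε) dε`, and phenotypic variance
  `σ_z² = Φ² σ_ε²` under zero-truncated normal expression distributions,
  each computed both by quadrature and by closed form through the
  truncated-normal MGF and cross-checked to 1e−8 (`predicted_mean`,
  `sensitivity_phi`, `predicted_variance`, `variance_response_surface`).
- **Geometric morphometrics**: order-invariant generalized Procrustes
  analysis of 3D landmarks, lab-offset removal, stage/size
  standardization, shape regression and regression scores (the 1D shape
  phenotype), Procrustes variance (morphological disparity), calibrated
  pairwise permutation tests, and a variance-detection power simulator.
- **Expression statistics**: ΔΔCt quantification, Levene/ANOVA wrappers,
  median-of-ratios count normalization, fold-change profiles with
  nearest-neighbor resampling tests, within-genotype expression
  concordance, and gene-set correlation tests against genome-wide
  resampling.
- **Strain genetics**: SNP allele frequencies, additive genetic variance
  (Σ 2p(1−p)), and relative inbreeding.
- **Synthetic data**: a fully parameterized allelic-series generator
  (expression, 3D landmarks with nuisance rotation/translation/scale,
  negative-binomial counts, qPCR Ct tables, SNP panels) with ground truth
  emitted alongside, so every stage is testable without external data.

## Worked example

Simulate the default nine-genotype allelic series (means spanning
0.14–1.1 of wild type, common expression SD 0.1, published E10.5 curve as
ground truth) and run the full analysis:

```r
library(gpcurve)
report <- run_pipeline(series_config(seed = 11), n_perm = 0)
report
#> Allelic-series robustness report
#>   curve: L_m = 0.01356, L_0 = -0.1332, k = 5.5 (R^2 = 0.974)
#>   shape ~ expression R^2 = 0.511
#>   threshold expression (10% slope) = 0.419
#>   Spearman(predicted, observed variance) = 0.933
#>   Levene P = 0.5772, ANOVA P = 1.556e-66
#>      genotype  n mean_expression observed_disparity predicted_var_exact
#>            WT 27           0.962           5.32e-05            2.97e-07
#>        Flox/+ 15           1.130           4.73e-05            4.72e-08
#>         Neo/+ 30           0.741           6.42e-05            3.40e-06
#>        Flox/- 13           0.574           4.92e-05            2.13e-05
#>           Het 16           0.509           1.18e-04            4.35e-05
#>  Flox/+;Crect 16           0.452           7.52e-05            8.14e-05
#>  Flox/-;Crect 19           0.311           3.31e-04            3.51e-04
#>       Neo/Neo 12           0.275           6.89e-04            4.83e-04
#>         Neo/-  8           0.204           9.36e-04            7.74e-04
```

Reading the output: the fitted curve recovers the generating parameters
(true L_0 = −0.12787, k = 5.3003); the threshold — where the curve's
slope has decayed to 10% of its zero-expression value — lands near 42% of
wild-type expression. Observed disparity (Procrustes variance per
genotype) is flat at ~5e−5 (the landmark-noise floor) for every genotype
above the threshold and rises an order of magnitude below it, tracking
the model's predicted variance with Spearman ρ = 0.93. Expression
variance itself is homogeneous across genotypes (Levene P = 0.58) while
the means differ overwhelmingly (ANOVA) — the increase in shape variance
comes from the curve's nonlinearity, not from noisier expression.

The curve machinery is equally usable standalone:

```r
p <- vb_params_e105()
spec <- truncnorm_spec(mean = 0.3, sd = 0.1)     # genotype at 30% of WT
predicted_variance(p, spec, "exact")             # 3.52e-04
predicted_variance(p, truncnorm_spec(1, 0.1))    # 1.96e-07 : canalized
threshold_expression(p, 0.1)                     # 0.434
```

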