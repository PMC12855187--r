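# psametab

Serum ¹H-NMR metabolomics discovery pipeline for psoriatic arthritis (PsA),
implemented as a fully testable R package.

## What this package is for

Untargeted serum NMR metabolomics can separate patients with active psoriatic
arthritis from healthy controls (HC) and point at the metabolic pathways that
shift with disease. The discovery workflow behind such studies is a long
chain of methods — spectral bucketing, normalization, chemometric modelling,
univariate screening, biomarker panel construction, clinical-score
correlation and pathway enrichment — usually spread across several
proprietary tools (SIMCA, ACD Labs, MetaboAnalyst). `psametab` re-implements
that whole chain as open, composable R functions, together with a calibrated
synthetic-cohort generator so that every stage can be exercised, validated
and regression-tested at desk scale without access to patient data.

It is aimed at metabolomics analysts and methodologists who want a
transparent, scriptable version of this standard discovery pipeline, and at
anyone who needs realistic simulated NMR cohorts for method evaluation.

## The methods at its core

* **Intelligent bucketing** — the 0.80–8.50 ppm region is divided into
  nominal 0.04 ppm buckets whose interior boundaries snap to local minima of
  the mean spectrum within ±50% looseness, so bucket widths stay in
  [0.02, 0.06] ppm and a peak whose position jitters between samples (the pH
  effect) stays in one bucket. The residual-water window 4.70–5.20 ppm is
  excluded, and each spectrum is normalized to unit total area.
* **Pareto scaling** — each variable is centered and divided by √s (s the
  sample SD), the standard chemometrics compromise between raw and
  unit-variance data.
* **OPLS-DA** (orthogonal projections to latent structures discriminant
  analysis), written from scratch: X-variation is split into one
  class-predictive component t and components t_o orthogonal to class;
  reported as R2X/R2Y (explained X- and Y-variation) and Q2 (predicted
  Y-variation from 7-fold cross-validation). Validity is checked with a
  label-permutation test: the regression of permuted Q2 on the label
  correlation must intercept below 0.05. Variables with VIP > 1 (variable
  importance in the projection; mean VIP² = 1) are carried forward.
* **Univariate screen** — Mann-Whitney U tests on relative concentrations
  (each metabolite as % of the sample's quantified pool) with
  Benjamini-Hochberg adjustment.
* **Logistic ROC panel** — a multi-metabolite logistic model, its ROC curve
  and AUC (which equals the normalized Mann-Whitney statistic U/(n₁n₂)),
  DeLong 95% CI, 100 Monte-Carlo stratified 2:1 cross-validation splits and
  a label-permutation guard. The published nine-metabolite panel
  (logit(P) = −61.645 + 2.991·Leucine + 2.08·Serine + 1.735·Alanine +
  0.394·Glucose + 6.134·Methionine − 0.313·Isoleucine − 0.072·Valine +
  0.256·Glycylproline + 0.346·Glutamine, cutoff P = 0.38, y = 1 coding HC)
  ships as a fixture for scoring new samples.
* **Clinical correlation** — Spearman r of each significant metabolite
  against the DAPSA disease-activity score (active disease: DAPSA > 14),
  with Fisher-z confidence intervals.
* **Pathway over-representation** — one-tailed hypergeometric tests against
  a curated GMT library of serum metabolite sets, with BH adjustment,
  enrichment ratios, and a pathway network linking sets that share members.
* **Synthetic cohorts** — group-specific correlated truncated-Gaussian
  concentrations for 13 metabolites (defaults: the published PsA/HC group
  means and SDs, n = 29/33), DAPSA scores drawn through a Gaussian copula
  (Spearman targets 0.384 for alanine, 0.487 for leucine) with a
  moment-matched left-truncated normal margin (mean 25.2, SD 10.4, floor 14),
  and rendered Lorentzian multiplet spectra with per-sample chemical-shift
  jitter, TSP reference peak and residual-water band.

## Worked example

```r
library(psametab)
res <- run_pipeline(pipeline_config(seed = 11, spectra = TRUE,
                                    n_perm_opls = 100))
res
#> Discovery pipeline result
#>   cohort: 29 PsA / 33 HC
#>   buckets: 180 (after water exclusion)
#>   OPLS-DA: R2X 0.289  R2Y 0.554  Q2 0.280  (Q2 intercept -0.448)
#>   significant metabolites (raw p < 0.05): 2-aminobutyrate, glucose,
#>     glutamine, glycylproline, isoleucine, leucine, serine, threonate, valine
#>   panel AUC: 0.953 (CV mean 0.824, permutation p 0.000999)
```

The OPLS-DA on the bucket matrix separates the groups (R2Y 0.554, Q2 0.280)
and the permutation test clears the validity criterion (Q2 intercept
−0.448 < 0.05). The univariate screen flags the discriminating metabolites in
this simulated cohort, the logistic panel built on them reaches a
resubstitution AUC of 0.953 with an honest Monte-Carlo CV mean of 0.824, and
the permutation guard bottoms out at its attainable floor. Downstream:

```r
res$dapsa_correlation[res$dapsa_correlation$p < 0.05, ]
#>   metabolite         r     ci_lo     ci_hi           p  n
#> 6    leucine 0.4871921 0.1357841 0.7297143 0.007352044 29

head(as.data.frame(res$enrichment)[, c("set", "hits", "p")], 3)
#>                                         set hits          p
#> 1 Valine Leucine and Isoleucine Degradation    3 0.03480959
#> 2                      Protein Biosynthesis    5 0.05412808
#> 3                         Ammonia Recycling    2 0.15283559
```

Leucine's simulated DAPSA correlation lands on its configured target, and
branched-chain amino acid catabolism tops the pathway ranking — the signal
the generator was asked to produce.

Scoring new samples with the published panel:

```r
sc <- score_fixed_panel(relative_concentrations(conc))  # cutoff P >= 0.38 -> "HC"
```

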