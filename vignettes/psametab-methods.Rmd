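---
title: "Models, parameters and design choices in the psametab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in the psametab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psametab)
```

`psametab` implements the serum ¹H-NMR discovery workflow that compares
active psoriatic arthritis (PsA) patients with healthy controls (HC), plus a
synthetic-cohort generator that makes every stage verifiable. This vignette
explains the models behind each stage, the parameters that matter, the
numerical decisions taken where the method family leaves choices open, and
what the simulation does and does not establish about real data.

## The synthetic cohort generator

The generator is not a test fixture but a first-class model of the study
conditions, and its defaults *are* those conditions: two groups of n = 29
(PsA) and n = 33 (HC); 13 serum metabolites with the group-specific means
and SDs of the discovery cohort, expressed as relative concentrations (each
metabolite as a percentage of the total quantified pool — the published mean
vectors sum to ~100, which settles the otherwise ambiguous concentration
scale); DAPSA disease-activity scores for the PsA arm with mean 25.2, SD
10.4, and every value above the active-disease floor of 14.

**Concentration margins.** Only means and SDs are reported for the cohort,
so each group is modelled as a multivariate Gaussian truncated at zero, with
redraw-on-negative rather than clipping so the configured means are
preserved (at the default parameters the negative mass is negligible — the
smallest mean sits 3.3 SDs above zero). No covariance information exists
either, so the metabolite–metabolite correlation defaults to an exchangeable
matrix with ρ = 0.1 — weak positive dependence of the kind ubiquitous in
serum panels — and is fully configurable, including a ρ = 0 variant used
when independent margins are wanted.

**DAPSA.** A naive truncation of N(25.2, 10.4²) at 14 would bias the mean
upward, so the generator solves for the *parent* (μ, σ) whose left-truncated
distribution has exactly the target mean and SD. The solver works on the
standardized truncation point α = (14 − μ)/σ, for which the ratio
SD/(mean − floor) is monotone; `uniroot` on α followed by closed-form
back-substitution is robust across the whole feasible range (the ratio must
lie in (0, 1); here it is 10.4/11.2 ≈ 0.93, i.e. a strongly truncated,
near-exponential shape — a consequence of matching both printed moments
above the printed floor). A quadrature oracle in the test suite confirms the
solved parameters reproduce the moments to 1e-6.

**The DAPSA–metabolite link.** The published Spearman correlations between
DAPSA and alanine (0.384) and leucine (0.487) are imposed through a Gaussian
copula: the linked metabolites' latent scores are their standardized
concentrations, the DAPSA latent is drawn conditionally on them with Pearson
correlations ρ = 2·sin(πr_s/6) (the exact Spearman-to-Pearson conversion for
bivariate Gaussian copulas), and the latent is then mapped through the
truncated-normal quantile function. Monotone mapping preserves Spearman
correlation exactly, so the large-n empirical rank correlations converge on
the targets; at n = 29 the sample Spearman estimator carries a small
negative bias (~0.01–0.015), which is why recovery is checked as a mean over
many cohorts within ±0.02 rather than per cohort. Whether the real cohort's
correlations arise directly or through disease severity is unknowable from
the published summaries; the copula is a phenomenological stand-in.

**Spectra.** Each sample's spectrum is a sum of Lorentzian multiplets with
area proportional to concentration, built from an editable multiplet library
(approximate 500 MHz chemical shifts; the pipeline relies only on the
library's internal consistency, never on literature exactness). Per-sample,
per-multiplet position jitter ~ N(0, 0.005 ppm) emulates pH-dependent shift
variation; a TSP reference peak sits at 0.00 ppm and a residual-water band
inside 4.70–5.20 ppm. The water band is rendered as a Gaussian rather than a
Lorentzian: a band with hundreds of times a metabolite peak's area would
otherwise leak heavy Lorentzian tails across the entire spectrum, whereas a
presaturation residual is localized. Additive Gaussian noise (default SD 0.5
intensity units) completes the model. Not emulated: J-coupling fine
structure, field-strength effects, T2 relaxation, baseline/phase artifacts —
the renderer exists to exercise bucketing, normalization and the multivariate
stage, not to imitate an instrument.

## Bucketing

Nominal boundaries are laid every 0.04 ppm across 0.80–8.50 ppm; each
interior boundary relocates to the minimum of the reference spectrum within
±looseness·width/2 (= ±0.01 ppm), reproducing the printed width range
[0.02, 0.06] exactly. Open choices resolved here:

* *Reference spectrum* = pointwise mean across samples (deterministic, the
  standard choice).
* *Ties and flat windows*: argmin ties break toward the nominal position; a
  flat window keeps the exact nominal boundary.
* *The trailing remainder*: 0.80–8.50 ppm is 192.5 nominal buckets. A
  remainder at least width·(1 − looseness) becomes its own bucket with fixed
  boundaries (the default case: a final 0.02 ppm bucket); a smaller one is
  merged into the last full bucket, whose left boundary is then frozen. Both
  rules provably keep every width inside [0.02, 0.06].
* *Integration*: trapezoidal, with intensities interpolated at the exact
  boundary positions so adjacent buckets tile the region and their sum equals
  the full-region quadrature to 1e-9 (tested against an independent
  integrator).
* *Order of operations*: water exclusion (any bucket overlapping the open
  interval 4.70–5.20 is dropped, applied literally) happens after bucketing
  and before total-area normalization, following the stated method order.

## Scaling and OPLS-DA

Pareto scaling uses the sample (n−1) SD, matching common chemometrics
software; centering is applied even though descriptions of Pareto scaling
often mention only the division, because the latent-structure model requires
centered data. Zero-variance columns are flagged and zeroed rather than
producing NaNs.

The OPLS-DA follows the Trygg–Wold orthogonal-signal-correction iteration.
With a single response column the NIPALS inner loop converges in one pass,
so the fit is deterministic with no tolerance to tune. The class is coded as
one centered 0/1 dummy (two-class only; multi-class is out of scope). One
consequence of the weight normalization worth knowing: swapping the class
labels negates the scores t and the fitted values, but leaves the y-loading
c — and hence R2, Q2 and VIP — unchanged.

Cross-validation uses 7 folds assigned deterministically round-robin within
class by input order, so results are reproducible without recording a
permutation; the scaling model is refit inside every training fold. The
permutation test shuffles labels (default 500; scaled runs use 100),
records |corr(y_perm, y)|, R2Y and Q2 per permutation, and reports the
intercepts of least-squares lines through all points including the
unpermuted model at correlation 1 (the line is not constrained through that
point). VIP is the predictive-component variant — for one predictive
component, VIP_j = √p·|w_j| with mean VIP² = 1 — stated explicitly because
software implementations differ on whether orthogonal components contribute.

## Univariate screen, panel and correlation

Mann-Whitney U uses midranks for ties; the two-sided p is exact by
enumeration when both groups have ≤ 8 tie-free observations, otherwise the
normal approximation with tie and continuity corrections (at the cohort's
n = 29/33 the approximation is the appropriate regime). BH adjustment runs
across the 13-metabolite family mirroring the discovery table; the
significance flag is raw p < 0.05 with adjusted p ≤ 0.05 *inclusive*,
matching the way a boundary value of exactly 0.05 was reported as
significant in the reference table.

The logistic panel is fitted by IRLS with a 1e-8 ridge on standardized
slopes — invisible on well-conditioned data (agreement with `glm` to 1e-4 is
tested) but it keeps coefficients finite under the complete separation that
strong simulated cohorts regularly produce; separation is detected and
flagged rather than hidden. The "100-fold cross-validation" of the original
workflow cannot be literal at n = 62; it is interpreted as 100 stratified
Monte-Carlo 2:1 train/test splits, and the permutation guard reports the
add-one estimate (1 + #{perm ≥ obs})/(n_perm + 1), whose floor at 500–1000
permutations is the resolution limit of the test. The published
nine-coefficient panel ships as a JSON fixture with its 0.38 cutoff; its
y = 1 class is HC, a fact the package establishes by direct arithmetic
(evaluating the printed formula at the two group mean vectors gives
P = 0.936 and 0.094) rather than by assumption. Threshold selection for
*newly fitted* panels uses Youden's J; the fixture's 0.38 is never
re-derived silently. ROC curves are stepwise over all unique thresholds with
trapezoid AUC, which makes the AUC equal the midrank Mann-Whitney statistic
exactly, ties included; the default CI is DeLong's, with a stratified
percentile bootstrap fallback when the AUC is degenerate.

Spearman correlation against DAPSA uses midranks, exact permutation p for
n ≤ 10, the t approximation otherwise (the regime of the n = 29 PsA arm),
and Fisher-z intervals with the Spearman-specific variance inflation
√(1.06/(n−3)) — the published table does not state its CI method, so this
standard construction is used and its ~95% coverage at the leucine target is
verified by simulation.

## Enrichment

Over-representation is the one-tailed upper hypergeometric tail, BH-adjusted
across sets. The reference analysis ran against a proprietary pathway
library that cannot be redistributed, so the package ships a small curated
GMT library (~20 serum metabolite sets, including the pathways named in the
reference results, with literature-standard members) plus an editable alias
table; name matching lowercases, strips D-/L- prefixes and punctuation, and
errors on unmapped query names instead of silently dropping them. The
default universe is all library members plus the query. Exact pathway
rankings therefore depend on this library and are direction checks, not
reproduction targets. The pathway network connects sets with ≥ 1 query hit
that share ≥ `min_shared` members, nodes carrying the enrichment ratio and
p-value (the size and color channels of the usual figure).

## Validation scale and limitations

The test suite and the acceptance script run the stochastic checks at sizes
chosen to make Monte-Carlo error small relative to each tolerance while
keeping a desk-scale footprint: 1000 cohorts of n = 29 for rank-correlation
recovery, 200 cohorts for the panel-AUC and leucine-significance
distributions, 25 cohorts × 100 permutations for the Q2-intercept criterion,
and n = 10 000 single draws for generator calibration; large-sample copula
checks use n = 10⁵.

Passing these checks shows the pipeline's machinery is correct and that its
behavior under the *assumed* generative model matches the published
reference points. It does not show that real serum spectra meet those
assumptions: Gaussian margins, exchangeable correlation, a phenomenological
DAPSA copula and idealized Lorentzian peaks are all simplifications, and the
published model statistics (R2/Q2, exact p-values, the 0.842 AUC) belong to
an unreleased patient dataset that no simulation can reproduce exactly.
Treatment subgroup modelling, acquisition physics, phase/baseline
correction, and library-fitting quantification from real spectra are out of
scope by design; the pipeline accepts concentration tables for the tabular
branch and externally preprocessed spectra for the spectral branch.
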