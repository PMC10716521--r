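---
title: "Methods: islet methylation association, risk scores, and matched-pair validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: islet methylation association, risk scores, and matched-pair validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletewas)
```

# The analysis chain

`isletewas` implements the computational chain that links pancreatic-islet
DNA methylation to type 2 diabetes (T2D):

1. **Probe filtering** of an array manifest (detection p-value, Y-chromosome,
   rs, ch, cross-reactive and polymorphic probe classes).
2. **Site-level association (EWAS)** of methylation with a binary
   case/control phenotype and with continuous HbA1c, by ordinary least
   squares on the M-value scale, adjusted for age, BMI, sex, islet purity and
   days in culture, with Benjamini–Hochberg false-discovery-rate control.
3. **Directional concordance** between the two analyses: sites significant in
   both with the same coefficient sign.
4. **Genomic integration** of significant CpG sites with open-chromatin,
   transcription-factor and regulome interval tracks, and with ±10 kb gene
   windows around differentially expressed genes (DEGs).
5. **Methylation risk scores (MRS)**: per-gene weighted sums of methylation
   percentages, associated with disease status by linear and logistic models.
6. **Prospective validation**: conditional logistic regression of incident
   disease on blood methylation in 1:1-matched case–control pairs.

A synthetic-cohort generator with planted ground truth makes the whole chain
testable without access to restricted individual-level data.

# Models and assumptions

## Site-level regression on the M scale

Methylation fractions (β-values, in [0, 1]) are strongly
heteroscedastic near their boundaries, so all inference uses the logit-like
M-value, $M = \log_2 \beta/(1-\beta)$. β-values are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the
transform, which bounds M at degenerate sites instead of producing
infinities. Per site the model is

$$ M_{ij} = \alpha_j + \gamma_j\, x_i + \boldsymbol{\delta}_j' \mathbf{c}_i + e_{ij}, $$

with $x_i$ the phenotype (case indicator or HbA1c in mmol/mol, untransformed)
and $\mathbf{c}_i$ the covariates. The phenotype coefficient is tested with a
two-sided t-test; p-values from all retained sites are adjusted once by the
Benjamini–Hochberg step-up procedure, and significance is the strict
inequality q < 0.05 (configurable). The model assumes independent Gaussian
errors on the M scale and linearity of the HbA1c effect; neither is checked
per site, which is standard for array-scale screens.

Effect sizes are reported on the interpretable β (%) scale as *unadjusted*
group means, their difference in percentage points, and the relative (fold)
change in percent of the control mean. This split — adjusted inference on M,
unadjusted descriptive effects on β% — mirrors the field convention of
reporting absolute methylation differences beside covariate-adjusted q-values.
Whether published absolute differences are covariate-adjusted is usually
unstated; the unadjusted-group-mean convention here is an explicit design
decision.

Missing values: samples missing any model variable are dropped; per site,
remaining missing β-values lead to complete-case fits with `n_used`
recorded; probes missing in more than 10% of samples are dropped before
modelling. Rank-deficient per-site designs (for example a constant
covariate) are flagged, never fatal. Sex enters as a single 0/1 indicator
whose level mapping is recorded on the result.

## Concordance and genomic integration

Two EWAS tables over the same probe universe are intersected at a common q
threshold; "concordant" sites must agree in coefficient sign
(up/up or down/down quadrants), and doubly significant sites with discordant
signs are excluded and listed. CpG sites are treated as 1-bp points (the
interrogated cytosine), all coordinates are 0-based half-open (BED
convention; manifest positions are converted from 1-based on load), and
overlap is strand-blind — CpG methylation is strand-symmetric. A site at
position $p$ is inside $[s, e)$ iff $s \le p < e$. Gene windows default to
the gene body extended by ±10 kb, i.e. $[\max(0, \text{start} - f),
\text{end} + f)$; whether published ±10 kb windows anchor at the body or the
TSS is typically ambiguous, so a strand-aware TSS anchoring is available as
a flag (`anchor = "tss"`, window $[\text{tss} - f, \text{tss} + f + 1)$).
Overlap queries delegate to `GenomicRanges`; the test suite checks every
operation against all-pairs brute-force scans.

## Methylation risk scores

For each gene with differential expression (q < 0.05) and **more than five**
(≥ 6) significant methylation sites in its window, the score of sample $s$ is

$$ \mathrm{MRS}_s = \sum_j w_j \cdot (100\,\beta_{sj}), $$

with weights $w_j$ the per-site regression effect sizes. Published
descriptions of such weights are ambiguous about the coefficient scale
(regressions are run on M-values but the score sums methylation
percentages), so the weights here come from a re-fit of the per-site model
with methylation **percent** as the outcome — making score units
interpretable "per weighted %" — and an M-scale alternative is a flag
(`scale = "m"`). Missing methylation is imputed by the site's cohort mean
(counts logged). Association uses a linear model (score on group +
covariates) and a logistic model (group on score + covariates, odds ratio
per unit score with Wald 95% CI). Complete or quasi-complete separation is
detected (fitted probabilities within 1e−8 of 0/1, or a standardised
coefficient beyond 30) and flagged with no silent estimate: with strongly
planted effects at n = 100 the per-gene score can separate the groups
perfectly, in which case the logistic MLE does not exist.

## Conditional logistic regression for 1:1 matched pairs

For pairs matched on age and sex (and, in real designs, sampling
conditions), the conditional likelihood depends only on within-pair
differences $d_i$ (case − control) of the predictors:
$\ell(b) = \sum_i \log \mathrm{logistic}(d_i' b)$. This is maximised by
Newton iterations with step-halving (never accepting a decrease in the
log-likelihood), stopping when successive log-likelihoods differ by less
than 1e−10 or at 50 iterations (flagged). Pairs with zero difference in
every predictor are non-informative and dropped with a count. Separation is
declared when a standardised coefficient $|b_j|\,\mathrm{sd}(d_j)$ exceeds
15 — a bounded, reportable failure instead of a runaway estimate. The
predictor is kept on the percent scale so coefficients read "per percentage
point of methylation". For a binary exposure the estimator reduces exactly
to the classical discordant-pair ratio $n_{10}/n_{01}$, which the tests
assert, and the general case is cross-checked against both an
intercept-free logistic fit on differences and `survival::clogit`.

# The synthetic cohort generator

The generator emulates the structure of a ~100-donor islet case/control
cohort with a continuous HbA1c phenotype on the same donors, plus annotation
tracks and a matched blood cohort. It does **not** simulate array chemistry,
probe-type bias, batch effects, or cell-type composition — so passing tests
demonstrate correctness of the estimators under a clean generative model,
not robustness to those real-data artifacts (normalisation and
reference-free composition adjustment are out of scope and assumed done
upstream).

Key defaults, chosen once to mirror the emulated study conditions:

| Parameter | Default | Why |
|---|---|---|
| `n_controls` / `n_cases` | 75 / 25 | cohort sizes of the emulated design |
| age | N(61.4, 9) yr, clipped [30, 85] | donor age distribution |
| BMI | N(26.3, 3.5) kg/m², clipped [18, 40.1] | donor BMI distribution |
| sex | 63% male | donor male fraction |
| islet purity | N(83.2, 7) %, confined [70, 100] | preparations below 70% excluded |
| days in culture | 1 + Poisson(2) | typical 1–9 day culture times |
| HbA1c | controls N(37, 3), cases N(50, 6), clipped [23, 86] mmol/mol | group means/ranges of the emulated cohorts |
| `frac_hypo` | 0.77 | majority of case-associated sites lose methylation |
| `noise_sd_m` | 0.5 | within-group M-value dispersion; arrays typically show 0.3–1; exposed as a parameter because source studies rarely report it |
| `hba1c_slope_pp_per_unit` | 0.5 pp per mmol/mol | a 13 mmol/mol group gap then conveys an HbA1c signal commensurate with the planted 10 pp case effect |

Null baseline β-values follow a bimodal mixture (arrays are dominated by
near-0 and near-1 sites); planted sites draw mid-range baselines so the
target shift stays inside (0.02, 0.98). Effects are planted **additively on
the M scale** and calibrated numerically: the shift $\Delta m_j$ solves

$$ \mathbb{E}[\beta(m_{0j} + \Delta m_j + \sigma Z)] -
   \mathbb{E}[\beta(m_{0j} + \sigma Z)] = \Delta\beta_{\text{target}}, $$

with the expectation over the noise computed by 31-node Gauss–Hermite
quadrature and the root found by `uniroot`. Calibrating through the noise
matters because the M→β map is nonlinear, so noise shifts group means of β;
planting on M keeps β in (0, 1) without truncation artifacts. The HbA1c
association is planted through the *within-group* HbA1c residual so it never
perturbs the case−control difference, and shares the site's direction so
concordance holds by construction. One master seed feeds fixed, documented
offset sub-streams (covariates +11, HbA1c +13, truth +17, baselines +19,
noise +23; tracks +101…; matched cohort +31), so adding a generator never
perturbs another's draws, and identical seeds give byte-identical files.

Annotation tracks place a configurable fraction of true differential sites
inside intervals (±250 bp) per track, plus background intervals around null
sites that are explicitly prevented from covering a differential site — so
an overlap fraction of zero really means zero.

The matched blood cohort draws both members' methylation percentages
(N(50, 3 pp), a realistic inter-individual spread for blood CpGs) and then
assigns the case label *within* each pair from the exact 1:1 conditional
likelihood, $P(\text{member 1 is the case}) = \mathrm{logistic}(\theta'(x_1 -
x_2))$ — so conditional logistic regression is correctly specified and
recovers planted log odds ratios without bias.

# Numerical choices

* ε = 1e−6 clipping in `beta_to_m`; round-trip exact to 1e−9 over M ∈ [−10, 10].
* Multi-site OLS by one QR factorisation of the shared design (pivoting
  undone explicitly); per-site complete-case fits only where a site has
  missing values.
* BH adjustment delegates to `stats::p.adjust`; the hand step-up oracle
  lives in the tests.
* Newton/step-halving tolerances as above; logistic (unconditional) fits use
  `stats::glm` and are oracle-checked against hand-rolled IRLS.
* Ties and zero coefficients: a site with coefficient exactly 0 in either
  analysis is never "concordant" (sign agreement requires a nonzero common
  sign).
* Degenerate inputs: empty overlap inputs yield zero counts, not errors;
  removing every probe in filtering warns instead of failing; a relative
  change with control mean 0 is NA-flagged.

# Problem sizes used by the tests and the acceptance script

Chosen as the package's own verification scale: null calibration on 20,000
sites × 100 samples (per-site type-I error within [0.04, 0.06]); planted
recovery at the emulated study scale (5,000 sites, 2% differential, 10 pp,
n = 100; ≥ 80% recovery at q < 0.05 with observed FDR ≤ 0.10); matched-pair
OR recovery at 500 pairs × 200 replicates (mean within [1.8, 2.2]); CI
coverage at 100 pairs × 500 replicates (within [0.93, 0.97]); MRS direction
at a moderate planted effect (6 pp, 4% of 1,000 sites) where the logistic
MLE exists, OR > 1 in ≥ 90% of replicates that produce a score. The
direction rate conditions on a score existing because failing the six-site
screen in a given replicate is a power event, tested separately at its
boundary (6 selects, 5 does not).

# Known limitations

* The generator's covariates are independent of methylation except through
  the phenotype, so covariate adjustment is exercised but confounding
  recovery is not.
* No probe-type (Infinium I/II) effects, batch structure, or cell-type
  mixtures; conclusions about calibration transfer to real arrays only after
  proper normalisation and composition adjustment upstream.
* The MRS logistic model is reported per unit of the weighted score; with
  few samples and strong effects it can be inestimable (separation), which
  is flagged rather than regularised — no Firth correction is applied.
* Wald intervals are used throughout; profile-likelihood intervals would be
  preferable near separation but are out of scope.

# A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  cohort = cohort_config(n_sites = 2000, seed = 11),
  out_dir = "demo-run", seed = 11)
res <- run_pipeline(cfg)
res$concordance
head(res$prospective$results)
```
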