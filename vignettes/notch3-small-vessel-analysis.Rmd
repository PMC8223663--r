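---
title: "Cysteine-altering NOTCH3 variants and small-vessel disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cysteine-altering NOTCH3 variants and small-vessel disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notch3risk)
```

## The scientific problem

CADASIL, the most common monogenic cause of stroke and vascular dementia,
is caused by missense variants in *NOTCH3* that create or remove a
cysteine in one of the 34 epidermal growth factor-like repeat (EGFR)
domains of the extracellular protein (residues 40–1373, Q9UM47
numbering). Each repeat normally carries six cysteines; an odd number
leaves an unpaired residue that misfolds and aggregates. The same variant
class turns out to be present in roughly 1 in 400–450 people in
population biobanks — two orders of magnitude above clinical CADASIL
prevalence — raising the question this package's analysis battery is
built for: do these "asymptomatic" carriers have measurably elevated risk
of stroke, vascular dementia and MRI markers of small-vessel disease?

Answering it at population scale needs a specific statistical toolkit:

* **Variant ascertainment** at the protein-consequence level (cysteine
  gain/loss inside an EGFR domain), with the domains split into the
  clinically severe proximal group (EGFR 1–6) and the milder distal group
  (EGFR 7–34).
* **Rare-event logistic regression.** With ~440 carriers among ~200,000
  participants and outcomes at 0.3–2% prevalence, ordinary maximum
  likelihood is biased and can diverge under separation. All binary
  models therefore use Firth's penalized likelihood.
* **An association battery** over binary and skewed continuous
  phenotypes, with per-phenotype transforms, standardized effects, and
  Benjamini–Hochberg FDR control.
* **Polygenic-score equivalence**: expressing the carrier effect as the
  number of standard deviations of a polygenic risk score (PRS) that
  confers the same log-odds.
* **Matched visual-MRI comparison**: 3 controls per carrier, exact on
  sex, ethnicity and family history of stroke, nearest in age.

Because the underlying cohort data are access-controlled, the package
ships a synthetic-cohort generator that emulates the assumed data
structure; every analysis stage is validated by parameter recovery
against the generator plus independent numerical oracles.

## The Firth engine

The penalized log-likelihood is

$$ l^*(\beta) = l(\beta) + \tfrac12 \log\lvert I(\beta)\rvert, \qquad
   I(\beta) = X^\top W X,\; W = \operatorname{diag}\{\pi_i(1-\pi_i)\}, $$

maximized by Newton–Raphson on the modified score
$U^*_r = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\}x_{ir}$, where the
$h_i$ are the leverages of the weighted hat matrix. Numerical choices:

* Step-halving (at most 5 halvings per step) whenever a step does not
  increase $l^*$; convergence when $\max_r |U^*_r| < 10^{-6}$ and the
  coefficient update is below $10^{-8}$; at most 100 iterations, with a
  non-convergence flag rather than a silent result.
* The information solve is preconditioned to correlation form
  ($D^{-1} I D^{-1}$ with $D = \sqrt{\operatorname{diag} I}$) so that
  covariates on very different scales — age in years next to unit-scale
  ancestry PCs — do not degrade the Cholesky factorization. This is the
  package's equivalent of internally standardizing covariates, chosen
  because it leaves the likelihood value, the coefficients and the
  constrained-profiling machinery all on the original scale with no
  back-transformation step.
* Confidence intervals default to profile penalized likelihood: the
  bounds solve $l^*_{\text{prof}}(\beta_j) = l^*_{\max} -
  \chi^2_1(0.95)/2$, found by bracket expansion from the Wald radius and
  Brent root-finding; a bound not bracketed within $|\beta| < 20$ is
  reported open. The constrained maximizations keep the **full** model's
  information penalty (the logistf convention), so the intervals invert
  exactly the penalized likelihood-ratio test (PLRT) used for p-values.
  Wald intervals and tests are available by flag and are used inside
  large simulation loops, where the three-fold refit cost of profiling
  buys no additional validity for a mean over replicates.
* On a saturated intercept+exposure model for a 2×2 table, the Firth
  estimate equals the Haldane half-cell-corrected log odds ratio; the
  test suite uses this identity, plus brute-force grid maximization of
  $l^*$, as independent oracles.

## Transforms and standardized effects

Continuous outcomes are transformed (natural log for strictly positive
skewed measures such as WMH volume; Blom rank-based inverse-normal,
$\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$ with average ranks for ties, for
regional WMH scores and Lp(a)-like measures; square root for lesion
counts), then z-scored **on the complete-case analysis sample**, so the
carrier coefficient of the linear model is a standardized difference in
SD units. Z-scoring on the analysis sample rather than the full cohort
keeps each model internally consistent with its own complete-case set.
The cognitive composite z-scores each test, flips reversed-polarity
tests (e.g. reaction time) via an explicit per-test polarity map, and
averages the available scores per participant.

The descriptive comparison table uses Pearson's chi-square without
continuity correction for categorical variables and the pooled-variance
two-sample t-test for continuous ones (the unqualified "two-sample
t-test" convention).

## PRS equivalence

The PRS is consumed as a column, residualized on the first 10 ancestry
PCs and standardized. The SD-equivalent of carrier status is
$\ln(OR_{\text{carrier}})/\ln(OR_{\text{perSD}})$; with the package's
reference inputs (carrier OR 3.07, lower CI 1.81; per-SD OR 1.26, upper
CI 1.32) the three recipes give 4.85 (average), 2.57 (conservative) and
2.14 (most conservative) SD, i.e. one-sided upper tails of ≈0.0001%,
0.51% and 1.6% of the population. The conservative pair brackets the
often-quoted "upper ~1.5% of the population"; the package reports the
computed tails rather than targeting a rounded headline figure, since
the recipes applied to the rounded ORs do not reproduce exactly 1.5%.
Interaction between carrier status and PRS is tested both with a
continuous product term (PLRT, 1 df) and with carrier-by-group terms
after cutting the PRS at its 20th/80th sample percentiles
(linear-interpolation quantiles, left-closed intervals; PLRT, 2 df).

## Matching and the visual-MRI battery

Matching is greedy and without replacement: cases are processed in
seeded random order, each taking the `ratio` (default 3) nearest-age
controls among those agreeing exactly on sex, ethnicity and family
history of stroke, within a ±5-year age caliper (the caliper is a
documented default, relaxable by flag — no caliper is inherent to the
design). Age ties are broken by a seeded random draw, making the output
a deterministic function of inputs and seed. The package enforces
exactly `ratio × cases` controls; published counts of the reference
analysis (148 controls for 47 cases) differ slightly from 3×47 for
reasons the source does not state (likely per-sequence availability),
and the package does not attempt to reproduce that asymmetry.

Regional WMH is rated on the modified Scheltens scale over 17 named
regions. The package models scores as ordinal 0–6 (the classic Scheltens
ceiling; analyses assume only ordinality, so the ceiling is a config
constant). Presence models dichotomize at score > 0 and use Firth
logistic regression; severity models inverse-normal transform the score
(making them invariant to any monotone relabeling) and use linear
regression, with BH flags at q = 0.05 across regions. Missing FLAIR
nulls the regional scores and lacune counts; missing SWI nulls
microbleed counts.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions of the reference
analysis: n = 200,632 with carrier frequency 443/200,632 (2.2 per 1000,
heterozygous); 11/443 of carriers in EGFR 1–6; binary outcomes from
logistic models with carrier ORs (stroke 2.33 — or 13.60/2.17 when
stratified by domain group — ischaemic stroke 3.07, vascular dementia
5.00, all-cause dementia 2.11, epilepsy 1.92, family history 1.41,
migraine 1.41, depression 0.88); a standard-normal PRS at OR 1.26 per
SD of ischaemic stroke; an MRI subset of 19,686/200,632; log-normal WMH
volume with a 0.52 SD carrier shift and PSMD with 0.72; regional
presence from a latent-logistic threshold model whose carrier presence
OR is exactly the configured one (anterior temporal 7.65, external
capsule 13.32, and plausible values for the remaining regions); and
lacune/microbleed counts from a Bernoulli gate (presence ORs 5.97 and
4.38) times 1 + Poisson.

Baseline prevalences are not part of the published record and are
assumptions chosen to give realistic case counts at cohort scale:
stroke 2%, ischaemic stroke 1.2%, vascular dementia 0.3%, all-cause
dementia 0.6%, epilepsy 1%, migraine 3%, depression 6%, family history
of stroke 25%. Covariates (age uniform 40–70, sex Bernoulli 0.455,
6-level ethnicity, 2-level batch, 10 standard-normal PCs) have zero true
effect by default so that recovery targets isolate the carrier term; a
`confounded` switch adds age/sex effects for testing adjustment.

What the generator deliberately does **not** emulate: sequence-level
genotypes and linkage disequilibrium, realistic PRS construction,
covariate–outcome confounding structure, relatedness, ICD
misclassification, informative MRI subsampling, and site/scanner
effects. Passing recovery tests therefore demonstrates that the
estimators recover the effects they target under the assumed data model
— not that real-data estimates are unbiased against these
real-world complications.

## Recovery-suite problem sizes

The package's own validation suite uses: 200 cohorts of n = 200,632 for
stroke-OR recovery (exponentiated mean log-OR within ±0.05 of the
generating 2.33); 500 MRI subcohorts of n = 19,686 with 47 carriers for
the WMH standardized difference (mean within ±0.02 of 0.52); 50
full-pipeline replicates (generate → classify → analyse) for the
complete set of configured effects, compared within 3-SE Monte-Carlo
bands computed from per-replicate standard errors; 500 null datasets for
profile-CI coverage; and 1000 null replicates of 17 p-values for FDR
control. Mean-recovery bands are meaningful where expected event counts
are adequate (a few events or more per cell); penalized estimates from
cells with expected counts well below one carry a known finite-sample
bias toward zero cells' shrinkage and are not used as recovery targets.

## Population attributable fraction

`population_attributable_fraction()` defaults to Levin's formula
$p(OR-1)/\{1+p(OR-1)\}$ with the carrier frequency as exposure
prevalence; with p = 0.002208 and OR = 2.33 this gives 0.29%. Published
headline PAFs for this analysis (0.26% of stroke) are not reproducible
from the printed inputs by Levin's formula, so Miettinen's case-based
estimator $p_c(OR-1)/OR$ is offered as an alternative and the
discrepancy is left documented rather than resolved by fitting to the
headline number.

## Interfaces and other design decisions

* The package's interface is the R API plus `run_full_analysis()` /
  `write_report()`; tables are plain data frames, serialized as TSV and
  JSON.
* The EGFR domain table ships as a synthetic fixture: a uniform
  34-repeat tiling of residues 40–1373, validated against published
  anchor residues (578 → domain 14, 1231 → domain 31, and classic
  proximal-domain assignments such as Arg90 → domain 2). Inter-domain
  residues and residues outside 40–1373 map to no domain and are never
  carrier-defining. A user-supplied coordinate table is accepted
  everywhere.
* The genomic → protein consequence path uses a reverse-strand
  transcript model on the GRCh38 NOTCH3 gene region with a generated
  coding sequence; consequence calls are validated against a brute-force
  oracle (translate the full mutant CDS and diff) over every coding SNV
  of a test transcript. Exon-level reporting is only emitted when the
  transcript model declares an exon numbering. Multi-nucleotide alleles
  are rejected; multi-allelic records must be split upstream.
* Complete-case analysis per model, with the drop count recorded in
  `n_used`; homozygous carriers are retained and tallied, never assumed
  absent.
* Reporting precision follows field convention (ORs to 2 dp, SD
  equivalents to 2 dp, tail percentages to 1–2 dp), with full-precision
  values in all returned objects.

## Known limitations

* The Firth engine covers the logit link only; no conditional logistic
  or time-to-event models (the battery deliberately uses logistic models
  for incident outcomes as well).
* Profile CIs refit the constrained model ~30 times per bound; for
  p ≈ 15 covariates at n ≈ 200,000 a single profiled CI takes seconds,
  which is why simulation loops default to Wald inference.
* The matching algorithm is greedy, not optimal; with scarce strata the
  seeded processing order can change which of two competing cases gets
  the closer control (by design, reproducibly).
* Synthetic-data realism limits are listed above; no claim is made about
  robustness to confounding structures the generator does not produce.
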