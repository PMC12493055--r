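---
title: "Methods: the exercise-ALS gene-environment analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the exercise-ALS gene-environment analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exals` implements the three computational strategies used to study whether
strenuous leisure-time physical exercise contributes to amyotrophic lateral
sclerosis (ALS) risk in a sex-specific, dose-concentrated way: a two-sample
Mendelian-randomization (MR) battery, a prospective-cohort survival arm, and
a rare-variant loss-of-function (LOF) burden arm.  Individual-level biobank
data are access-controlled, so the package ships synthetic-data generators
that emulate all three input classes with known ground truth; every claim
the test suite makes is a parameter-recovery, calibration, or discrimination
property on those generators.

```{r setup}
library(exals)
```

## Two-sample Mendelian randomization

### Model

For instrument $j$, let $\hat\beta_{Xj}$ (s.e. $\sigma_{Xj}$) be its
association with the exposure (genetic liability to frequent or strenuous
leisure-time exercise) and $\hat\beta_{Yj}$ (s.e. $\sigma_{Yj}$) its
association with the outcome (ALS risk), estimated in independent GWAS.
The per-SNP Wald ratio is
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ and inverse-variance weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.  The IVW estimate is
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$, with a multiplicative
random-effects standard error: the fixed-effect value
$(\sum_j w_j)^{-1/2}$ inflated by $\max\{1, \sqrt{Q/(k-1)}\}$, where $Q$ is
Cochran's heterogeneity statistic.  Excess heterogeneity therefore widens
the interval while under-dispersion never narrows it; the same convention
(with $k-2$ degrees of freedom) scales the MR-Egger slope and intercept.
No formula for the random-effects scaling is universal; this multiplicative
`max(1, .)` rule is the convention of the major MR toolkits and is the one
adopted here.

The battery mirrors the standard published workflow, in this order:

1. **Instrument selection** at exposure $p < 5\times10^{-5}$ (strict).
2. **Greedy LD clumping**: ascending-$p$ iteration, drop any SNP with
   $r^2 \ge 0.001$ to an already-kept SNP within 10,000 kb on the same
   chromosome.  LD arrives as a user-supplied pairwise table; a missing
   entry is treated as $r^2 = 0$ with a logged warning (permissive default,
   loud trace).  Reference-panel proxy lookup is out of scope; unmatched
   variants are dropped and counted.
3. **Harmonization** of outcome betas onto exposure effect alleles: swapped
   labels negate the beta, strand flips resolve through complements, and
   palindromic (A/T, G/C) variants are excluded when the minor-allele
   frequency exceeds 0.42, since their strand is unresolvable near 0.5.
   The *exposure* frequency decides the palindrome filter: the outcome
   frequency enters no statistic, which is what makes the relabeling
   invariance below hold bit-for-bit.
4. **Radial-MR outlier removal** before any other statistical test: a
   single pass flags SNPs whose Q contribution
   $w_j(\hat\theta_j - \hat\theta)^2$ exceeds the $\chi^2_1$ upper-$\alpha$
   tail at $\alpha = 0.05$ per SNP.  Iterated removal exists behind a flag
   but is off by default, matching the remove-once convention.
5. **Pleiotropy filter**: drop instruments with outcome $p$ strictly below
   exposure $p$ (a literal reading of "lower"), guarding against reverse
   causation.
6. **Estimators and sensitivity statistics**: IVW, MR-Egger slope and
   intercept (instruments oriented to $\hat\beta_{Xj} \ge 0$, the standard
   treatment that identifies the intercept), weighted median (cumulative
   inverse-variance weight 0.5 with linear interpolation), weighted mode
   (weighted Gaussian KDE argmax), Cochran's $Q$, $I^2$, mean $F$, and
   leave-one-out IVW.

### Numerical and design choices

* **Wald-ratio standard error** uses the first-order delta method; the
  exposure-side sampling term is ignored, which is the standard default
  and slightly anti-conservative for weak instruments (hence the mean-$F$
  report with its conventional $F > 10$ bar).
* **Weighted median/mode standard errors** have no closed form and come
  from a parametric bootstrap (default 1000 replicates, explicit seed):
  ratios are resampled from $N(\hat\theta_j, \text{se}_j)$ and the point
  estimator recomputed per draw.
* **Mode bandwidth** is a modified-Silverman scale,
  $0.9\,\min(\text{sd}, \text{mad})\,k^{-1/5}$, times a user factor
  (default 1).  Identical ratios have zero spread; a tiny positive floor
  keeps the kernel proper (the argmax is that shared ratio regardless).
* **Two $I^2$ variants** are reported.  The heterogeneity $I^2$,
  $\max\{0, (Q-(k-1))/Q\}$, measures dispersion of the per-SNP causal
  estimates.  The instrument-strength variant ($I^2_{GX}$, computed from
  exposure-side dispersion) measures how far instrument effects exceed
  their sampling noise; low values signal regression-dilution bias toward
  the null in Egger-type estimates.  Published sensitivity tables do not
  always say which of the two they print, so both are exposed.

### What the generator emulates

`gen_sumstats()` draws independent instruments (the post-clumping state; no
LD between instruments is simulated) with true exposure effects uniform on
$[0.01, 0.05]$, oriented positive — the convention for instruments selected
and aligned to the exposure-increasing allele.  This orientation matters:
with random-sign exposure effects, directional pleiotropy in the outcome
becomes sign-balanced in ratio space and the weighted-median breakdown
property would be undefined.  Standard errors follow the GWAS asymptotic
$1/\sqrt{2p(1-p)n}$ with default sample sizes 175,000 (exposure) and
80,000 (outcome), giving mean $F$ comfortably above the weak-instrument
bar.  Pleiotropic direct effects hit a Bernoulli fraction of SNPs — mean
zero ("balanced") or shifted ("directional", default mean 0.1, spread
0.01) — and planted outliers inflate the direct effect at least tenfold.
Real summary statistics additionally carry LD, allele-frequency errors and
sample overlap, none of which is emulated; passing tests therefore
establish correctness of the estimators and filters, not robustness to
those artefacts.

## Cohort survival arm

`cox_fit()` maximizes the Efron-tie-corrected Cox partial likelihood
(via the `survival` package) of event hazard on activity dose plus named
covariates.  Two time scales are supported — follow-up interval and
attained age — both adjusting for enrolment age as a covariate rather than
left-truncating, mirroring the questionnaire-study convention of
controlling for age at enrolment.  `hazard_ratio()` rescales a coefficient
to a stated dose contrast (e.g. $\exp(\hat\beta \cdot 100)$ for "HR per
100 kJ/min"); `met_equivalent()` converts power to METs through
1 kcal/kg/h and 4.184 kJ/kcal, so 100 kJ/min in an 80 kg person is
about 17.9 MET.

The **sliding-removal sensitivity procedure** asks whether a dose
association is driven by the heaviest exercisers: rank participants by
dose descending, remove each contiguous window of 20 (step 1, so
consecutive windows overlap by 19), refit, and correlate the removed
subset's mean dose with the refitted dose coefficient (Pearson, two-sided
t-based $p$).  For a positive dose effect concentrated at high doses, the
coefficient collapses exactly when the top windows are removed, giving a
negative correlation; under a homogeneous effect no systematic trend
exists.  The correlation is computed against the fitted coefficient (the
quantity the procedure's published figure plots), not against symptom-onset
age directly; failed reduced fits are excluded from the correlation with a
logged count rather than aborting the scan.  Note one honest caveat:
overlapping windows make consecutive coefficients highly autocorrelated,
so under the null the per-replicate $|r|$ can be sizeable even though it
is centred at zero — which is why the discrimination test compares
distributions across replicates rather than thresholding a single $r$.

`gen_cohort()` draws a zero-inflated log-normal dose (default 25%
non-exercisers, median 1,200 MET-min/week, log-sd 1 — the right-skewed
shape of questionnaire activity data; the exact IPAQ-style MET derivation
is not public, so the distribution is emulated in shape only), exponential
event times with hazard
$\lambda_0 \exp\{\beta\, f(\text{dose})\}$ and independent exponential
censoring.  $f$ is the identity or, under the threshold model,
$\text{dose}\cdot 1[\text{dose} > q]$ with $q$ a dose *quantile* (default
0.9), keeping the model scale-free across activity units.  The constant
baseline hazard makes the Cox coefficient's target exact.  For the
discrimination experiments the package uses $\beta = \log(2)/5000$ per
MET-min/week — hazard ratio 2 at 5,000 MET-min/week, the "very strenuous
exerciser doubles their hazard" magnitude — with $n = 400$, window 20,
step 1 (381 refits per cohort).

## Rare-variant burden arm

`classify_extreme()` reduces the two questionnaire activity classes to
weekly hours (frequency category times duration band, both mapped to their
*lower* bounds, so computed hours never overstate a report and strict
"more than" thresholds are guaranteed; midpoint mapping is available) and
labels a participant *extreme* when strenuous hours exceed 6 or other
leisure-time exercise exceeds 12, *sedentary control* when both are zero.
The summary rule is implemented rather than the published enumeration of
category combinations, because that enumeration joins mutually exclusive
frequency categories conjunctively and cannot be evaluated as written;
the summary rule reproduces its intent.

`burden_scan()` filters variants to rare (MAF strictly below 1%) LOF
(nonsense or splice-site) consequences, collapses each gene to a
per-sample carrier indicator (allele-count mode behind a flag), and tests
carrier status against the phenotype with **Firth-penalized logistic
regression** plus covariates, adjusting across genes by Benjamini-Hochberg.
The Firth fit maximizes $\ell(\beta) + \tfrac12\log\det I(\beta)$ by
Newton iteration on the hat-adjusted score with step-halving; the Jeffreys
penalty keeps estimates finite under the complete separation that ultra-
rare carriers routinely produce.  Per-coefficient $p$-values use the
penalized likelihood-ratio test (refit with the column removed), which is
better calibrated than Wald at rare carrier counts.  Published methods for
this design name both SKAT-O and Firth regression; the reported odds
ratios are Firth quantities, so Firth is the engine implemented here and
SKAT-O is out of scope.  The default significance cutoff is FDR < 0.05,
with the stricter 0.01 available as an argument.  Sex-stratified scans are
run by subsetting the phenotype table; no interaction model is fitted.

Gene-set overlap (`set_overlap_test()`) builds the 2x2 membership table
over a stated universe and applies the conditional hypergeometric
(Fisher) test; `enrichment_scan()` repeats this across annotation sets
with BH adjustment.  The reported odds ratio is the sample cross-product
$ad/bc$; the Haldane 0.5 correction is applied only when the denominator
vanishes, since correcting a zero *numerator* in a large-universe table
would flip an honest depletion (OR 0) into spurious enrichment.

`gen_genotypes()` plants two qualifying LOF variants (per-variant allele
frequency `carrier_freq/4`, below the 1% bar) plus one common missense
decoy per gene, with case carrier odds multiplied by the configured odds
ratio for signal genes.  Default contrast: 2,000 cases vs 2,000 controls
over 200 genes with 2% background carrier frequency — a desk-scale
miniature of an extreme-exerciser vs sedentary biobank contrast (three
orders of magnitude smaller), so power statements transfer only
qualitatively.

## Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed; one global
pipeline seed expands to per-stage sub-seeds by a fixed counter scheme
(`stage_seed()`), so a stage re-run alone sees the stream it saw in the
full run.  Writers serialize doubles with 17 significant digits, making
write-then-read exact, and stamp a `#` header block with version,
parameters and seed.

The validation suite sizes its simulations for a desk machine: 500
replicates for IVW recovery and coverage, 1,000 for Egger test size, 200
for breakdown and outlier detection, 100 cohorts per arm of the
sliding-removal discrimination experiment, 50 burden-scan replicates, and
exhaustive sweeps for the exact tests (every 2x2 table with total at most
30; every separated carrier configuration with $n \le 12$).  These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands.

## Known limitations

* No LD structure among instruments and no reference-panel proxy lookup;
  clumping consumes a user-supplied pairwise $r^2$ table.
* The first-order Wald standard error and the `max(1, .)` random-effects
  convention are defaults, not the only defensible choices.
* The cohort arm fits no left-truncated risk sets and no proportionality
  diagnostics; questionnaire measurement error is not modelled.
* The burden arm consumes pre-annotated consequences; VCF parsing and
  VEP-style annotation are out of scope, as is SKAT-O.
* Generator realism is deliberately minimal (independent instruments,
  exponential times, Bernoulli carriers): sufficient for correctness and
  calibration claims, not a substitute for real-data robustness studies.
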