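# exals

Gene–environment analysis of physical exercise and amyotrophic lateral
sclerosis (ALS) risk: a reusable, tested implementation of the three
computational arms such studies combine, exercisable end to end on
synthetic data with known ground truth.

**Who it is for.** Biostatisticians and genetic epidemiologists who want
the full analysis machinery of an exercise–ALS (or any exposure–disease)
gene–environment study — not the access-controlled biobank data — as
composable R functions with a validation surface.

## What it implements

1. **Two-sample Mendelian randomization** (`run_mr_battery()`):
   instrument selection (exposure *p* < 5×10⁻⁵), greedy LD clumping
   (r² ≥ 0.001 within 10,000 kb), allele harmonization with palindrome
   exclusion (MAF > 0.42), radial-MR outlier removal, an
   outcome-vs-exposure *p*-value pleiotropy filter, then IVW
   (multiplicative random effects), MR-Egger slope and intercept,
   weighted median and weighted mode, with Cochran's *Q*, *I*², mean *F*
   and leave-one-out sensitivity. Per SNP *j* the Wald ratio is
   θ̂ⱼ = β̂ᵧⱼ/β̂ₓⱼ with weight wⱼ = β̂ₓⱼ²/σᵧⱼ², and
   θ̂ᵢᵥᵥ = Σwⱼθ̂ⱼ / Σwⱼ with standard error
   (Σwⱼ)^(-1/2) · max{1, √(Q/(k−1))}.
2. **Cohort survival dose–response** (`cox_fit()`, `hazard_ratio()`,
   `kaplan_meier()`, `dose_quartiles()`,
   `sliding_removal_sensitivity()`): Efron-tie Cox fits of event hazard
   on activity dose, hazard-ratio rescaling to stated dose contrasts
   (e.g. HR per 100 kJ/min), quartile Kaplan–Meier contrasts, and the
   sliding-window removal sensitivity procedure — remove each contiguous
   window of 20 participants by descending dose rank (step 1), refit,
   and correlate the removed subset's mean dose with the refitted
   coefficient.
3. **Rare-variant LOF burden testing** (`classify_extreme()`,
   `lof_filter()`, `burden_scan()`, `firth_logistic()`,
   `set_overlap_test()`, `enrichment_scan()`): extreme-exercise
   phenotype classification (> 6 h strenuous or > 12 h other
   leisure-time exercise weekly), rare (MAF < 1%) nonsense/splice-site
   filtering, per-gene carrier collapsing, Firth-penalized logistic
   regression (finite under complete separation; penalized-LRT
   *p*-values) with Benjamini–Hochberg FDR, and Fisher-exact gene-set
   overlap and enrichment.

Synthetic generators (`gen_sumstats()`, `gen_cohort()`,
`gen_genotypes()`, `gen_gene_sets()`) emulate all three input classes
with controllable causal effects, pleiotropy, threshold-concentrated
hazards and per-gene carrier odds ratios. Plain TSV/CSV readers/writers
and an end-to-end `run_pipeline()` (plus a thin CLI at
`inst/cli/exals-cli.R`) tie the stages together reproducibly; every
stochastic step takes an explicit seed.

## Worked example

```r
library(exals)

## -- MR arm: known causal effect theta = 0.1 --------------------------
ss <- gen_sumstats(sumstat_sim_config(n_snps = 120, theta = 0.1, seed = 7))
report <- run_mr_battery(ss$exposure, ss$outcome, mr_config(seed = 7))
print(report)
#> Two-sample MR report
#>   instruments: 102 selected, 94 analysed
#>   IVW              beta =   0.1122  se =  0.0162  p = 4.08e-12
#>   Egger-slope      beta =   0.1337  se =  0.0609  p = 0.0307
#>   Egger-intercept  beta =  -0.0008  se =  0.0022  p = 0.716
#>   weighted-median  beta =   0.1280  se =  0.0223  p = 8.92e-09
#>   weighted-mode    beta =   0.1446  se =  0.0529  p = 0.00631
#>   Cochran's Q = 65.171 (p = 0.987), I2 = 0.000, I2_GX = 0.842
#>   mean F = 88.81
#>   radial outliers removed: 5; LOO rows with p > 0.05: 0
```

All five estimators bracket the true θ = 0.1; the Egger intercept is
consistent with no directional pleiotropy (none was simulated), mean
*F* ≈ 89 clears the weak-instrument bar of 10, and the heterogeneity
*I*² of 0 against an instrument-strength *I*²(GX) of 0.84 shows why both
variants are reported.

```r
## -- Survival arm: effect confined above the 90th dose percentile -----
co <- gen_cohort(cohort_sim_config(n = 400, effect_model = "threshold",
                                   beta_dose = log(2) / 5000,
                                   threshold_quantile = 0.9,
                                   activity_sdlog = 1, seed = 7))
sens <- sliding_removal_sensitivity(co, window = 20, step = 1)
print(sens)
#> Sliding-removal sensitivity: 381 windows of 20 (step 1), 0 failed
#>   Pearson r = -0.423 (p = 5.61e-18)
hazard_ratio(cox_fit(co), delta = 5000)
#> [1] 1.71
```

The negative correlation says the dose association weakens exactly when
the heaviest exercisers are removed — the signature of a
threshold-concentrated effect.

```r
## -- Burden arm: one planted gene with carrier odds ratio 10 ----------
g <- gen_genotypes(genotype_sim_config(n_cases = 2000, n_controls = 2000,
                                       n_genes = 50, carrier_freq = 0.02,
                                       signal_genes = data.frame(gene = 7L,
                                                                 or = 10),
                                       seed = 7))
scan <- burden_scan(g$carriers, g$variants, g$phenotypes,
                    covariates = c("cov1", "cov2"))
head(as.data.frame(scan), 3)
#>      gene carriers_cases carriers_controls odds_ratio   pvalue      fdr
#> 1 GENE007            354                32     13.040 2.41e-77 1.21e-75
#> 2 GENE017             49                28      1.758 3.00e-03 7.49e-02
#> 3 GENE004             34                54      0.626 5.49e-03 9.14e-02
```

The planted gene ranks first with an odds ratio near its simulated
value; the 49 null genes stay above the FDR bar.

See `vignettes/exercise-als-methods.Rmd` for the models, assumptions,
parameter defaults and known limitations.

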