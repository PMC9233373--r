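# deltameth

Paired differential DNA methylation and prognostic risk scoring for
neoadjuvant chemotherapy (NACT) cohorts.

Locally advanced breast cancer is treated with chemotherapy before surgery,
and tumor biopsies taken before and after treatment let us ask how the
tumor's DNA methylation responds — and whether that response predicts
long-term survival. `deltameth` implements the full analysis pipeline for
such a design on Illumina 450k-style data: array preprocessing, paired
differential methylation, genomic-region and toward-normal characterisation
of the changes, gene-set overrepresentation, immune-cell deconvolution, a
delta-beta LASSO risk score, and Kaplan–Meier / log-rank evaluation.
Because patient-level data from such trials are access-restricted, the
package ships a seeded synthetic-cohort generator that emulates the study
design (83 patients; 55 pre- and 75 post-treatment samples; 47 complete
pairs; survivor-specific change), so every stage is testable end to end.

## The model at the core

Methylation is analysed on the M scale, `M = log2(beta / (1 - beta))`.
For each CpG *g*, pre/post samples are compared with a generalized
least-squares fit of `M ~ timepoint` under a block-equicorrelated
covariance: a single consensus intra-patient correlation ρ (the 15%-trimmed
mean, on the atanh scale, of per-CpG REML estimates of the patient
random-intercept variance ratio) is shared across CpGs, so paired samples
inform the fit without discarding the 36 unpaired samples. Residual
variances are shrunk with an empirical-Bayes scaled-inverse-chi-square
prior (`s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, moment-matched on
log s²), giving moderated t statistics; Benjamini–Hochberg adjusted
p < 0.01 defines differentially methylated sites.

The prognostic score is built from the paired patients' methylation change
Δβ = β_post − β_pre at the significant CpGs: leave-one-out L1-penalised
logistic regression of 5-year survival, keeping CpGs with nonzero
coefficients in > 80% of the leave-one-out fits and averaging their nonzero
coefficients, so the frozen score is `R_i = Σ_j w_j Δβ_ij`. Risk groups
(held-out predictions in the discovery cohort; median cutoff in external
cohorts) are compared by Kaplan–Meier curves and the log-rank test.

## Worked example

```r
library(deltameth)

config <- simulation_config(seed = 1)        # the emulated study design
cohort <- generate_cohort(config)

# preprocessing: detection filter -> type-II peak correction -> quantile norm
filt <- detection_filter(cohort$beta, cohort$detp)
pc   <- peak_correct_type2(beta_to_m(filt$beta), cohort$annot)
beta <- quantile_normalize(m_to_beta(pc$m))

# paired differential methylation within 5-year survivors
survivors <- dplyr::filter(cohort$sheet, survival_group == "survivor")
dm <- diff_methylation(beta, survivors, alpha = 0.01)
glance(dm)
#> # A tibble: 1 x 7
#>   n_cpgs n_significant alpha consensus    d0  s0_2 n_skipped
#>    <int>         <int> <dbl>     <dbl> <dbl> <dbl>     <int>
#> 1   2000           279  0.01     0.479  175. 0.268         0
```

2,000 simulated CpGs, 279 significant at BH < 0.01 (the generator planted
300 survivor-specific changes, mean |ΔM| = 1), and a consensus
intra-patient correlation of 0.48 against a simulated 0.5.

```r
# delta-beta risk score on the paired patients
dB  <- build_delta_beta(beta, cohort$sheet, dm$cpg_id[dm$significant])
sel <- loo_lasso_select(dB, five_year_death(cohort$sheet, dB$patient_id))
risk_group_survival(assign_groups_loo(sel$loo), cohort$sheet)
#> high risk: n = 14, events = 14, median survival = 1.726 years
#> low risk: n = 33, events = 11, median survival = not reached
#> log-rank chi-square = 68.34, p = 1.379e-16
```

The leave-one-out-predicted risk groups separate the simulated 10-year
survival sharply, as the generator couples survival to the planted
delta-beta at 4 causal CpGs. `autoplot()` methods draw the volcano,
region, fraction and survival figures; `run_pipeline(config, outdir)`
executes all stages (regions, toward-normal statistic, enrichment,
deconvolution, risk, survival) and writes every artifact with provenance.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the
synthetic cohort (generation, preprocessing, differential methylation,
regions, enrichment, deconvolution, risk model, discovery and validation
survival analysis), seeded by `--seed`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It logs the stage summaries, leaves all pipeline artifacts next to the
output file, and writes the JSON report to `--out`.
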