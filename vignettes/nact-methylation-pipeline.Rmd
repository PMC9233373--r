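---
title: "Methods: paired methylation change and prognostic scoring after NACT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired methylation change and prognostic scoring after NACT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltameth)
```

# The problem

Tumor biopsies taken before and after neoadjuvant chemotherapy (NACT) in
locally advanced breast cancer give a partially paired design: some
patients contribute both a pre- and a post-treatment 450k methylation
profile, others only one. The questions the pipeline answers are (i) which
CpGs change during treatment, within clinically defined subgroups (5-year
survivors vs non-survivors, responders vs non-responders, treatment arms);
(ii) where in the genome the changes sit and whether they move the tumor
toward the methylation state of normal breast tissue; (iii) whether the
changes implicate particular gene sets or shifts in immune-cell
composition; and (iv) whether a sparse linear score on the per-patient
methylation change predicts long-term survival.

# The differential model

Modelling is done on M-values, `M = log2(beta/(1-beta))`, the
variance-stabilised scale for array methylation; betas are clipped to
`[epsilon, 1-epsilon]` with `epsilon = 1e-3` first so boundary values stay
finite (the clipping bound only matters for betas within 0.001 of 0 or 1,
far outside the simulated and typical observed range).

A full per-CpG mixed model is replaced by the standard two-stage
consensus-correlation approximation:

1. **Consensus correlation.** Per CpG, the model
   `M ~ timepoint + (1 | patient)` is fit by REML, parameterised directly
   by the intra-patient correlation `rho = var(intercept)/var(total)`. The
   profiled REML criterion for the block-equicorrelated GLS problem is
   evaluated on a 60-point `rho` grid (range [-0.45, 0.98]) simultaneously
   for all CpGs by block whitening, and each CpG's optimum is refined with
   a parabolic step. The grid-plus-refinement strategy computes the same
   estimand as a per-CpG optimiser but vectorises across CpGs; grid
   resolution (~0.024 before refinement) is far below the sampling noise
   of a single-CpG estimate. Slightly negative values are allowed so that
   estimates at a true correlation of zero scatter on both sides instead
   of piling on a boundary, which would bias the consensus upward. The
   consensus is `tanh(mean(atanh(rho_g), trim = 0.15))`; constant or
   incomplete CpGs are excluded and counted. By default the consensus uses
   an evenly spaced subset of 500 CpGs (a single scalar is being
   estimated; the subset is deterministic so runs are reproducible).

2. **Per-CpG GLS.** With the consensus `rho` fixed, each CpG is fit by
   generalized least squares under the block covariance (correlation `rho`
   within a patient's pre/post pair, zero elsewhere; unpaired samples are
   singleton blocks), yielding the effect `delta = post - pre` (M scale),
   residual variance and df. CpGs with missing values take a per-CpG
   whitening path; CpGs with fewer than 3 non-missing samples in either
   timepoint are skipped with a logged reason (the source analysis is
   silent on missingness; we exclude per fit rather than impute).

3. **Moderation and control.** Residual variances are shrunk with the
   scaled-inverse-chi-square empirical-Bayes prior estimated by moment
   matching on `log s^2` (digamma/trigamma inversion). When the observed
   log-variance spread is no larger than expected from chi-square noise,
   the prior df is infinite and the prior variance is set to the geometric
   mean of the variances — so if all variances coincide, the posterior
   equals that common value. Moderated t statistics use `df_g + df_prior`
   degrees of freedom; BH-adjusted p < 0.01 (configurable `alpha`) defines
   significance; `direction` is `gain` iff the effect is positive.

A property worth knowing: in a fully paired design the GLS effect equals
the mean within-pair difference for any `rho`, but the GLS *t* does not
converge to the textbook paired *t* in the `rho -> 1` limit, because the
profiled residual variance pools pre-sample and difference information
with `n - 2` rather than `n_pairs - 1` df. The tests therefore assert the
exact effect identity and the close tracking of the paired *t* at strong
correlation, not a degenerate limit equality.

# Genomic context and the toward-normal statistic

CpGs are classified by the cross of genomic context (promoter, gene body,
intergenic) and CpG-island status; per region, the gain and loss
proportions are significant counts divided by all array CpGs in the
region. The toward-normal statistic compares subgroup-level mean betas:
a significant site moves toward normal iff
`|mean_post - mu_normal| < |mean_pre - mu_normal|`, with ties counted as
not-toward (conservative). Mean-level rather than per-sample distances are
used because the reference itself is a per-CpG mean over normal tissues;
the group means are taken over the same subgroup (survivors) the
significant sites came from.

# Enrichment

Overrepresentation of significant-CpG-bearing genes in user-supplied GMT
gene sets is tested against a permutation null that draws
`length(significant_genes)` genes from the universe without replacement
with probabilities proportional to a probe-count bias weight: an isotonic
fit of P(gene has a significant CpG) against log probe count over
probe-count bins, floored and normalised to mean 1. Genes with many array
probes are more likely to carry a significant CpG by chance alone; the
weighting builds that into the null instead of approximating it with a
noncentral hypergeometric. `p = (1 + #{null >= obs}) / (1 + n_perm)` never
returns 0; BH across the sets of one region-by-direction stratum gives the
FDR (per-stratum, matching "each analysis"). With uniform weights the
permutation p converges to the hypergeometric tail, which the tests verify
against the exact distribution. Term databases are supplied as files, never
fetched; `synthetic_gene_sets()` builds random stand-ins for pipeline runs.

# Deconvolution

Immune fractions per sample solve the constrained least-absolute-deviation
problem `min_f sum_i |beta_i - sum_k f_k S_ik|` subject to `f >= 0`,
`sum f <= 1`, then rescale to relative fractions `f / sum f`. No linear
programming solver is installed in the target environment, so the LAD
objective is minimised by iteratively reweighted least squares with
quadprog-solved constrained subproblems (weights `1/max(|r_i|, 1e-6)`,
tolerance 1e-10, at most 60 iterations); on noise-free mixtures the first
subproblem already attains the zero-residual optimum exactly. Pre/post
fraction comparisons use the unpaired Wilcoxon rank-sum test — a
faithful-reproduction choice despite the partially paired design — with
exact enumeration up to 12 pooled observations and the tie- and
continuity-corrected normal approximation beyond.

# The risk score

Candidates default to the significant CpGs of the survivor comparison.
For the paired patients, `delta beta = beta_post - beta_pre` per candidate
enters a leave-one-out L1-penalised logistic regression of death within
five years. Within each LOO fit, lambda is chosen by seeded inner 5-fold
cross-validation; the **one-standard-error rule** is the default rather
than the raw deviance minimiser. The reason is observable in the package's
own null simulations: LOO training sets overlap in all but one patient, so
a covariate the deviance minimiser picks up by chance is picked up in
nearly every LOO refit and sails through the >80% stability filter —
permuted outcomes then yield non-empty "stable" models in a material
fraction of runs. Under the one-standard-error rule permuted outcomes
yield the empty model, while strongly coupled causal CpGs are still
selected in every fit. The raw minimiser remains available
(`lambda_rule = "min"`).

The final model keeps CpGs nonzero in more than 80% of completed LOO fits
(fits whose training fold lost an outcome class are skipped and counted),
with coefficients the mean of their nonzero values; an empty selection is
returned explicitly and scores everyone 0. Discovery risk groups come from
the held-out predictions; the default rule is high risk iff the held-out
death probability is at least 0.5 (ties high). The alternative
(`rule = "train_median"`, high iff the held-out linear predictor exceeds
the training median) is implemented but not default: a forced median split
assigns half the cohort to high risk regardless of evidence and measurably
dilutes the survival separation. External cohorts use the frozen score
with a median cutoff, ties to low; the delta-beta orientation
(post - pre) and outcome coding are stored inside the serialised model so
frozen models are portable. Selection is invariant to candidate column
order up to coordinate-descent numerics (identical stable sets; selection
frequencies can differ by a fit or two for marginal covariates).

# Survival

Kaplan–Meier curves, median survival (smallest t with `S(t) <= 0.5`) and
the 1-df chi-square log-rank test are delegated to the survival package
behind the package's tabular interface; the tests hold them to hand
computations and a brute-force observed-minus-expected oracle. Curves with
no events return `S == 1` and an undefined median; evaluation beyond the
last observed time returns the last value with an extrapolation flag.

# The synthetic cohort: what it emulates, and what it does not

The generator states the emulated design once, as defaults: 83 patients
(8 pre-only, 28 post-only, 47 paired; 59 survivors, matching the reported
Table-1 proportions for response, treatment arm, stage and subtype);
2,000 CpGs with bimodal baseline M (unmethylated mode -3, methylated mode
+2.5, sd 0.8; CpG-island sites 80% unmethylated, non-island reversed; 30%
type-I probes); total residual sd 0.5 on the M scale split by an
intra-patient correlation of 0.5; 300 affected CpGs in survivors with loss
at island sites and gain elsewhere, |dM| folded-normal with mean 1 (a
`"constant"` option fixes |dM| exactly); detection p-values failing at
rate 0.01; an optional multiplicative type-II mode compression used only
to exercise peak correction. Affected sites draw their baseline from the
intermediate range M in [-2, 2]: a site saturated at beta near 0 or 1 has
no beta-scale room to change, and planting "responsive" sites there would
produce ghost effects invisible to every beta-scale statistic.

Survival is exponential with log-hazard `hazard_coefficient` times the
true risk score (the planted-weight sum of noise-free causal delta-betas),
administratively censored at 10 years. Survival-group labels are assigned
first (the group sizes are part of the stated design) and times are drawn
conditionally on the label — non-survivors truncated to death before five
years, survivors memorylessly beyond five — which preserves both the exact
group sizes and the stochastic ordering between true risk and
pre-censoring survival. Causal CpGs (a subset of the affected ones) carry
independent per-patient lognormal effect modifiers (sd 0.5): with a single
shared modifier all causal delta-betas would be collinear copies of one
latent factor and any LASSO would arbitrarily drop the redundant ones.
Survivors' other affected sites share one lognormal (sd 0.2) modifier.

The normal-tissue reference is constructed against the realised survivor
group means, putting exactly `round(toward_normal_fraction * n_affected)`
affected CpGs on the far side of the post-treatment mean (toward) and the
rest at the pre-treatment mean (away), so the toward-normal statistic on
the truth set equals the configured fraction exactly. Immune mixtures mix
uniform random signature profiles with per-patient Dirichlet fractions
(concentration 8 per cell type, 24 for regulatory T cells, giving a
regulatory-T mean near 0.27 with sd about 0.06 — tight enough that a 0.05
shift is a detectable effect, as in the emulated analysis); survivors'
post-treatment samples have the regulatory-T fraction reduced by exactly
`treg_shift`, the freed mass redistributed proportionally so fractions
still sum to one.

What the generator does **not** emulate: probe-level chemistry beyond the
single type-II scale factor, background or dye bias, tumor purity and
copy-number effects, batch structure, correlated CpG blocks along the
genome, or biologically structured gene sets. A green test therefore
establishes that the estimators recover the stated statistical structure
at the stated scales — not that the pipeline is robust to artifacts the
generator does not contain.

# Numerical and procedural choices

- Preprocessing order: detection filter (betas) -> type-II peak correction
  (M-values; Gaussian kernel, Silverman bandwidth, 512-point grid on
  [-8, 8], per-sample unmethylated/methylated modes per probe type) ->
  quantile normalisation (betas, mean-quantile reference, ties receive the
  mean of tied reference values, missing values interpolate the reference
  at their own quantile grid) -> M-values for modelling. The source lists
  the steps but not their scales; these are the package's choices.
- The detection filter removes a site iff strictly more than 75% of its
  measurements have detection p >= 0.05 (the literal reading of the
  filtering rule); both knobs are exposed.
- Percentage rendering in the cohort summary rounds half up to one
  decimal, matching the published table's style.
- Seeds: every stochastic routine takes or derives an explicit seed;
  derived seeds stay below 2^31.

# Limitations

- The consensus-correlation GLS is an approximation to a full per-CpG
  mixed model; with very few paired patients the consensus is noisy and
  everything downstream inherits that noise.
- The enrichment null conditions on the number of significant genes, not
  on inter-gene correlation of methylation.
- Survival machinery covers two-group product-limit comparison only; no
  Cox regression or competing risks.
- The acceptance-level behaviour of the risk model is demonstrated in a
  strong-coupling regime (constant |dM| = 2 at causal sites); weaker or
  collinear signals will show partial selection frequencies by design.
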