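# Seeded synthetic cohort generator emulating the design of a pre/post
# neoadjuvant chemotherapy (NACT) methylation study: 83 patients with 55
# pre- and 75 post-treatment samples (47 complete pairs), survivor-specific
# methylation change (loss at CpG islands, gain outside), a normal-tissue
# reference placed so a configurable fraction of changes move toward normal,
# survival times coupled to the planted delta-beta at a few causal CpGs,
# and immune mixtures with a post-treatment regulatory-T decrease in
# survivors.

#' Simulation configuration
#'
#' Defaults state the emulated study design: 83 patients (8 pre-only, 28
#' post-only, 47 paired; 59 survivors), 2,000 CpGs with 300 affected in
#' survivors (mean |dM| = 1 on the M scale), residual sd 0.5 with
#' intra-patient correlation 0.5, 4 causal CpGs driving an exponential
#' survival model censored at 10 years, 90% of planted changes toward the
#' normal-tissue mean, and a 0.05 post-treatment regulatory-T decrease in
#' survivors.
#'
#' @param n_patients Number of patients.
#' @param n_pre_only,n_post_only Patients with only one timepoint.
#' @param pair_fraction Optional; checked against the counts when given.
#' @param n_cpg Number of CpGs.
#' @param fraction_cgi Fraction of CpGs in CpG islands.
#' @param n_affected_cpgs CpGs with a planted survivor pre-to-post shift.
#' @param effect_size_m Mean |dM| of the planted shift.
#' @param effect_distribution `"folded_normal"` (|dM| ~ folded normal with
#'   mean `effect_size_m`) or `"constant"` (|dM| = `effect_size_m` at every
#'   affected CpG).
#' @param noise_sd_m Total per-measurement sd on the M scale.
#' @param intra_patient_correlation Share of variance from the patient
#'   random intercept, in `[0, 1)`.
#' @param n_causal_cpgs Affected CpGs whose delta-beta drives survival.
#' @param hazard_coefficient Log-hazard per unit of true risk score.
#' @param censor_time Administrative censoring time (years).
#' @param toward_normal_fraction Fraction of affected CpGs whose planted
#'   change moves toward the normal-tissue mean.
#' @param treg_shift Post-treatment decrease of the regulatory-T fraction in
#'   survivors.
#' @param seed Integer seed; every generator output is a pure function of it.
#' @param survivor_fraction Fraction of patients in the survivor group.
#' @param detection_fail_rate Per-measurement probability of a failed
#'   detection p-value.
#' @param type2_scale Multiplicative compression of type-II probe M-values
#'   (1 = no probe-type artifact).
#' @param effect_heterogeneity_sd Lognormal sd of the per-survivor effect
#'   modifier shared across affected sites.
#' @param causal_heterogeneity_sd Lognormal sd of the independent
#'   per-patient, per-causal-CpG effect modifier.
#' @param baseline_hazard Baseline exponential hazard (per year).
#' @param fraction_type1 Fraction of type-I probes.
#' @param n_cell_types,n_signature_cpgs,mixture_noise_sd Immune-mixture
#'   defaults for [generate_immune_mixtures()].
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_patients = 83,
                              n_pre_only = 8,
                              n_post_only = 28,
                              pair_fraction = NULL,
                              n_cpg = 2000,
                              fraction_cgi = 0.35,
                              n_affected_cpgs = 300,
                              effect_size_m = 1,
                              effect_distribution = c("folded_normal",
                                                      "constant"),
                              noise_sd_m = 0.5,
                              intra_patient_correlation = 0.5,
                              n_causal_cpgs = 4,
                              hazard_coefficient = 8,
                              censor_time = 10,
                              toward_normal_fraction = 0.9,
                              treg_shift = 0.05,
                              seed = 1,
                              survivor_fraction = 59 / 83,
                              detection_fail_rate = 0.01,
                              type2_scale = 1,
                              effect_heterogeneity_sd = 0.2,
                              causal_heterogeneity_sd = 0.5,
                              baseline_hazard = 0.15,
                              fraction_type1 = 0.3,
                              n_cell_types = 6,
                              n_signature_cpgs = 200,
                              mixture_noise_sd = 0.02) {
  cfg <- as.list(environment())
  cfg$effect_distribution <- match.arg(effect_distribution)
  for (nm in c("n_patients", "n_cpg")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 1)
  }
  for (nm in c("n_pre_only", "n_post_only", "n_affected_cpgs",
               "n_causal_cpgs")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  for (nm in c("fraction_cgi", "toward_normal_fraction", "survivor_fraction",
               "detection_fail_rate", "fraction_type1", "treg_shift")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0, upper = 1)
  }
  assert_scalar_number(cfg$intra_patient_correlation,
                       "intra_patient_correlation", 0, 1 - 1e-9)
  assert_scalar_number(cfg$effect_size_m, "effect_size_m", lower = 0)
  assert_scalar_number(cfg$noise_sd_m, "noise_sd_m", lower = 0)
  assert_scalar_number(cfg$censor_time, "censor_time", lower = 0)
  if (cfg$n_causal_cpgs > cfg$n_affected_cpgs) {
    abort("n_causal_cpgs must be <= n_affected_cpgs")
  }
  if (cfg$n_affected_cpgs > cfg$n_cpg) abort("n_affected_cpgs must be <= n_cpg")
  n_paired <- cfg$n_patients - cfg$n_pre_only - cfg$n_post_only
  if (n_paired < 0) abort("n_pre_only + n_post_only exceeds n_patients")
  if (!is.null(pair_fraction) &&
      round(pair_fraction * cfg$n_patients) != n_paired) {
    abort("pair_fraction inconsistent with n_pre_only / n_post_only")
  }
  cfg$pair_fraction <- n_paired / cfg$n_patients
  cfg$n_paired <- n_paired
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic pre/post NACT methylation cohort
#'
#' Draws M-values per CpG as baseline + patient random intercept + residual
#' noise (variance split by `intra_patient_correlation`), shifts survivors'
#' post-treatment samples at affected CpGs (loss at CGI sites, gain at
#' non-CGI sites, per-survivor lognormal effect modifier), converts to betas
#' by the inverse-M transform, and draws exponential survival times with
#' log-hazard `hazard_coefficient * true risk score` conditionally on the
#' assigned 5-year survival group (administrative censoring at
#' `censor_time`). Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param template Optional `sim_cohort` from a previous call: its CpG
#'   annotation, baseline M-values and planted affected/causal structure are
#'   reused so the new cohort follows the same generative law with fresh
#'   patients (an external "validation" cohort).
#' @return A `sim_cohort` list: `beta`, `detp`, `sheet`, `annot` tibbles,
#'   the `truth` ground-truth list and the `config`.
#' @export
generate_cohort <- function(config, template = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (!is.null(template)) {
    stopifnot(inherits(template, "sim_cohort"),
              template$config$n_cpg == config$n_cpg)
  }
  cpg_ids <- if (is.null(template)) {
    sprintf("cg%07d", seq_len(config$n_cpg))
  } else {
    template$truth$baseline_m$cpg_id
  }

  # --- annotation -----------------------------------------------------------
  if (is.null(template)) {
    context <- sample(c("promoter", "gene_body", "intergenic"), config$n_cpg,
                      replace = TRUE, prob = c(0.30, 0.35, 0.35))
    island <- ifelse(runif(config$n_cpg) < config$fraction_cgi,
                     "cgi", "non_cgi")
    probe_type <- ifelse(runif(config$n_cpg) < config$fraction_type1,
                         "I", "II")
    genic <- context != "intergenic"
    n_genes <- max(10L, round(sum(genic) / 4))
    gene_pool <- sprintf("GENE%04d", seq_len(n_genes))
    gene <- character(config$n_cpg)
    gene[genic] <- sample(gene_pool, sum(genic), replace = TRUE,
                          prob = 1 / seq_len(n_genes)^0.7)
    annot <- tibble::tibble(
      cpg_id = cpg_ids, gene = gene, genomic_context = context,
      island = island, probe_type = probe_type,
      chrom = paste0("chr", sample(1:22, config$n_cpg, replace = TRUE)),
      pos = sample.int(2e8, config$n_cpg, replace = TRUE)
    )
  } else {
    annot <- template$annot
    island <- annot$island
    probe_type <- annot$probe_type
  }

  # --- patients & sample sheet ---------------------------------------------
  n_pat <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n_pat))
  n_surv <- round(config$survivor_fraction * n_pat)
  group <- sample(c(rep("survivor", n_surv),
                    rep("non_survivor", n_pat - n_surv)))
  status <- sample(c(rep("paired", config$n_paired),
                     rep("pre_only", config$n_pre_only),
                     rep("post_only", config$n_post_only)))
  surv <- group == "survivor"
  # clinical covariates with the study's reported group-wise proportions
  response <- ifelse(runif(n_pat) < ifelse(surv, 41 / 59, 11 / 24),
                     "partial_response", "stable_disease")
  treatment <- character(n_pat)
  treatment[surv] <- sample(c("epirubicin", "paclitaxel", "epitax"),
                            sum(surv), replace = TRUE,
                            prob = c(25, 24, 10) / 59)
  treatment[!surv] <- sample(c("epirubicin", "paclitaxel", "epitax"),
                             sum(!surv), replace = TRUE,
                             prob = c(8, 6, 10) / 24)
  subtype <- sample(c("basal", "her2_enriched", "luminal_a", "luminal_b",
                      "normal_like"), n_pat, replace = TRUE,
                    prob = c(9, 16, 14, 22, 13))
  stage <- sample(c("iib", "iiia", "iiib", "iv"), n_pat, replace = TRUE,
                  prob = c(28, 36, 14, 5))
  age <- round(rnorm(n_pat, 51, 8), 1)

  # --- planted effects ------------------------------------------------------
  if (is.null(template)) {
    affected_idx <- sample.int(config$n_cpg, config$n_affected_cpgs)
    direction <- ifelse(island[affected_idx] == "cgi", -1, 1)
    magnitude <- if (config$effect_distribution == "constant") {
      rep(config$effect_size_m, config$n_affected_cpgs)
    } else {
      abs(rnorm(config$n_affected_cpgs, 0,
                config$effect_size_m * sqrt(pi / 2)))
    }
    causal_pos <- seq_len(config$n_causal_cpgs)  # within the affected set
  } else {
    affected_idx <- match(template$truth$affected$cpg_id, cpg_ids)
    direction <- template$truth$affected$direction
    magnitude <- template$truth$affected$magnitude_m
    causal_pos <- which(template$truth$affected$causal)
  }
  modifier <- ifelse(
    surv,
    rlnorm(n_pat, meanlog = -config$effect_heterogeneity_sd^2 / 2,
           sdlog = config$effect_heterogeneity_sd),
    0
  )
  # causal sites carry independent per-patient effect heterogeneity, so each
  # contributes its own delta-beta variation to the risk signal rather than a
  # copy of one shared latent factor
  sdc <- config$causal_heterogeneity_sd
  mod_causal <- matrix(
    rlnorm(length(causal_pos) * n_pat, meanlog = -sdc^2 / 2, sdlog = sdc),
    length(causal_pos), n_pat)
  mod_causal[, !surv] <- 0

  # --- baseline M, random intercepts, noise --------------------------------
  if (is.null(template)) {
    p_low <- ifelse(island == "cgi", 0.8, 0.2)
    low_mode <- runif(config$n_cpg) < p_low
    mu <- ifelse(low_mode, rnorm(config$n_cpg, -3, 0.8),
                 rnorm(config$n_cpg, 2.5, 0.8))
  } else {
    mu <- template$truth$baseline_m$mu
  }
  if (is.null(template)) {
    # treatment-responsive sites live in the intermediate-methylation range
    # (saturated probes have no beta-scale dynamic range to change over)
    mu[affected_idx] <- runif(config$n_affected_cpgs, -2, 2)
  }
  rho <- config$intra_patient_correlation
  sd_b <- config$noise_sd_m * sqrt(rho)
  sd_e <- config$noise_sd_m * sqrt(1 - rho)
  b_pat <- matrix(rnorm(config$n_cpg * n_pat, 0, sd_b), config$n_cpg, n_pat)

  has_pre <- status %in% c("paired", "pre_only")
  has_post <- status %in% c("paired", "post_only")
  sheet <- dplyr::bind_rows(
    tibble::tibble(patient_id = pid[has_pre], timepoint = "pre"),
    tibble::tibble(patient_id = pid[has_post], timepoint = "post")
  )
  sheet$sample_id <- paste0(sheet$patient_id, "_", sheet$timepoint)
  pat_of <- match(sheet$patient_id, pid)

  M <- mu + b_pat[, pat_of] +
    matrix(rnorm(config$n_cpg * nrow(sheet), 0, sd_e),
           config$n_cpg, nrow(sheet))
  shift_base <- direction * magnitude           # per affected CpG
  is_post <- sheet$timepoint == "post"
  for (s in which(is_post & surv[pat_of])) {
    shift_s <- shift_base * modifier[pat_of[s]]
    shift_s[causal_pos] <- shift_base[causal_pos] * mod_causal[, pat_of[s]]
    M[affected_idx, s] <- M[affected_idx, s] + shift_s
  }
  M_obs <- M
  if (config$type2_scale != 1) {
    t2 <- probe_type == "II"
    M_obs[t2, ] <- M_obs[t2, ] * config$type2_scale
  }
  beta <- 1 / (1 + 2^(-M_obs))
  dimnames(beta) <- list(cpg_ids, sheet$sample_id)

  n_cells <- length(beta)
  failing <- runif(n_cells) < config$detection_fail_rate
  detp <- ifelse(failing, runif(n_cells, 0.05, 1), runif(n_cells, 0, 0.01))
  detp <- matrix(detp, config$n_cpg, nrow(sheet),
                 dimnames = dimnames(beta))

  # --- survival -------------------------------------------------------------
  dbeta_nf <- function(j, jc, p) {       # noise-free planted delta-beta
    m0 <- mu[affected_idx[j]]
    1 / (1 + 2^(-(m0 + shift_base[j] * mod_causal[jc, p]))) -
      1 / (1 + 2^(-m0))
  }
  w <- -direction[causal_pos] / max(config$n_causal_cpgs, 1L)
  z <- vapply(seq_len(n_pat), function(p) {
    if (config$n_causal_cpgs == 0L) return(0)
    sum(w * vapply(seq_along(causal_pos), function(jc) {
      dbeta_nf(causal_pos[jc], jc, p)
    }, numeric(1)))
  }, numeric(1))
  rate <- config$baseline_hazard * exp(config$hazard_coefficient * z)
  u <- runif(n_pat)
  t_pre_censor <- ifelse(
    surv,
    5 - log(1 - u) / rate,                       # memoryless tail beyond 5y
    -log(1 - u * (1 - exp(-5 * rate))) / rate    # truncated to (0, 5)
  )
  event <- ifelse(surv, as.numeric(t_pre_censor < config$censor_time), 1)
  time <- pmin(t_pre_censor, config$censor_time)

  patients <- tibble::tibble(
    patient_id = pid, survival_group = group, status = status,
    modifier = modifier, true_risk_score = z,
    survival_time_precensor = t_pre_censor,
    survival_time = round(time, 4), event = event,
    response = response, treatment = treatment, subtype = subtype,
    tumor_stage = stage, age = age
  )
  sheet <- sheet |>
    dplyr::left_join(
      patients |>
        dplyr::select("patient_id", "survival_group", "response", "treatment",
                      "subtype", "tumor_stage", "age", "survival_time",
                      "event"),
      by = "patient_id"
    ) |>
    dplyr::select("sample_id", "patient_id", "timepoint",
                  dplyr::everything())
  sheet <- validate_sample_sheet(sheet)

  surv_samples <- sheet$survival_group == "survivor"
  anchor <- tibble::tibble(
    cpg_id = cpg_ids,
    mean_beta_pre_surv = rowMeans(
      beta[, surv_samples & !is_post, drop = FALSE]),
    mean_beta_post_surv = rowMeans(
      beta[, surv_samples & is_post, drop = FALSE])
  )

  truth <- list(
    affected = tibble::tibble(
      cpg_id = cpg_ids[affected_idx], direction = direction,
      magnitude_m = magnitude,
      causal = seq_along(affected_idx) %in% causal_pos
    ),
    causal = tibble::tibble(cpg_id = cpg_ids[affected_idx][causal_pos],
                            weight = w),
    patients = patients,
    baseline_m = tibble::tibble(cpg_id = cpg_ids, mu = mu),
    survivor_means = anchor
  )
  structure(
    list(beta = meth_tibble(beta), detp = meth_tibble(detp),
         sheet = sheet, annot = annot, truth = truth, config = config),
    class = "sim_cohort"
  )
}

#' Generate a normal-tissue reference coupled to the planted changes
#'
#' Places the normal-tissue mean of exactly
#' `round(toward_normal_fraction * n_affected)` affected CpGs on the far
#' side of the survivors' post-treatment mean relative to their
#' pre-treatment mean (so the planted change moves toward normal) and the
#' remainder at the pre-treatment mean (so it moves away). Unaffected CpGs
#' get their cohort mean plus jitter.
#'
#' @param config The [simulation_config()] used for the cohort.
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @return A tibble with `cpg_id`, `mean_beta`.
#' @export
generate_normal_reference <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  anchor <- truth$survivor_means
  pre <- anchor$mean_beta_pre_surv
  post <- anchor$mean_beta_post_surv
  mean_beta <- pmin(pmax((pre + post) / 2 +
                           rnorm(nrow(anchor), 0, 0.05), 0), 1)
  aff <- match(truth$affected$cpg_id, anchor$cpg_id)
  n_aff <- length(aff)
  n_toward <- round(config$toward_normal_fraction * n_aff)
  toward <- seq_len(n_aff) <= n_toward
  s <- ifelse(post[aff] >= pre[aff], 1, -1)
  room <- ifelse(s > 0, 1 - post[aff], post[aff])
  mean_beta[aff] <- ifelse(toward, post[aff] + s * room / 2, pre[aff])
  tibble::tibble(cpg_id = anchor$cpg_id, mean_beta = mean_beta)
}

#' Generate immune reference profiles and mixed samples
#'
#' Builds a beta-scale signature matrix for `config$n_cell_types` cell
#' types (always including `regulatory_T`), draws per-patient Dirichlet
#' fractions, reduces the regulatory-T fraction of survivors'
#' post-treatment samples by `treg_shift` (redistributing the freed mass
#' over the other cell types so fractions still sum to one), and mixes
#' `mixture beta = sum_k fraction_k * signature_k` plus truncated Gaussian
#' noise.
#'
#' @param config A [simulation_config()].
#' @param sheet Optional sample sheet whose samples the mixtures should
#'   cover; by default a fully paired design of `n_patients` patients with
#'   `survivor_fraction` survivors is generated.
#' @return A list with `reference` (tibble `cpg_id` x cell types),
#'   `mixtures` (beta tibble), `fractions` (long tibble of true fractions)
#'   and the `sheet` used.
#' @export
generate_immune_mixtures <- function(config, sheet = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cell_types < 2L) abort("need at least 2 cell types")
  if (config$n_signature_cpgs < 50L) abort("need at least 50 signature CpGs")
  set.seed(derive_seed(config$seed, 2L))
  k <- config$n_cell_types
  others <- c("b_cell", "cd4_t", "cd8_t", "monocyte", "nk", "neutrophil",
              "dendritic")
  types <- c(others[seq_len(k - 1L)], "regulatory_T")
  sig_ids <- sprintf("sig%05d", seq_len(config$n_signature_cpgs))
  S <- matrix(runif(config$n_signature_cpgs * k, 0.05, 0.95),
              ncol = k, dimnames = list(sig_ids, types))

  if (is.null(sheet)) {
    n_pat <- config$n_patients
    pid <- sprintf("P%03d", seq_len(n_pat))
    n_surv <- round(config$survivor_fraction * n_pat)
    grp <- c(rep("survivor", n_surv), rep("non_survivor", n_pat - n_surv))
    sheet <- tibble::tibble(
      sample_id = c(paste0(pid, "_pre"), paste0(pid, "_post")),
      patient_id = rep(pid, 2),
      timepoint = rep(c("pre", "post"), each = n_pat),
      survival_group = rep(grp, 2),
      survival_time = 10, event = 0
    )
    sheet <- validate_sample_sheet(sheet)
  }
  pats <- unique(sheet$patient_id)
  # Dirichlet fractions per patient; regulatory-T kept above the shift so
  # the planted decrease is exact
  draw <- function() {
    g <- rgamma(k, shape = c(rep(8, k - 1L), 24))
    g / sum(g)
  }
  frac_pat <- matrix(NA_real_, length(pats), k,
                     dimnames = list(pats, types))
  for (i in seq_along(pats)) {
    f <- draw()
    while (f[k] < config$treg_shift + 0.02) f <- draw()
    frac_pat[i, ] <- f
  }
  frac <- frac_pat[match(sheet$patient_id, pats), , drop = FALSE]
  rownames(frac) <- sheet$sample_id
  shift_rows <- sheet$survival_group == "survivor" & sheet$timepoint == "post"
  if (any(shift_rows) && config$treg_shift > 0) {
    f <- frac[shift_rows, , drop = FALSE]
    freed <- config$treg_shift
    f[, k] <- f[, k] - freed
    scale_others <- (1 - f[, k]) / rowSums(f[, -k, drop = FALSE])
    f[, -k] <- f[, -k, drop = FALSE] * scale_others
    frac[shift_rows, ] <- f
  }
  mix <- S %*% t(frac)
  if (config$mixture_noise_sd > 0) {
    mix <- mix + matrix(rnorm(length(mix), 0, config$mixture_noise_sd),
                        nrow(mix))
    mix <- pmin(pmax(mix, 0), 1)
  }
  dimnames(mix) <- list(sig_ids, sheet$sample_id)
  list(
    reference = dplyr::bind_cols(tibble::tibble(cpg_id = sig_ids),
                                 tibble::as_tibble(S)),
    mixtures = meth_tibble(mix),
    fractions = tibble::as_tibble(frac, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                          values_to = "fraction"),
    sheet = sheet
  )
}
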