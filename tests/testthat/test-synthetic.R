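# The cohort generator is first-class code: determinism, design counts,
# value ranges, and the planted structure every downstream stage relies on.

small_cfg <- function(...) {
  defaults <- list(n_patients = 20, n_pre_only = 2, n_post_only = 4,
                   n_cpg = 300, n_affected_cpgs = 40, n_causal_cpgs = 2,
                   seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is a pure function of its seed", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a$beta, b$beta)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$patients, b$truth$patients)
  c2 <- generate_cohort(small_cfg(seed = 43))
  expect_false(identical(a$beta, c2$beta))
})

test_that("the default design reproduces the study's sample counts", {
  co <- cached("cohort_default", generate_cohort(simulation_config()))
  expect_equal(sum(co$sheet$timepoint == "pre"), 55)
  expect_equal(sum(co$sheet$timepoint == "post"), 75)
  expect_equal(nrow(co$sheet), 130)
  expect_equal(dplyr::n_distinct(co$sheet$patient_id), 83)
  idx <- pairing_index(co$sheet)
  expect_equal(sum(idx$paired), 47)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_causal_cpgs = 10, n_affected_cpgs = 5),
               "n_causal")
  expect_error(simulation_config(n_pre_only = 50, n_post_only = 50),
               "exceeds")
  expect_error(simulation_config(pair_fraction = 0.2), "inconsistent")
  expect_error(simulation_config(toward_normal_fraction = 1.3), "toward")
  expect_error(simulation_config(intra_patient_correlation = 1), "correlation")
})

test_that("betas live in (0,1) and the M round trip is exact", {
  co <- generate_cohort(small_cfg())
  b <- meth_matrix(co$beta)
  expect_true(all(b > 0 & b < 1))
  m <- log2(b / (1 - b))
  expect_equal(1 / (1 + 2^(-m)), b, tolerance = 1e-12)
  p <- meth_matrix(co$detp)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a zero effect size leaves the planted set at the null", {
  # intra-patient correlation 0 so the unpaired per-CpG t-test is exact
  co <- generate_cohort(small_cfg(effect_size_m = 0, n_affected_cpgs = 100,
                                  effect_distribution = "constant",
                                  n_causal_cpgs = 0, n_cpg = 400,
                                  intra_patient_correlation = 0))
  surv <- co$sheet[co$sheet$survival_group == "survivor", ]
  b <- meth_matrix(co$beta)[co$truth$affected$cpg_id, surv$sample_id]
  m <- log2(b / (1 - b))
  pre <- surv$timepoint == "pre"
  pvals <- apply(m, 1, function(x) t.test(x[pre], x[!pre])$p.value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("empirical intra-patient correlation approaches the configured value", {
  co <- cached("cohort_rho_check", generate_cohort(simulation_config(
    seed = 51, n_patients = 60, n_pre_only = 0, n_post_only = 0,
    n_cpg = 2000, n_affected_cpgs = 0, n_causal_cpgs = 0)))
  idx <- pairing_index(co$sheet)
  b <- meth_matrix(co$beta)
  m <- log2(b / (1 - b))
  pre <- m[, idx$pre]
  post <- m[, idx$post]
  r <- vapply(seq_len(nrow(m)), function(g) cor(pre[g, ], post[g, ]),
              numeric(1))
  expect_lt(abs(mean(r) - 0.5), 0.05)
})

test_that("higher true risk means stochastically shorter survival", {
  co <- generate_cohort(small_cfg())
  tr <- co$truth$patients
  tau <- cor(tr$true_risk_score, tr$survival_time_precensor,
             method = "kendall")
  expect_lt(tau, 0)
  # group labels consistent with the 5-year rule
  expect_true(all(tr$survival_time[tr$survival_group == "non_survivor"] < 5))
  expect_true(all(tr$survival_time[tr$survival_group == "survivor"] >= 5))
  expect_true(all(tr$event[tr$survival_group == "non_survivor"] == 1))
})

test_that("the normal reference encodes the configured toward-normal fraction", {
  for (f in c(0, 0.9, 1)) {
    co <- generate_cohort(small_cfg(toward_normal_fraction = f))
    normal <- generate_normal_reference(co$config, co$truth)
    surv <- co$sheet[co$sheet$survival_group == "survivor", ]
    tn <- toward_normal_fraction(co$beta, surv, co$truth$affected$cpg_id,
                                 normal)
    expect_equal(tn$fraction_toward,
                 round(f * nrow(co$truth$affected)) /
                   nrow(co$truth$affected))
  }
})

test_that("immune mixtures are exact convex combinations with the planted Treg shift", {
  cfg <- small_cfg(mixture_noise_sd = 0, n_signature_cpgs = 60,
                   n_cell_types = 3)
  imm <- generate_immune_mixtures(cfg)
  S <- meth_matrix(imm$reference)
  frac <- tidyr::pivot_wider(imm$fractions, names_from = "cell_type",
                             values_from = "fraction")
  fmat <- as.matrix(frac[, colnames(S)])
  expect_equal(meth_matrix(imm$mixtures),
               S %*% t(fmat), tolerance = 1e-12, ignore_attr = TRUE)
  # fractions sum to one
  expect_equal(rowSums(fmat), rep(1, nrow(fmat)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # planted shift: survivor post Treg lower by exactly treg_shift
  joined <- imm$fractions |>
    dplyr::filter(.data$cell_type == "regulatory_T") |>
    dplyr::inner_join(imm$sheet, by = "sample_id") |>
    dplyr::filter(.data$survival_group == "survivor")
  pre <- joined$fraction[joined$timepoint == "pre"]
  post <- joined$fraction[joined$timepoint == "post"]
  expect_equal(mean(pre) - mean(post), cfg$treg_shift, tolerance = 1e-12)
  # reproducible
  imm2 <- generate_immune_mixtures(cfg)
  expect_identical(imm$mixtures, imm2$mixtures)
  expect_error(generate_immune_mixtures(small_cfg(n_cell_types = 1)),
               "2 cell types")
})

test_that("template cohorts share the generative law but not the patients", {
  co <- generate_cohort(small_cfg())
  cfg2 <- small_cfg(seed = 99)
  val <- generate_cohort(cfg2, template = co)
  expect_identical(val$annot, co$annot)
  expect_identical(val$truth$affected, co$truth$affected)
  expect_identical(val$truth$baseline_m, co$truth$baseline_m)
  expect_false(identical(val$beta, co$beta))
})
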