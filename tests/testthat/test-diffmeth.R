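# The differential engine: consensus correlation, GLS, moderation, BH.

test_that("consensus correlation recovers the simulated intra-patient correlation", {
  co <- cached("cohort_rho05", {
    generate_cohort(simulation_config(
      seed = 22, n_patients = 40, n_pre_only = 0, n_post_only = 0,
      n_cpg = 500, n_affected_cpgs = 0, n_causal_cpgs = 0))
  })
  cc <- estimate_consensus_correlation(beta_to_m(co$beta), co$sheet,
                                       n_cpgs = Inf)
  expect_gt(cc$consensus, 0.40)
  expect_lt(cc$consensus, 0.60)

  co0 <- generate_cohort(simulation_config(
    seed = 23, n_patients = 40, n_pre_only = 0, n_post_only = 0,
    n_cpg = 500, n_affected_cpgs = 0, n_causal_cpgs = 0,
    intra_patient_correlation = 0))
  cc0 <- estimate_consensus_correlation(beta_to_m(co0$beta), co0$sheet,
                                        n_cpgs = Inf)
  expect_lt(abs(cc0$consensus), 0.10)
})

test_that("constant CpGs are excluded from the consensus and pairing is required", {
  sheet <- make_sheet(4)
  set.seed(1)
  m <- matrix(rnorm(8 * 50), 50, 8,
              dimnames = list(sprintf("cg%02d", 1:50), sheet$sample_id))
  m[1, ] <- 0.7
  cc <- estimate_consensus_correlation(meth_tibble(m), sheet, n_cpgs = Inf)
  expect_equal(cc$n_excluded, 1)
  expect_equal(cc$n_cpgs_used, 49)
  expect_false("cg01" %in% cc$rho$cpg_id)

  unpaired <- make_sheet(0, n_pre_only = 2, n_post_only = 2)
  m2 <- matrix(rnorm(4 * 50), 50, 4,
               dimnames = list(sprintf("cg%02d", 1:50), unpaired$sample_id))
  expect_error(estimate_consensus_correlation(meth_tibble(m2), unpaired),
               "pairing required")
})

test_that("GLS matches the dense-covariance oracle on small mixed designs", {
  set.seed(7)
  for (case in 1:4) {
    n_paired <- sample(2:4, 1)
    n_pre <- sample(0:2, 1)
    n_post <- sample(0:2, 1)
    sheet <- make_sheet(n_paired, n_pre, n_post)
    rho <- runif(1, -0.2, 0.8)
    n <- nrow(sheet)
    m <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(paste0("cg", 1:3), sheet$sample_id))
    fits <- fit_gls_per_cpg(meth_tibble(m), sheet, rho,
                            min_per_group = 2)$fits
    V <- oracle_block_V(sheet, rho)
    X <- cbind(1, as.numeric(sheet$timepoint == "post"))
    for (g in 1:3) {
      o <- oracle_gls(m[g, ], X, V)
      expect_equal(fits$effect[g], o$effect, tolerance = 1e-8)
      expect_equal(fits$sigma2[g], o$sigma2, tolerance = 1e-8)
      expect_equal(fits$se_unit[g], o$se_unit, tolerance = 1e-8)
    }
  }
})

test_that("GLS reduces to OLS when unpaired and approaches the paired t as rho -> 1", {
  # fully unpaired, consensus 0: ordinary two-group mean difference
  sheet <- make_sheet(0, n_pre_only = 4, n_post_only = 4)
  set.seed(8)
  m <- matrix(rnorm(2 * 8), 2, 8,
              dimnames = list(c("cg1", "cg2"), sheet$sample_id))
  fits <- fit_gls_per_cpg(meth_tibble(m), sheet, 0)$fits
  pre <- sheet$timepoint == "pre"
  expect_equal(fits$effect,
               rowMeans(m[, !pre]) - rowMeans(m[, pre]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # fully paired with strong true intra-patient correlation: the GLS effect
  # is exactly the mean paired difference and the t tracks the paired t
  sheet2 <- make_sheet(10)
  idx <- pairing_index(sheet2)
  set.seed(81)
  t_gls <- t_paired <- numeric(200)
  for (g in 1:200) {
    patient <- rnorm(10, sd = 2)
    m2 <- matrix(patient[rep(1:10, each = 2)] + rnorm(20, sd = 0.4),
                 1, 20, dimnames = list("cg1", sheet2$sample_id))
    f <- fit_gls_per_cpg(meth_tibble(m2), sheet2, 0.96)$fits
    expect_equal(f$effect,
                 mean(m2[1, idx$post] - m2[1, idx$pre]), tolerance = 1e-10)
    t_gls[g] <- f$effect / (sqrt(f$sigma2) * f$se_unit)
    d <- m2[1, idx$post] - m2[1, idx$pre]
    t_paired[g] <- mean(d) / (sd(d) / sqrt(length(d)))
  }
  expect_gt(cor(t_gls, t_paired), 0.95)
  expect_lt(abs(median(t_gls / t_paired) - 1), 0.15)
})

test_that("CpGs with too few samples per group are skipped with a reason", {
  sheet <- make_sheet(4)
  m <- matrix(rnorm(2 * 8), 2, 8,
              dimnames = list(c("cg1", "cg2"), sheet$sample_id))
  m[2, sheet$timepoint == "pre"][1:2] <- NA
  out <- fit_gls_per_cpg(meth_tibble(m), sheet, 0.3, min_per_group = 3)
  expect_equal(out$skipped$cpg_id, "cg2")
  expect_match(out$skipped$reason, "non-missing")
  expect_equal(out$fits$cpg_id, "cg1")
})

test_that("missing values fall back to a per-CpG whitening that matches the oracle", {
  sheet <- make_sheet(4, 1, 1)
  set.seed(9)
  m <- matrix(rnorm(10), 1, 10, dimnames = list("cg1", sheet$sample_id))
  m[1, 2] <- NA                       # breaks one pair
  rho <- 0.5
  fits <- fit_gls_per_cpg(meth_tibble(m), sheet, rho, min_per_group = 2)$fits
  obs <- which(!is.na(m[1, ]))
  sub_sheet <- sheet[obs, ]
  V <- oracle_block_V(sub_sheet, rho)
  X <- cbind(1, as.numeric(sub_sheet$timepoint == "post"))
  o <- oracle_gls(m[1, obs], X, V)
  expect_equal(fits$effect, o$effect, tolerance = 1e-8)
  expect_equal(fits$sigma2, o$sigma2, tolerance = 1e-8)
})

test_that("variance moderation matches limma's squeezeVar", {
  set.seed(10)
  dfree <- 20L
  s2 <- exp(rnorm(200, -1, 0.7))
  fits <- tibble::tibble(cpg_id = sprintf("cg%03d", 1:200),
                         effect = rnorm(200), sigma2 = s2,
                         df = dfree, se_unit = 0.3)
  mod <- empirical_bayes_moderate(fits)
  sq <- limma::squeezeVar(s2, df = dfree)
  expect_equal(mod$params$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$table$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("moderation handles equal variances and excludes zero-variance CpGs", {
  fits <- tibble::tibble(cpg_id = sprintf("cg%02d", 1:12),
                         effect = rnorm(12), sigma2 = 0.25, df = 10,
                         se_unit = 0.5)
  mod <- empirical_bayes_moderate(fits)
  expect_equal(mod$params$d0, Inf)
  expect_equal(mod$table$s2_post, rep(0.25, 12), tolerance = 1e-12)
  # with infinite prior df the moderated t is Gaussian-calibrated
  expect_equal(mod$table$p,
               2 * pnorm(-abs(mod$table$t)), tolerance = 1e-12)

  fits$sigma2[1] <- 0
  mod2 <- empirical_bayes_moderate(fits)
  expect_equal(mod2$params$n_zero_variance, 1)
  expect_true(is.na(mod2$table$t[1]))
})

test_that("BH adjustment equals the direct step-up evaluation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(11)
  p <- runif(100)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  o <- order(p)
  expect_false(is.unsorted(bh_adjust(p)[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1|\\[0, 1\\]")
})

test_that("planted survivor effects are recovered and results are permutation-invariant", {
  co <- cached("cohort_main", {
    generate_cohort(simulation_config(seed = 7,
                                      effect_distribution = "constant"))
  })
  surv <- co$sheet[co$sheet$survival_group == "survivor", ]
  dm <- cached("dm_main", diff_methylation(co$beta, surv))
  sig <- dm$cpg_id[dm$significant]
  expect_gt(mean(co$truth$affected$cpg_id %in% sig), 0.9)

  # permuting matrix rows and columns changes nothing (consensus held
  # fixed: its default estimation subsamples CpGs by row position)
  cc <- attr(dm, "consensus")
  dm1 <- diff_methylation(co$beta, surv, consensus = cc)
  b <- meth_matrix(co$beta)
  set.seed(12)
  bp <- b[sample(nrow(b)), sample(ncol(b))]
  dm2 <- diff_methylation(meth_tibble(bp), surv, consensus = cc)
  expect_equal(dplyr::arrange(tidy(dm1), cpg_id),
               dplyr::arrange(tidy(dm2), cpg_id), tolerance = 1e-8)
})

test_that("group comparisons cover levels, skip unpaired subgroups, honour alpha", {
  co <- cached("cohort_main", {
    generate_cohort(simulation_config(seed = 7,
                                      effect_distribution = "constant"))
  })
  small <- co$sheet
  res <- run_group_comparisons(co$beta, small, group_by = "survival_group")
  expect_setequal(names(res), c("survival_group:survivor",
                                "survival_group:non_survivor"))
  # non-survivors carry no planted change
  expect_lte(mean(res[["survival_group:non_survivor"]]$significant), 0.01)

  # alpha = 1 flags everything
  surv <- co$sheet[co$sheet$survival_group == "survivor", ]
  cc <- attr(cached("dm_main", diff_methylation(co$beta, surv)), "consensus")
  dm_all <- diff_methylation(co$beta, surv, alpha = 1, consensus = cc)
  expect_true(all(dm_all$significant))

  # a single-level grouping equals the whole-cohort run
  sheet_one <- dplyr::mutate(co$sheet, arm = "all")
  r1 <- run_group_comparisons(co$beta, sheet_one, group_by = "arm")
  whole <- diff_methylation(co$beta, co$sheet)
  expect_equal(tidy(r1[["arm:all"]]), tidy(whole), tolerance = 1e-12)

  # subgroup without pairs is skipped with a reason
  sheet_bad <- dplyr::mutate(
    co$sheet, arm = ifelse(.data$paired, "paired_arm", "unpaired_arm"))
  r2 <- run_group_comparisons(co$beta, sheet_bad, group_by = "arm")
  expect_match(attr(r2, "skipped")[["arm:unpaired_arm"]], "no paired")
})

test_that("tidy and glance expose the differential fit", {
  co <- cached("cohort_main", {
    generate_cohort(simulation_config(seed = 7,
                                      effect_distribution = "constant"))
  })
  surv <- co$sheet[co$sheet$survival_group == "survivor", ]
  dm <- cached("dm_main", diff_methylation(co$beta, surv))
  td <- tidy(dm)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cpg_id", "effect", "mean_beta_pre", "mean_beta_post",
                     "t", "p", "p_adj", "significant", "direction"))
  expect_true(all(td$direction[td$effect > 0] == "gain"))
  gl <- glance(dm)
  expect_equal(gl$n_significant, sum(td$significant))
  expect_s3_class(autoplot(dm), "ggplot")
})
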