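test_that("delta-beta is post minus pre over fully paired patients only", {
  sheet <- make_sheet(2, n_post_only = 1)
  b <- make_beta_tbl(c(0.6, 0.3, 0.4, 0.5, 0.7, 0.2, 0.5, 0.9, 0.1, 0.8),
                     c("cg1", "cg2"), sheet$sample_id)
  dB <- build_delta_beta(b, sheet, c("cg1", "cg2"))
  expect_equal(nrow(dB), 2)
  expect_equal(attr(dB, "n_excluded_unpaired"), 1)
  bm <- meth_matrix(b)
  expect_equal(dB$cg1[dB$patient_id == "P01"],
               unname(bm["cg1", "P01_post"] - bm["cg1", "P01_pre"]))
  expect_error(build_delta_beta(b, sheet, "cg9"), "absent")
})

test_that("the emulated study design yields 47 delta-beta rows", {
  co <- cached("cohort_default", generate_cohort(simulation_config()))
  dB <- build_delta_beta(co$beta, co$sheet, co$beta$cpg_id[1:5])
  expect_equal(nrow(dB), 47)
})

test_that("risk scores are the coefficient-weighted delta-beta sums", {
  model <- structure(list(
    cpgs = tibble::tibble(cpg_id = c("cg1", "cg2"), coefficient = c(2, -1),
                          selection_frequency = c(1, 1)),
    stability_threshold = 0.8, empty = FALSE), class = "risk_score_model")
  dB <- tibble::tibble(patient_id = "P1", cg1 = 0.1, cg2 = 0.1)
  class(dB) <- c("delta_beta", class(dB))
  expect_equal(apply_risk_score(model, dB)$risk_score, 0.1)

  # linearity
  dB2 <- dplyr::mutate(dB, cg1 = cg1 * 2, cg2 = cg2 * 2)
  expect_equal(apply_risk_score(model, dB2)$risk_score,
               2 * apply_risk_score(model, dB)$risk_score)

  empty <- structure(list(cpgs = model$cpgs[0, ], empty = TRUE),
                     class = "risk_score_model")
  expect_equal(apply_risk_score(empty, dB)$risk_score, 0)

  missing <- dplyr::select(dB, -"cg2")
  expect_error(apply_risk_score(model, missing), "cg2")
})

test_that("LOO group assignment applies the documented probability tie rule", {
  loo <- tibble::tibble(patient_id = c("a", "b", "c"),
                        outcome = c(1, 0, 0),
                        prob_death = c(0.7, 0.5, 0.2),
                        linear_predictor = c(1, 0, -2),
                        train_median_lp = c(-0.5, -0.5, -0.5))
  gr <- assign_groups_loo(loo)
  expect_equal(gr$group, c("high", "high", "low"))
  expect_equal(unique(gr$provenance), "loo_predicted")
  gr2 <- assign_groups_loo(loo, rule = "train_median")
  expect_equal(gr2$group, c("high", "high", "low"))
  loo$prob_death[2] <- NA
  expect_error(assign_groups_loo(loo), "missing LOO prediction")
})

test_that("median cutoff sends ties low and rejects degenerate scores", {
  s <- tibble::tibble(patient_id = paste0("p", 1:4),
                      risk_score = c(1, 2, 3, 4))
  gr <- assign_groups_median(s)
  expect_equal(gr$group, c("low", "low", "high", "high"))
  s2 <- tibble::tibble(patient_id = paste0("p", 1:4),
                       risk_score = c(1, 2, 2, 3))
  expect_equal(assign_groups_median(s2)$group,
               c("low", "low", "low", "high"))
  s3 <- tibble::tibble(patient_id = c("a", "b"), risk_score = c(0, 1))
  expect_setequal(assign_groups_median(s3)$group, c("low", "high"))
  expect_error(assign_groups_median(
    tibble::tibble(patient_id = c("a", "b"), risk_score = c(1, 1))),
    "degenerate")
  expect_error(assign_groups_median(s3[1, ]), "at least 2")
})

test_that("stability selection respects its threshold boundaries and contracts", {
  co <- cached("risk_cohort_small", {
    generate_cohort(simulation_config(
      seed = 40, n_patients = 30, n_pre_only = 0, n_post_only = 0,
      n_cpg = 60, n_affected_cpgs = 3, n_causal_cpgs = 3,
      effect_distribution = "constant", effect_size_m = 2))
  })
  dB <- build_delta_beta(co$beta, co$sheet, co$beta$cpg_id)
  y <- five_year_death(co$sheet, dB$patient_id)
  sel <- suppressWarnings(loo_lasso_select(dB, y, seed = 2))
  # threshold 0: every ever-nonzero CpG is included
  sel0 <- suppressWarnings(loo_lasso_select(dB, y, stability_threshold = 0,
                                            seed = 2))
  ever <- sel0$model$selection_frequency
  expect_setequal(sel0$model$cpgs$cpg_id,
                  ever$cpg_id[ever$frequency > 0])
  expect_true(all(sel$model$cpgs$selection_frequency > 0.8))
  expect_true(all(sel$model$cpgs$coefficient != 0))
  expect_equal(nrow(sel$loo), nrow(dB))
  expect_false(anyNA(sel$loo$prob_death))

  # selection is invariant to candidate column order up to coordinate-
  # descent numerics: the stable set matches, frequencies nearly so
  perm <- c(1, sample(2:ncol(dB)))
  selp <- suppressWarnings(loo_lasso_select(dB[, perm], y, seed = 2))
  f1 <- sel$model$selection_frequency |> dplyr::arrange(.data$cpg_id)
  f2 <- selp$model$selection_frequency |> dplyr::arrange(.data$cpg_id)
  expect_equal(f1$cpg_id, f2$cpg_id)
  expect_lt(max(abs(f1$frequency - f2$frequency)), 0.1)
  expect_setequal(sel$model$cpgs$cpg_id, selp$model$cpgs$cpg_id)

  expect_error(loo_lasso_select(dB[1:5, ], y[1:5]), "at least 10")
  expect_error(loo_lasso_select(dB, setNames(rep(0, nrow(dB)),
                                             dB$patient_id)),
               "both outcome classes")
})

test_that("risk models serialise to JSON and back", {
  co <- cached("risk_cohort_small", {
    generate_cohort(simulation_config(
      seed = 40, n_patients = 30, n_pre_only = 0, n_post_only = 0,
      n_cpg = 60, n_affected_cpgs = 3, n_causal_cpgs = 3,
      effect_distribution = "constant", effect_size_m = 2))
  })
  dB <- build_delta_beta(co$beta, co$sheet, co$beta$cpg_id)
  y <- five_year_death(co$sheet, dB$patient_id)
  sel <- suppressWarnings(loo_lasso_select(dB, y, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(sel$model, path)
  back <- read_risk_model(path)
  expect_equal(back$cpgs$coefficient, sel$model$cpgs$coefficient,
               tolerance = 1e-12)
  expect_equal(back$orientation, sel$model$orientation)
  s1 <- apply_risk_score(sel$model, dB)
  s2 <- apply_risk_score(back, dB)
  expect_equal(s1$risk_score, s2$risk_score, tolerance = 1e-12)
})
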