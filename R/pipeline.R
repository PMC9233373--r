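# End-to-end orchestration on a synthetic cohort (simulate -> preprocess ->
# differential methylation -> regions/toward-normal -> enrichment ->
# deconvolution -> risk model -> survival), plus the Table-1-style cohort
# summary. Every artifact is written under `outdir` with a provenance
# record (config hash + seed), and a rerun with the same config reproduces
# identical outputs.

#' Synthetic gene sets over a cohort's gene universe
#'
#' Builds random gene sets from the genes present in the annotation. These
#' are synthetic stand-ins for GO/KEGG term collections (which are
#' versioned external resources and never fetched).
#'
#' @param annot CpG annotation.
#' @param n_sets Number of sets.
#' @param size_range Set sizes drawn uniformly from this range.
#' @param seed Integer seed.
#' @return A gene-sets tibble as from [read_gmt()].
#' @export
synthetic_gene_sets <- function(annot, n_sets = 20, size_range = c(5, 40),
                                seed = 1) {
  genes <- sort(unique(annot$gene[annot$gene != ""]))
  if (length(genes) < size_range[1]) abort("too few genes for gene sets")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], min(size_range[2], length(genes))),
                  n_sets, replace = TRUE)
  tibble::tibble(
    set = sprintf("SET%03d", seq_len(n_sets)),
    description = "synthetic gene set",
    genes = lapply(sizes, function(s) sample(genes, s))
  )
}

#' Table-1-style cohort summary
#'
#' Counts and one-decimal percentages (rounded half up) per outcome group
#' for each categorical clinical variable, plus median and IQR for
#' continuous ones. Accepts a sample sheet (collapsed to one row per
#' patient first) or any per-patient tibble.
#'
#' @param data Sample sheet or per-patient clinical tibble.
#' @param group_col Grouping column; default `survival_group`.
#' @param categorical Categorical variables to tabulate (only those present
#'   are used).
#' @param continuous Continuous variables to summarise.
#' @return A `cohort_summary` list: `groups` (sizes), `categorical`
#'   (`group`, `variable`, `level`, `n`, `percent`) and `continuous`
#'   (`group`, `variable`, `median`, `q1`, `q3`).
#' @export
cohort_summary <- function(data, group_col = "survival_group",
                           categorical = c("tumor_stage", "subtype",
                                           "response", "treatment"),
                           continuous = "age") {
  data <- tibble::as_tibble(data)
  if (!group_col %in% names(data)) {
    abort(paste0("grouping column not found: ", group_col))
  }
  if ("patient_id" %in% names(data)) {
    keep <- intersect(c("patient_id", group_col, categorical, continuous),
                      names(data))
    data <- dplyr::distinct(data[keep])
    if (anyDuplicated(data$patient_id)) {
      abort("inconsistent per-patient clinical values")
    }
  }
  sizes <- data |>
    dplyr::count(group = .data[[group_col]], name = "n_group")
  if (any(sizes$n_group == 0L) || nrow(sizes) == 0L) abort("empty group")
  cat_rows <- lapply(intersect(categorical, names(data)), function(v) {
    data |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::count(group = .data[[group_col]], level = .data[[v]]) |>
      dplyr::mutate(variable = v)
  })
  cat_tbl <- dplyr::bind_rows(cat_rows)
  if (nrow(cat_tbl) > 0L) {
    cat_tbl <- cat_tbl |>
      dplyr::left_join(sizes, by = "group") |>
      dplyr::mutate(percent = round_half_up(100 * .data$n / .data$n_group, 1)) |>
      dplyr::select("group", "variable", "level", "n", "percent")
  }
  cont_rows <- lapply(intersect(continuous, names(data)), function(v) {
    data |>
      dplyr::group_by(group = .data[[group_col]]) |>
      dplyr::summarise(
        variable = v,
        median = median(.data[[v]], na.rm = TRUE),
        q1 = unname(quantile(.data[[v]], 0.25, na.rm = TRUE)),
        q3 = unname(quantile(.data[[v]], 0.75, na.rm = TRUE)),
        .groups = "drop"
      )
  })
  structure(
    list(groups = sizes, categorical = cat_tbl,
         continuous = dplyr::bind_rows(cont_rows)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$groups)
  if (nrow(x$continuous) > 0) print(x$continuous)
  print(x$categorical, n = Inf)
  invisible(x)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order on a generated cohort and writes
#' all tabular artifacts plus a provenance record under `outdir`. The run
#' is a pure function of `config` (including its seed): rerunning with the
#' same config reproduces identical outputs.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed); NULL skips writing.
#' @param stages Character vector of stages to run, a subset of
#'   `c("preprocess", "diffmeth", "regions", "enrich", "deconv", "risk",
#'   "survival")`. The simulation and cohort summary always run.
#' @param alpha BH significance threshold; default 0.01.
#' @param stability_threshold LASSO stability cutoff; default 0.8.
#' @param k_top Top enriched terms kept per stratum; default 6.
#' @param n_perm Enrichment permutations; default 2000.
#' @param gene_sets Optional gene-sets tibble; defaults to
#'   [synthetic_gene_sets()] on the cohort's annotation.
#' @param max_candidates Cap on the number of candidate CpGs entering the
#'   risk model (top of the survivor table); default 1000.
#' @return A `pipeline_result` list with each stage's objects and the
#'   provenance record.
#' @export
run_pipeline <- function(config = simulation_config(),
                         outdir = NULL,
                         stages = c("preprocess", "diffmeth", "regions",
                                    "enrich", "deconv", "risk", "survival"),
                         alpha = 0.01, stability_threshold = 0.8,
                         k_top = 6, n_perm = 2000, gene_sets = NULL,
                         max_candidates = 1000) {
  stages <- match.arg(stages, several.ok = TRUE)
  write_out <- !is.null(outdir)
  if (write_out && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(x, name) {
    if (write_out) write_results_table(x, file.path(outdir, name))
  }
  log_msg <- function(...) inform(sprintf(...))
  res <- list()

  log_msg("stage simulate: seed %d", config$seed)
  cohort <- generate_cohort(config)
  res$cohort <- cohort
  res$summary <- cohort_summary(cohort$sheet)
  emit(cohort$sheet, "sample_sheet.csv")
  emit(cohort$annot, "cpg_annotation.csv")
  emit(res$summary$categorical, "cohort_summary.csv")

  beta <- cohort$beta
  if ("preprocess" %in% stages) {
    log_msg("stage preprocess")
    filt <- detection_filter(beta, cohort$detp)
    pc <- peak_correct_type2(beta_to_m(filt$beta), cohort$annot)
    beta <- quantile_normalize(m_to_beta(pc$m))
    res$preprocess <- list(
      detection = filt$report, peaks = pc$report,
      n_sites_out = nrow(beta)
    )
    if (write_out) {
      jsonlite::write_json(
        list(n_sites_in = filt$report$n_sites_in,
             n_sites_removed_detection = filt$report$n_sites_removed_detection,
             n_sites_out = nrow(beta)),
        file.path(outdir, "preprocess_report.json"), auto_unbox = TRUE)
      emit(pc$report, "peak_correction.csv")
    }
  }
  res$beta_processed <- beta

  survivor_sheet <- cohort$sheet[cohort$sheet$survival_group == "survivor", ]
  if ("diffmeth" %in% stages) {
    log_msg("stage diffmeth")
    comparisons <- run_group_comparisons(beta, cohort$sheet, alpha = alpha)
    res$comparisons <- comparisons
    if (write_out) {
      for (nm in names(comparisons)) {
        emit(tidy(comparisons[[nm]]),
             paste0("diffmeth_", gsub("[^[:alnum:]]+", "_", nm), ".csv"))
      }
      jsonlite::write_json(
        lapply(comparisons, function(x) sum(x$significant)),
        file.path(outdir, "diffmeth_counts.json"), auto_unbox = TRUE)
    }
  }
  survivor_key <- "survival_group:survivor"
  survivor_res <- res$comparisons[[survivor_key]]

  if ("regions" %in% stages && !is.null(survivor_res)) {
    log_msg("stage regions")
    res$regions <- region_proportions(survivor_res, cohort$annot)
    normal <- generate_normal_reference(config, cohort$truth)
    sig_ids <- survivor_res$cpg_id[survivor_res$significant]
    res$toward_normal <- toward_normal_fraction(beta, survivor_sheet,
                                                sig_ids, normal)
    emit(res$regions, "region_proportions.csv")
    if (write_out) {
      jsonlite::write_json(
        res$toward_normal[c("n_evaluated", "n_toward", "fraction_toward")],
        file.path(outdir, "toward_normal.json"), auto_unbox = TRUE)
    }
  }

  if ("enrich" %in% stages && !is.null(survivor_res)) {
    log_msg("stage enrich")
    sets <- gene_sets %||%
      synthetic_gene_sets(cohort$annot, seed = config$seed)
    annot_r <- classify_region(cohort$annot)
    sig <- survivor_res[survivor_res$significant, c("cpg_id", "direction")]
    enr <- list()
    for (reg in region_levels) {
      reg_cpgs <- annot_r$cpg_id[!is.na(annot_r$region) &
                                   annot_r$region == reg]
      gene_of <- annot_r$gene[match(reg_cpgs, annot_r$cpg_id)]
      universe <- unique(gene_of[gene_of != ""])
      if (length(universe) < 5L) next
      for (dir in c("gain", "loss")) {
        sig_reg <- sig$cpg_id[sig$direction == dir &
                                sig$cpg_id %in% reg_cpgs]
        sig_genes <- unique(gene_of[match(sig_reg, reg_cpgs)])
        sig_genes <- sig_genes[!is.na(sig_genes) & sig_genes != ""]
        if (length(sig_genes) == 0L) next
        weights <- estimate_probe_bias(
          annot_r[annot_r$cpg_id %in% reg_cpgs, ], sig_reg)
        enr[[paste(reg, dir, sep = "_")]] <- test_gene_sets(
          sig_genes, universe, sets, weights,
          direction = dir, region = reg, n_perm = n_perm,
          seed = derive_seed(config$seed, 3L))
      }
    }
    res$enrichment <- dplyr::bind_rows(enr)
    if (nrow(res$enrichment %||% tibble::tibble()) > 0) {
      res$top_terms <- top_terms(res$enrichment, k = k_top)
      emit(res$enrichment, "enrichment.csv")
      emit(res$top_terms, "enrichment_top_terms.csv")
    }
  }

  if ("deconv" %in% stages) {
    log_msg("stage deconv")
    imm <- generate_immune_mixtures(config, cohort$sheet)
    est <- estimate_fractions(imm$mixtures, imm$reference)
    res$deconvolution <- list(
      estimates = est,
      comparison = compare_pre_post_fractions(est, cohort$sheet,
                                              subgroup = "survivor")
    )
    emit(est, "immune_fractions.csv")
    emit(res$deconvolution$comparison, "immune_pre_post.csv")
  }

  if ("risk" %in% stages && !is.null(survivor_res)) {
    log_msg("stage risk")
    sig_tab <- survivor_res[survivor_res$significant, ]
    candidates <- head(sig_tab$cpg_id, max_candidates)
    if (length(candidates) >= 2L) {
      dB <- build_delta_beta(beta, cohort$sheet, candidates)
      y <- five_year_death(cohort$sheet, dB$patient_id)
      sel <- loo_lasso_select(dB, y,
                              stability_threshold = stability_threshold,
                              seed = derive_seed(config$seed, 4L))
      res$risk <- c(sel, list(
        scores = apply_risk_score(sel$model, dB),
        groups = assign_groups_loo(sel$loo)
      ))
      if (write_out) {
        write_risk_model(sel$model, file.path(outdir, "risk_model.json"))
        emit(res$risk$scores, "risk_scores.csv")
        emit(res$risk$groups, "risk_groups.csv")
      }
    } else {
      log_msg("stage risk skipped: fewer than 2 candidate CpGs")
    }
  }

  if ("survival" %in% stages && !is.null(res$risk)) {
    log_msg("stage survival")
    if (length(unique(res$risk$groups$group)) == 2L) {
      res$survival <- risk_group_survival(res$risk$groups, cohort$sheet)
      if (write_out) {
        curves <- dplyr::bind_rows(lapply(
          names(res$survival$fits),
          function(g) dplyr::mutate(tidy(res$survival$fits[[g]]), group = g)))
        emit(curves, "survival_curves.csv")
        jsonlite::write_json(res$survival$logrank,
                             file.path(outdir, "logrank.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    } else {
      log_msg("stage survival skipped: only one risk group predicted")
    }
    # external validation on an independently simulated cohort
    vconfig <- config
    vconfig$seed <- derive_seed(config$seed, 5L)
    vcohort <- generate_cohort(vconfig, template = cohort)
    if (!res$risk$model$empty) {
      vdB <- build_delta_beta(vcohort$beta, vcohort$sheet,
                              res$risk$model$cpgs$cpg_id)
      vscores <- apply_risk_score(res$risk$model, vdB)
      vgroups <- assign_groups_median(vscores)
      res$validation <- risk_group_survival(vgroups, vcohort$sheet)
      if (write_out) {
        jsonlite::write_json(res$validation$logrank,
                             file.path(outdir, "logrank_validation.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  res$provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("deltameth"))
  )
  if (write_out) {
    jsonlite::write_json(res$provenance,
                         file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  class(res) <- "pipeline_result"
  res
}
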