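# Region classification (context x island), gain/loss proportions per
# region, and the toward-normal-tissue direction statistic.

region_levels <- c("promoter_cgi", "promoter_non_cgi", "body_cgi",
                   "body_non_cgi", "intergenic_cgi", "intergenic_non_cgi")

#' Classify CpGs into the six genomic regions of interest
#'
#' Deterministic cross of genomic context (promoter, gene body, intergenic)
#' and CpG-island status.
#'
#' @param annot A validated CpG annotation tibble.
#' @return The annotation with an added `region` factor column.
#' @export
classify_region <- function(annot) {
  annot <- validate_cpg_annotation(annot)
  ctx <- c(promoter = "promoter", gene_body = "body",
           intergenic = "intergenic")[annot$genomic_context]
  region <- paste0(ctx, "_", annot$island)
  annot$region <- factor(region, levels = region_levels)
  annot
}

#' Gain/loss proportions of significant sites per genomic region
#'
#' For each region, the proportion of array CpGs in that region that are
#' significant with a methylation gain (respectively loss): significant
#' count divided by the number of array sites in the region.
#'
#' @param results A `meth_diff` result (or any tibble with `cpg_id`,
#'   `significant`, `direction`).
#' @param annot A CpG annotation covering all result CpGs.
#' @return A `region_summary` tibble: `region`, `n_array_sites`,
#'   `n_significant_gain`, `n_significant_loss`, `proportion_gain`,
#'   `proportion_loss`, `empty_region` flag.
#' @export
region_proportions <- function(results, annot) {
  annot <- classify_region(annot)
  missing_ids <- setdiff(results$cpg_id, annot$cpg_id)
  if (length(missing_ids) > 0L) {
    abort(paste0("CpGs absent from annotation: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  sig <- tibble::as_tibble(results)[, c("cpg_id", "significant", "direction")]
  joined <- annot |>
    dplyr::left_join(sig, by = "cpg_id") |>
    dplyr::mutate(significant = !is.na(.data$significant) & .data$significant)
  out <- joined |>
    dplyr::group_by(region = .data$region, .drop = FALSE) |>
    dplyr::summarise(
      n_array_sites = dplyr::n(),
      n_significant_gain = sum(.data$significant & .data$direction == "gain",
                               na.rm = TRUE),
      n_significant_loss = sum(.data$significant & .data$direction == "loss",
                               na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      empty_region = .data$n_array_sites == 0L,
      proportion_gain = ifelse(.data$empty_region, 0,
                               .data$n_significant_gain / .data$n_array_sites),
      proportion_loss = ifelse(.data$empty_region, 0,
                               .data$n_significant_loss / .data$n_array_sites)
    )
  class(out) <- c("region_summary", class(out))
  out
}

#' Bar chart of gain/loss proportions per region
#'
#' @param object A `region_summary` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_summary
#' @export
autoplot.region_summary <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("proportion_gain", "proportion_loss"),
                        names_to = "direction", values_to = "proportion",
                        names_prefix = "proportion_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$proportion,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(gain = "steelblue",
                                          loss = "firebrick")) +
    ggplot2::labs(x = NULL, y = "proportion of array sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Fraction of changed CpGs moving toward the normal-tissue mean
#'
#' For each evaluated CpG the mean beta over pre-treatment samples and over
#' post-treatment samples of `sheet` is compared with the normal-tissue
#' mean: the site counts as "toward normal" iff
#' `|mean_post - normal| < |mean_pre - normal|`; ties count as not-toward.
#' Sites absent from the reference are excluded and counted.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet restricted to the subgroup the significant
#'   sites came from (e.g. survivors).
#' @param cpg_ids CpGs to evaluate (typically the significant sites).
#' @param normal Normal reference tibble (`cpg_id`, `mean_beta`).
#' @return A list with `n_evaluated`, `n_toward`, `fraction_toward`,
#'   `n_missing_reference` and the per-site tibble `sites`.
#' @export
toward_normal_fraction <- function(beta, sheet, cpg_ids, normal) {
  sheet <- validate_sample_sheet(sheet)
  b <- meth_matrix(beta)
  cpg_ids <- unique(as.character(cpg_ids))
  missing_mat <- setdiff(cpg_ids, rownames(b))
  if (length(missing_mat) > 0L) {
    abort(paste0("CpGs absent from beta matrix: ",
                 paste(head(missing_mat, 5), collapse = ", ")))
  }
  in_ref <- cpg_ids %in% normal$cpg_id
  n_missing <- sum(!in_ref)
  eval_ids <- cpg_ids[in_ref]
  b <- b[eval_ids, sheet$sample_id, drop = FALSE]
  pre <- sheet$timepoint == "pre"
  m_pre <- rowMeans(b[, pre, drop = FALSE], na.rm = TRUE)
  m_post <- rowMeans(b[, !pre, drop = FALSE], na.rm = TRUE)
  mu_n <- normal$mean_beta[match(eval_ids, normal$cpg_id)]
  m_pre <- unname(m_pre)
  m_post <- unname(m_post)
  toward <- abs(m_post - mu_n) < abs(m_pre - mu_n)
  list(
    n_evaluated = length(eval_ids),
    n_toward = sum(toward),
    fraction_toward = if (length(eval_ids) > 0) mean(toward) else NA_real_,
    n_missing_reference = n_missing,
    sites = tibble::tibble(cpg_id = eval_ids, mean_beta_pre = m_pre,
                           mean_beta_post = m_post, normal_mean = mu_n,
                           toward = toward)
  )
}
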