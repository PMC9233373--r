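# Gene-set overrepresentation of significant CpG-bearing genes with a
# permutation null that corrects for the per-gene probe-count selection
# bias: genes with many array probes are more likely to carry at least one
# significant CpG, so null gene draws are weighted by an isotonic fit of
# P(gene significant) against log probe count.

#' Estimate per-gene probe-count selection weights
#'
#' Fits a monotone (isotonic) curve of the probability that a gene carries
#' at least one significant CpG against log probe count, over probe-count
#' bins, and returns per-gene weights proportional to the fitted
#' probability, normalised to mean 1.
#'
#' @param annot CpG annotation (maps CpGs to genes).
#' @param significant_cpgs Character vector of significant CpG ids.
#' @return A tibble with `gene`, `n_probes`, `significant`, `weight`.
#' @export
estimate_probe_bias <- function(annot, significant_cpgs) {
  annot <- validate_cpg_annotation(annot)
  genic <- annot[annot$gene != "", c("cpg_id", "gene")]
  genes <- genic |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      significant = any(.data$cpg_id %in% significant_cpgs),
      .groups = "drop"
    )
  if (length(unique(genes$n_probes)) < 2L) {
    warn("fewer than 2 distinct probe counts; using uniform weights")
    genes$weight <- 1
    return(genes)
  }
  bins <- genes |>
    dplyr::group_by(n_probes = .data$n_probes) |>
    dplyr::summarise(p_sig = mean(.data$significant), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$n_probes)
  iso <- isoreg(log(bins$n_probes), bins$p_sig)
  fitted <- iso$yf[order(order(log(bins$n_probes)))]
  w_bin <- setNames(fitted, bins$n_probes)
  w <- w_bin[as.character(genes$n_probes)]
  # floor so zero-probability genes stay sampleable, then mean-1 normalise
  floor_w <- max(min(w[w > 0], na.rm = TRUE) / 2, 1e-8)
  w <- pmax(w, floor_w)
  genes$weight <- as.numeric(w / mean(w))
  genes
}

#' Permutation test of gene-set overrepresentation
#'
#' For each set, counts the overlap between the significant genes and the
#' set, then compares it with a null in which `length(significant)` genes
#' are drawn from the universe without replacement with probability
#' proportional to the probe-bias weights. `p = (1 + #\{null >= observed\}) /
#' (1 + n_perm)`; BH across sets gives the FDR.
#'
#' @param significant_genes Character vector of significant genes.
#' @param universe Character vector of all testable genes.
#' @param sets Gene sets tibble from [read_gmt()].
#' @param weights Optional tibble from [estimate_probe_bias()] (or NULL for
#'   uniform weights).
#' @param direction,region Labels carried into the result.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed for the permutation draws.
#' @return An `enrichment_result` tibble: `set`, `region`, `direction`,
#'   `n_genes_in_set`, `n_significant_in_set`, `p`, `fdr`, `neg_log10_fdr`,
#'   with skipped sets in the `skipped` attribute.
#' @export
test_gene_sets <- function(significant_genes, universe, sets, weights = NULL,
                           direction = NA_character_, region = NA_character_,
                           n_perm = 10000, seed = 1) {
  if (n_perm < 1000) abort("n_perm must be >= 1000")
  universe <- unique(as.character(universe))
  significant_genes <- intersect(unique(significant_genes), universe)
  m <- length(significant_genes)
  w <- rep(1, length(universe))
  if (!is.null(weights)) {
    idx <- match(universe, weights$gene)
    w <- weights$weight[idx]
    w[is.na(w)] <- 1
  }
  set_members <- lapply(sets$genes, intersect, y = universe)
  keep <- lengths(set_members) > 0L
  skipped <- sets$set[!keep]
  sets_kept <- sets$set[keep]
  set_members <- set_members[keep]
  if (length(sets_kept) == 0L) {
    abort("no gene set overlaps the universe")
  }
  member_mat <- vapply(set_members, function(g) universe %in% g,
                       logical(length(universe)))
  obs <- as.integer(colSums(member_mat[match(significant_genes, universe), ,
                                       drop = FALSE]))
  if (m == 0L) {
    p <- rep(1, length(sets_kept))
  } else {
    set.seed(seed)
    exceed <- integer(length(sets_kept))
    for (b in seq_len(n_perm)) {
      draw <- sample.int(length(universe), m, replace = FALSE, prob = w)
      null_overlap <- colSums(member_mat[draw, , drop = FALSE])
      exceed <- exceed + (null_overlap >= obs)
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  fdr <- bh_adjust(p)
  out <- tibble::tibble(
    set = sets_kept, region = region, direction = direction,
    n_genes_in_set = lengths(set_members),
    n_significant_in_set = obs,
    p = p, fdr = fdr, neg_log10_fdr = -log10(fdr)
  )
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Top enriched terms per stratum
#'
#' Stable sort by (fdr, p, set name), head `k` within each region x
#' direction stratum.
#'
#' @param results An `enrichment_result` tibble (strata may be mixed).
#' @param k Number of terms per stratum; default 6.
#' @return The top-`k` rows per stratum.
#' @export
top_terms <- function(results, k = 6) {
  if (k <= 0) return(results[0, , drop = FALSE])
  tibble::as_tibble(results) |>
    dplyr::group_by(.data$region, .data$direction) |>
    dplyr::arrange(.data$fdr, .data$p, .data$set, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}
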