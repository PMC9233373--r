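# Reference-based immune-cell deconvolution: per sample, the beta values at
# the signature CpGs are regressed on the reference profiles by constrained
# least-absolute-deviation (LAD):
#   min_f sum_i | beta_i - sum_k f_k S_ik |  s.t.  f_k >= 0, sum_k f_k <= 1,
# then renormalised to relative fractions. The LAD fit is solved by IRLS
# with quadprog-constrained weighted-least-squares subproblems (no LP
# solver is available; the objective is unchanged).

solve_lad <- function(y, S, max_iter = 60, delta = 1e-6, tol = 1e-10) {
  k <- ncol(S)
  Amat <- cbind(diag(k), -rep(1, k))          # f >= 0, -sum(f) >= -1
  bvec <- c(rep(0, k), -1)
  w <- rep(1, length(y))
  f <- rep(1 / (k + 1), k)
  for (it in seq_len(max_iter)) {
    Sw <- S * w
    Dmat <- crossprod(Sw, S) + diag(1e-10, k)
    dvec <- crossprod(Sw, y)
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, Amat, bvec),
      error = function(e) abort(paste0(
        "deconvolution fit is degenerate (", conditionMessage(e),
        "); condition number of S'S: ",
        format(kappa(crossprod(S)), digits = 3)))
    )
    f_new <- pmax(sol$solution, 0)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
    w <- as.numeric(1 / pmax(abs(y - S %*% f), delta))
  }
  f
}

#' Estimate immune-cell fractions from methylation signatures
#'
#' Each sample's betas at the signature CpGs are fit as a nonnegative
#' combination of the reference cell-type profiles under the constrained
#' LAD objective, then scaled to relative fractions `f / sum(f)`.
#'
#' @param mixtures Beta tibble of the samples, covering the signature CpGs.
#' @param reference Signature tibble: `cpg_id` plus one column per cell
#'   type, beta scale (at least two cell types).
#' @return A `fraction_estimate` tibble: `sample_id`, one column per cell
#'   type (relative fractions), `residual` (mean absolute deviation of the
#'   fit) and `undefined` flag (all-zero raw solution).
#' @export
estimate_fractions <- function(mixtures, reference) {
  S_full <- meth_matrix(reference)
  if (ncol(S_full) < 2L) abort("reference needs at least 2 cell types")
  if (any(S_full < 0 | S_full > 1, na.rm = TRUE)) {
    abort("reference values must be betas in [0,1]")
  }
  b <- meth_matrix(mixtures)
  shared <- intersect(rownames(S_full), rownames(b))
  if (length(shared) < ncol(S_full) + 1L) {
    abort("need more observed signature CpGs than cell types")
  }
  S_full <- S_full[shared, , drop = FALSE]
  b <- b[shared, , drop = FALSE]
  rows <- lapply(colnames(b), function(sid) {
    y <- b[, sid]
    obs <- !is.na(y)
    if (sum(obs) < ncol(S_full) + 1L) {
      abort(sprintf("sample %s observes too few signature CpGs", sid))
    }
    f <- solve_lad(y[obs], S_full[obs, , drop = FALSE])
    tot <- sum(f)
    undefined <- tot <= 1e-8
    rel <- if (undefined) rep(NA_real_, length(f)) else f / tot
    resid <- mean(abs(y[obs] - S_full[obs, , drop = FALSE] %*% f))
    tibble::tibble(sample_id = sid,
                   cell_type = colnames(S_full),
                   fraction = rel, residual = resid, undefined = undefined)
  })
  out <- dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "fraction")
  class(out) <- c("fraction_estimate", class(out))
  out
}

# U statistic (number of (x, y) pairs with x > y, ties 0.5) from pooled ranks
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration of all group labelings when `length(x) + length(y) <=
#' 12`; otherwise the normal approximation with tie and continuity
#' corrections. Two-sided p-values measure how extreme the U statistic is
#' relative to its null mean.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A list with `U` (for the first group) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  u_obs <- u_statistic(x, y)
  centre <- n1 * n2 / 2
  if (max(pooled) == min(pooled)) {
    return(list(U = u_obs, p = 1))
  }
  if (n <= 12L) {
    labelings <- combn(n, n1)
    dev <- abs(apply(labelings, 2, function(idx) {
      u_statistic(pooled[idx], pooled[-idx])
    }) - centre)
    p <- mean(dev >= abs(u_obs - centre) - 1e-12)
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u_obs, p = 1))
    z <- (abs(u_obs - centre) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  list(U = u_obs, p = p)
}

#' Compare immune fractions before vs after treatment within a subgroup
#'
#' Per cell type, an (unpaired) rank-sum test of the pre- vs post-treatment
#' relative fractions among the samples of the subgroup, as the source
#' analysis specifies despite the partially paired design.
#'
#' @param estimates A `fraction_estimate` tibble from [estimate_fractions()].
#' @param sheet Sample sheet covering the estimated samples.
#' @param subgroup Level of `group_col` to restrict to; default "survivor".
#' @param group_col Sheet column holding the grouping; default
#'   `survival_group`.
#' @return A tibble with `cell_type`, `n_pre`, `n_post`, `delta_median`
#'   (post - pre), `U`, `p`, and a `low_n` flag when either side has fewer
#'   than 3 samples.
#' @export
compare_pre_post_fractions <- function(estimates, sheet,
                                       subgroup = "survivor",
                                       group_col = "survival_group") {
  sheet <- validate_sample_sheet(sheet)
  keep <- sheet$sample_id[sheet[[group_col]] == subgroup]
  long <- tibble::as_tibble(estimates) |>
    dplyr::select(-dplyr::any_of(c("residual", "undefined"))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction") |>
    dplyr::filter(.data$sample_id %in% keep, !is.na(.data$fraction)) |>
    dplyr::left_join(sheet[, c("sample_id", "timepoint")], by = "sample_id")
  if (nrow(long) == 0L) abort("subgroup has no estimated samples")
  long |>
    dplyr::group_by(cell_type = .data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      pre <- df$fraction[df$timepoint == "pre"]
      post <- df$fraction[df$timepoint == "post"]
      if (length(pre) == 0L || length(post) == 0L) {
        return(tibble::tibble(n_pre = length(pre), n_post = length(post),
                              delta_median = NA_real_, U = NA_real_,
                              p = NA_real_, low_n = TRUE))
      }
      ts <- rank_sum_test(pre, post)
      tibble::tibble(
        n_pre = length(pre), n_post = length(post),
        delta_median = median(post) - median(pre),
        U = ts$U, p = ts$p,
        low_n = length(pre) < 3L || length(post) < 3L
      )
    }) |>
    dplyr::ungroup()
}

#' Box plot of estimated fractions by timepoint
#'
#' @param object A `fraction_estimate` tibble.
#' @param sheet Sample sheet (for the timepoint of each sample).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fraction_estimate
#' @export
autoplot.fraction_estimate <- function(object, sheet, ...) {
  sheet <- validate_sample_sheet(sheet)
  long <- tibble::as_tibble(object) |>
    dplyr::select(-dplyr::any_of(c("residual", "undefined"))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction") |>
    dplyr::inner_join(sheet[, c("sample_id", "timepoint")], by = "sample_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$fraction,
                                     fill = .data$timepoint)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "relative fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
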