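# Paired / partially paired differential methylation on M-values.
#
# The "linear mixed model" is realised, as in the reference analysis path,
# as a two-stage consensus-correlation approximation: (1) estimate a single
# intra-patient correlation shared across CpGs from per-CpG REML fits of a
# patient random intercept; (2) per CpG, generalised least squares with a
# block-equicorrelated covariance (consensus correlation within patient,
# zero across), followed by empirical-Bayes moderation of the residual
# variances and Benjamini-Hochberg control.

# ---- internal: design & whitening ------------------------------------------

# Align an M tibble and sample sheet; returns list(Y samples x CpGs, sheet,
# X design [intercept, post], pair index rows of pre/post samples)
build_design <- function(m, sheet) {
  mm <- meth_matrix(m)
  sheet <- validate_sample_sheet(sheet)
  missing_samples <- setdiff(sheet$sample_id, colnames(mm))
  if (length(missing_samples) > 0L) {
    abort(paste0("samples in sheet but not in matrix: ",
                 paste(missing_samples, collapse = ", ")))
  }
  mm <- mm[, sheet$sample_id, drop = FALSE]
  pairs <- pairing_index(sheet) |> dplyr::filter(.data$paired)
  list(
    Y = t(mm),
    sheet = sheet,
    X = cbind(intercept = 1, post = as.numeric(sheet$timepoint == "post")),
    pre_idx = match(pairs$pre, sheet$sample_id),
    post_idx = match(pairs$post, sheet$sample_id)
  )
}

# Whiten rows of A (samples x k) under block-equicorrelation rho: the second
# member of each patient pair becomes (x_b - rho * x_a) / sqrt(1 - rho^2).
whiten <- function(A, pre_idx, post_idx, rho) {
  if (length(pre_idx) == 0L || rho == 0) return(A)
  s <- sqrt(1 - rho^2)
  A[post_idx, ] <- (A[post_idx, , drop = FALSE] -
                      rho * A[pre_idx, , drop = FALSE]) / s
  A
}

# ---- consensus correlation --------------------------------------------------

#' Estimate the consensus intra-patient correlation
#'
#' Per CpG, a patient random-intercept model on the pre/post design is fit by
#' REML, profiled over the intra-patient correlation
#' `rho = var(intercept) / var(total)` on a grid with parabolic refinement.
#' The consensus is the 15%-trimmed mean of the per-CpG estimates on the
#' atanh scale, transformed back with tanh.
#'
#' @param m M-value tibble.
#' @param sheet Validated sample sheet; at least one patient must have both
#'   timepoints.
#' @param n_cpgs Maximum number of CpGs used (evenly spaced subset when the
#'   matrix is larger); default 500. `Inf` uses all complete CpGs.
#' @param trim Trimming fraction for the consensus; default 0.15.
#' @param rho_limits Search range for the per-CpG correlation.
#' @return An object of class `consensus_correlation`: a list with
#'   `consensus`, per-CpG estimates `rho` (tibble), `n_cpgs_used`, and
#'   `n_excluded` (constant or incomplete CpGs).
#' @export
estimate_consensus_correlation <- function(m, sheet, n_cpgs = 500,
                                           trim = 0.15,
                                           rho_limits = c(-0.45, 0.98)) {
  d <- build_design(m, sheet)
  if (length(d$pre_idx) == 0L) {
    abort("pairing required: no patient has both a pre and a post sample")
  }
  Y <- d$Y
  complete <- colSums(is.na(Y)) == 0L
  nonconst <- apply(Y, 2, function(y) {
    r <- range(y, na.rm = TRUE); (r[2] - r[1]) > 0
  })
  keep <- which(complete & nonconst)
  n_excluded <- ncol(Y) - length(keep)
  if (length(keep) < 2L) abort("too few usable CpGs for consensus estimation")
  if (is.finite(n_cpgs) && length(keep) > n_cpgs) {
    keep <- keep[round(seq(1, length(keep), length.out = n_cpgs))]
  }
  Y <- Y[, keep, drop = FALSE]
  n <- nrow(Y)
  grid <- seq(rho_limits[1], rho_limits[2], length.out = 60L)
  crit <- matrix(NA_real_, length(grid), ncol(Y))
  for (i in seq_along(grid)) {
    crit[i, ] <- reml_criterion(Y, d$X, d$pre_idx, d$post_idx, grid[i], n)
  }
  best <- max.col(-t(crit), ties.method = "first")
  step <- grid[2] - grid[1]
  rho_hat <- vapply(seq_len(ncol(Y)), function(g) {
    i <- best[g]
    if (i == 1L || i == length(grid)) return(grid[i])
    cm <- crit[i - 1L, g]; c0 <- crit[i, g]; cp <- crit[i + 1L, g]
    denom <- cm - 2 * c0 + cp
    delta <- if (denom > 0) 0.5 * (cm - cp) / denom else 0
    grid[i] + max(-0.5, min(0.5, delta)) * step
  }, numeric(1))
  consensus <- tanh(mean(atanh(rho_hat), trim = trim))
  structure(
    list(
      consensus = consensus,
      rho = tibble::tibble(cpg_id = rownames(meth_matrix(m))[keep],
                           rho = rho_hat),
      n_cpgs_used = length(rho_hat),
      n_excluded = n_excluded
    ),
    class = "consensus_correlation"
  )
}

# Profiled REML criterion (to be minimised) for all CpGs at one rho:
#   (n - p) * log(RSS_gls) + log|V| + log|X' V^-1 X|
reml_criterion <- function(Y, X, pre_idx, post_idx, rho, n) {
  Yt <- whiten(Y, pre_idx, post_idx, rho)
  Xt <- whiten(X, pre_idx, post_idx, rho)
  C <- crossprod(Xt)
  Ci <- solve(C)
  A <- crossprod(Xt, Yt)                      # 2 x G
  qf <- Ci[1, 1] * A[1, ]^2 + 2 * Ci[1, 2] * A[1, ] * A[2, ] +
    Ci[2, 2] * A[2, ]^2
  rss <- pmax(colSums(Yt^2) - qf, 1e-300)
  ldV <- length(pre_idx) * log(1 - rho^2)
  (n - 2) * log(rss) + ldV + determinant(C, logarithm = TRUE)$modulus[1]
}

#' @export
print.consensus_correlation <- function(x, ...) {
  cat(sprintf(
    "Consensus intra-patient correlation: %.4f (from %d CpGs, %d excluded)\n",
    x$consensus, x$n_cpgs_used, x$n_excluded))
  invisible(x)
}

# ---- per-CpG GLS -------------------------------------------------------------

#' Per-CpG generalised least squares pre-vs-post fit
#'
#' Fits `M ~ timepoint` per CpG with a block-equicorrelated covariance:
#' correlation `consensus` between the two samples of a patient, zero across
#' patients; unpaired samples form singleton blocks. CpGs with fewer than
#' `min_per_group` non-missing samples in either timepoint are skipped with a
#' reason.
#'
#' @param m M-value tibble.
#' @param sheet Validated sample sheet.
#' @param consensus A `consensus_correlation` object or a plain correlation
#'   in (-1, 1).
#' @param min_per_group Minimum non-missing samples per timepoint; default 3.
#' @return A list with `fits` (tibble: `cpg_id`, `effect` = post - pre on the
#'   M scale, `sigma2`, `df`, `se_unit`) and `skipped` (tibble of CpG, reason).
#' @export
fit_gls_per_cpg <- function(m, sheet, consensus, min_per_group = 3) {
  rho <- if (inherits(consensus, "consensus_correlation")) {
    consensus$consensus
  } else {
    consensus
  }
  if (!is.numeric(rho) || abs(rho) >= 1) abort("consensus must be in (-1, 1)")
  d <- build_design(m, sheet)
  Y <- d$Y
  n_pre <- colSums(!is.na(Y[d$X[, "post"] == 0, , drop = FALSE]))
  n_post <- colSums(!is.na(Y[d$X[, "post"] == 1, , drop = FALSE]))
  low_n <- n_pre < min_per_group | n_post < min_per_group
  complete <- colSums(is.na(Y)) == 0L

  fit_rows <- list()
  # fast path: complete CpGs share design and whitening
  idx_fast <- which(complete & !low_n)
  if (length(idx_fast) > 0L) {
    Yt <- whiten(Y[, idx_fast, drop = FALSE], d$pre_idx, d$post_idx, rho)
    Xt <- whiten(d$X, d$pre_idx, d$post_idx, rho)
    C <- crossprod(Xt)
    Ci <- solve(C)
    A <- crossprod(Xt, Yt)
    coefs <- Ci %*% A                          # 2 x G
    qf <- colSums(A * coefs)
    dfree <- nrow(Yt) - 2L
    rss <- pmax(colSums(Yt^2) - qf, 0)
    fit_rows[["fast"]] <- tibble::tibble(
      cpg_id = colnames(Y)[idx_fast],
      effect = unname(coefs[2, ]),
      sigma2 = unname(rss / dfree),
      df = dfree,
      se_unit = sqrt(Ci[2, 2])
    )
  }
  # slow path: CpGs with missing values re-derive blocks per CpG
  idx_slow <- which(!complete & !low_n)
  for (g in idx_slow) {
    obs <- which(!is.na(Y[, g]))
    keep_pair <- d$pre_idx %in% obs & d$post_idx %in% obs
    pre_i <- match(d$pre_idx[keep_pair], obs)
    post_i <- match(d$post_idx[keep_pair], obs)
    yt <- whiten(matrix(Y[obs, g], ncol = 1), pre_i, post_i, rho)
    Xt <- whiten(d$X[obs, , drop = FALSE], pre_i, post_i, rho)
    C <- crossprod(Xt)
    Ci <- solve(C)
    a <- crossprod(Xt, yt)
    co <- Ci %*% a
    dfree <- length(obs) - 2L
    rss <- max(sum(yt^2) - sum(a * co), 0)
    fit_rows[[colnames(Y)[g]]] <- tibble::tibble(
      cpg_id = colnames(Y)[g], effect = unname(co[2, 1]),
      sigma2 = unname(rss / dfree), df = dfree,
      se_unit = unname(sqrt(Ci[2, 2]))
    )
  }
  fits <- dplyr::bind_rows(fit_rows)
  # restore input CpG order
  fits <- fits[order(match(fits$cpg_id, colnames(Y))), , drop = FALSE]
  skipped <- tibble::tibble(
    cpg_id = colnames(Y)[low_n],
    reason = sprintf("fewer than %d non-missing samples in a timepoint group",
                     min_per_group)
  )
  list(fits = fits, skipped = skipped)
}

# ---- empirical-Bayes moderation ---------------------------------------------

# Newton inversion of the trigamma function (method-of-moments prior df)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  x
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Estimates a scaled inverse-chi-square prior (`d0`, `s0^2`) for the
#' residual variances by moment matching on the log scale
#' (digamma/trigamma), shrinks each variance to the posterior
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` and returns moderated
#' t-statistics with `d + d0` degrees of freedom. Zero-variance CpGs are
#' excluded from moderation and reported with NA statistics.
#'
#' @param fits The `fits` tibble from [fit_gls_per_cpg()].
#' @return A list with `table` (tibble: `cpg_id`, `effect`, `t`, `p`,
#'   `s2_post`) and `params` (`d0`, `s0_2`, `n_zero_variance`).
#' @export
empirical_bayes_moderate <- function(fits) {
  ok <- is.finite(fits$sigma2) & fits$sigma2 > 0 & fits$df > 0
  if (sum(ok) < 10L) abort("need >= 10 CpGs with positive residual df")
  s2 <- fits$sigma2[ok]
  dfree <- fits$df[ok]
  z <- log(s2)
  e <- z - digamma(dfree / 2) + log(dfree / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(dfree / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # degenerate spread: infinite prior df; the geometric mean keeps
    # s_tilde^2 equal to the common variance when all variances coincide
    d0 <- Inf
    s0_2 <- exp(mean(z))
  }
  s2_post <- rep(NA_real_, nrow(fits))
  s2_post[ok] <- if (is.infinite(d0)) {
    rep(s0_2, sum(ok))
  } else {
    (d0 * s0_2 + dfree * s2) / (d0 + dfree)
  }
  tval <- fits$effect / (sqrt(s2_post) * fits$se_unit)
  df_total <- fits$df + d0
  pval <- 2 * pt(-abs(tval), df = df_total)
  list(
    table = tibble::tibble(
      cpg_id = fits$cpg_id, effect = fits$effect,
      t = tval, p = pval, s2_post = s2_post
    ),
    params = list(d0 = d0, s0_2 = s0_2, n_zero_variance = sum(!ok))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, in input order.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

# ---- end-to-end per-group comparison ----------------------------------------

#' Differential methylation, pre vs post, for one sample set
#'
#' Runs the full engine on one cohort/subgroup: beta to M transform,
#' consensus intra-patient correlation, per-CpG GLS, empirical-Bayes
#' moderation and BH adjustment. Sites with adjusted p below `alpha` are
#' flagged significant; direction is `gain` when the post - pre effect is
#' positive, `loss` otherwise.
#'
#' @param beta Beta tibble.
#' @param sheet Validated sample sheet (already restricted to the subgroup
#'   of interest).
#' @param alpha Significance threshold on the BH-adjusted p; default 0.01.
#' @param epsilon Clipping bound for the M transform.
#' @param n_consensus_cpgs Passed to [estimate_consensus_correlation()].
#' @param consensus Optional precomputed consensus correlation (skips
#'   re-estimation).
#' @return A `meth_diff` object: the per-CpG result tibble (`cpg_id`,
#'   `effect`, `mean_beta_pre`, `mean_beta_post`, `t`, `p`, `p_adj`,
#'   `significant`, `direction`), sorted by `p_adj`, carrying the consensus,
#'   moderation parameters and skipped CpGs as attributes.
#' @export
diff_methylation <- function(beta, sheet, alpha = 0.01, epsilon = 1e-3,
                             n_consensus_cpgs = 500, consensus = NULL) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  sheet <- validate_sample_sheet(sheet)
  m <- beta_to_m(beta, epsilon)
  if (is.null(consensus)) {
    consensus <- estimate_consensus_correlation(m, sheet,
                                                n_cpgs = n_consensus_cpgs)
  }
  gls <- fit_gls_per_cpg(m, sheet, consensus)
  mod <- empirical_bayes_moderate(gls$fits)
  b <- meth_matrix(beta)[, sheet$sample_id, drop = FALSE]
  pre_cols <- sheet$timepoint == "pre"
  mb_pre <- rowMeans(b[, pre_cols, drop = FALSE], na.rm = TRUE)
  mb_post <- rowMeans(b[, !pre_cols, drop = FALSE], na.rm = TRUE)
  res <- mod$table |>
    dplyr::mutate(
      mean_beta_pre = unname(mb_pre[.data$cpg_id]),
      mean_beta_post = unname(mb_post[.data$cpg_id]),
      p_adj = bh_adjust(.data$p),
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha,
      direction = ifelse(.data$effect > 0, "gain", "loss")
    ) |>
    dplyr::select("cpg_id", "effect", "mean_beta_pre", "mean_beta_post",
                  "t", "p", "p_adj", "significant", "direction") |>
    dplyr::arrange(.data$p_adj, .data$p)
  structure(res,
            class = c("meth_diff", class(res)),
            consensus = consensus,
            moderation = mod$params,
            skipped = gls$skipped,
            alpha = alpha)
}

#' @method tidy meth_diff
#' @export
tidy.meth_diff <- function(x, ...) {
  tibble::as_tibble(unclass2_tbl(x))
}

#' @method glance meth_diff
#' @export
glance.meth_diff <- function(x, ...) {
  mod <- attr(x, "moderation")
  tibble::tibble(
    n_cpgs = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    consensus = attr(x, "consensus")$consensus,
    d0 = mod$d0,
    s0_2 = mod$s0_2,
    n_skipped = nrow(attr(x, "skipped"))
  )
}

unclass2_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("meth_diff"))
  attr(x, "consensus") <- NULL
  attr(x, "moderation") <- NULL
  attr(x, "skipped") <- NULL
  attr(x, "alpha") <- NULL
  x
}

#' Volcano plot of a differential methylation result
#'
#' @param object A `meth_diff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_diff
#' @export
autoplot.meth_diff <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * M ~ "(post - pre)"),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Run the pre-vs-post comparison within each subgroup
#'
#' For every level of every grouping column (default: survival group,
#' clinical response, treatment arm) the full differential pipeline is run
#' on the samples of that level. Subgroups without any paired patient are
#' skipped with a logged reason.
#'
#' @param beta Beta tibble.
#' @param sheet Validated sample sheet.
#' @param group_by Character vector of sheet columns to stratify on.
#' @param alpha Significance threshold; default 0.01.
#' @param ... Passed to [diff_methylation()].
#' @return A named list of `meth_diff` tables (`"column:level"`), with a
#'   `skipped` attribute naming subgroups that could not be compared.
#' @export
run_group_comparisons <- function(beta, sheet,
                                  group_by = c("survival_group", "response",
                                               "treatment"),
                                  alpha = 0.01, ...) {
  sheet <- validate_sample_sheet(sheet)
  group_by <- intersect(group_by, names(sheet))
  out <- list()
  skipped <- character()
  for (col in group_by) {
    for (lev in sort(unique(sheet[[col]][!is.na(sheet[[col]])]))) {
      key <- paste0(col, ":", lev)
      sub <- sheet[!is.na(sheet[[col]]) & sheet[[col]] == lev, , drop = FALSE]
      if (!any(duplicated(sub$patient_id))) {
        skipped[key] <- "no paired patients in subgroup"
        next
      }
      out[[key]] <- diff_methylation(beta, sub, alpha = alpha, ...)
    }
  }
  attr(out, "skipped") <- skipped
  out
}
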