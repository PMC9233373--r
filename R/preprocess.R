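# Array preprocessing: detection filtering, type-II peak correction,
# quantile normalisation and the beta <-> M transforms.
#
# Scale conventions (the source order is filter -> peak correction ->
# quantile normalisation): the detection filter acts on betas, peak
# correction on M-values, quantile normalisation back on betas; modelling
# then uses M = log2(beta / (1 - beta)).

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`, with betas clipped to `[epsilon, 1 - epsilon]`
#' first so boundary betas do not map to +/-Inf. Missing values stay missing.
#'
#' @param beta A beta tibble (`cpg_id` + samples) or numeric matrix/vector.
#' @param epsilon Clipping bound in `(0, 0.5)`; default `1e-3`.
#' @return Same shape as the input, on the M scale.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  assert_scalar_number(epsilon, "epsilon")
  if (epsilon <= 0 || epsilon >= 0.5) abort("epsilon must be in (0, 0.5)")
  f <- function(b) {
    b <- pmin(pmax(b, epsilon), 1 - epsilon)
    log2(b / (1 - b))
  }
  transform_meth(beta, f)
}

#' Convert M-values back to beta values
#'
#' Inverse logit2: `beta = 2^M / (1 + 2^M)`. Exact round trip with
#' [beta_to_m()] for betas inside the clipping bounds.
#'
#' @param m An M-value tibble, matrix or vector.
#' @return Same shape as the input, on the beta scale.
#' @export
m_to_beta <- function(m) {
  transform_meth(m, function(x) 1 / (1 + 2^(-x)))
}

transform_meth <- function(x, f) {
  if (is.data.frame(x)) {
    m <- meth_matrix(x)
    meth_tibble(f(m))
  } else {
    f(x)
  }
}

#' Remove CpG sites failing the detection filter
#'
#' A site is removed iff strictly more than `fail_fraction` of its
#' measurements have detection p >= `p_threshold` (the per-measurement pass
#' rule is p < `p_threshold`).
#'
#' @param beta Beta tibble.
#' @param detp Detection-p tibble, aligned with `beta`.
#' @param p_threshold Detection p-value threshold; default 0.05.
#' @param fail_fraction Maximum tolerated failing fraction; default 0.75.
#' @return A list with the filtered `beta` tibble and a `report` list
#'   (`n_sites_in`, `n_sites_removed_detection`, `removed_cpgs`).
#' @export
detection_filter <- function(beta, detp, p_threshold = 0.05,
                             fail_fraction = 0.75) {
  b <- meth_matrix(beta)
  p <- meth_matrix(detp)
  if (!identical(dim(b), dim(p)) ||
      !identical(rownames(b), rownames(p)) ||
      !identical(colnames(b), colnames(p))) {
    abort("beta and detection-p matrices are not aligned")
  }
  fail <- rowMeans(p >= p_threshold, na.rm = TRUE)
  drop <- fail > fail_fraction
  report <- list(
    n_sites_in = nrow(b),
    n_sites_removed_detection = sum(drop),
    removed_cpgs = rownames(b)[drop]
  )
  list(beta = meth_tibble(b[!drop, , drop = FALSE]), report = report)
}

# per-sample density mode of M values on one side of zero
density_mode <- function(x, side = c("unmeth", "meth"), sample_id = "?") {
  side <- match.arg(side)
  x <- x[!is.na(x)]
  x <- if (side == "unmeth") x[x < 0] else x[x > 0]
  if (length(x) < 5L) {
    abort(sprintf("sample %s lacks a %sylated mode (too few M values %s 0)",
                  sample_id, side, if (side == "unmeth") "<" else ">"))
  }
  d <- density(x, kernel = "gaussian", bw = "nrd0", n = 512, from = -8, to = 8)
  keep <- if (side == "unmeth") d$x < 0 else d$x > 0
  d$x[keep][which.max(d$y[keep])]
}

#' Peak-correct type-II probes against type-I peaks
#'
#' Per sample, the unmethylated (M < 0) and methylated (M > 0) density modes
#' are estimated separately for type-I and type-II probes with a Gaussian
#' kernel (Silverman bandwidth, 512-point grid on \[-8, 8\]). Type-II
#' M-values are then rescaled so their peaks align with the type-I peaks:
#' `M' = M * peakI_unmeth / peakII_unmeth` for `M < 0` and
#' `M' = M * peakI_meth / peakII_meth` for `M > 0`. Type-I values are
#' untouched and `M = 0` is a fixed point.
#'
#' @param m M-value tibble.
#' @param annot CpG annotation with `probe_type`.
#' @return A list with the corrected `m` tibble and a `report` tibble of the
#'   four modes per sample before and after correction.
#' @export
peak_correct_type2 <- function(m, annot) {
  mm <- meth_matrix(m)
  annot <- validate_cpg_annotation(annot)
  type <- annot$probe_type[match(rownames(mm), annot$cpg_id)]
  if (anyNA(type)) abort("annotation does not cover all CpGs in the matrix")
  i1 <- type == "I"
  i2 <- type == "II"
  if (!any(i1) || !any(i2)) abort("both probe types must be present")
  out <- mm
  report <- vector("list", ncol(mm))
  for (j in seq_len(ncol(mm))) {
    sid <- colnames(mm)[j]
    p1u <- density_mode(mm[i1, j], "unmeth", sid)
    p1m <- density_mode(mm[i1, j], "meth", sid)
    p2u <- density_mode(mm[i2, j], "unmeth", sid)
    p2m <- density_mode(mm[i2, j], "meth", sid)
    v <- mm[i2, j]
    neg <- !is.na(v) & v < 0
    pos <- !is.na(v) & v > 0
    v[neg] <- v[neg] * (p1u / p2u)
    v[pos] <- v[pos] * (p1m / p2m)
    out[i2, j] <- v
    report[[j]] <- tibble::tibble(
      sample_id = sid,
      peak_I_unmeth = p1u, peak_I_meth = p1m,
      peak_II_unmeth = p2u, peak_II_meth = p2m,
      peak_II_unmeth_after = density_mode(v, "unmeth", sid),
      peak_II_meth_after = density_mode(v, "meth", sid)
    )
  }
  list(m = meth_tibble(out), report = dplyr::bind_rows(report))
}

#' Quantile-normalise a beta matrix
#'
#' Forces every sample onto the across-sample mean quantile distribution.
#' After normalisation each column's sorted non-missing values equal the
#' mean-quantile reference; ties within a column receive the mean of the
#' tied reference values. Columns with missing values are mapped through
#' linear interpolation of the reference at their own quantile grid.
#'
#' @param beta Beta tibble with at least 2 samples (a single sample is
#'   returned unchanged with a warning).
#' @return The normalised beta tibble.
#' @export
quantile_normalize <- function(beta) {
  b <- meth_matrix(beta)
  if (ncol(b) < 2L) {
    warn("quantile_normalize: single sample, returned unchanged")
    return(meth_tibble(b))
  }
  n <- nrow(b)
  # reference: mean across samples of each column's sorted values,
  # interpolated onto a common grid when columns have missing values
  grid <- (seq_len(n) - 1) / (n - 1)
  ref_cols <- vapply(seq_len(ncol(b)), function(j) {
    x <- sort(b[, j])  # drops NA
    if (length(x) < 2L) abort("quantile_normalize: a column has <2 values")
    if (length(x) == n) x else approx((seq_along(x) - 1) / (length(x) - 1),
                                      x, grid, rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(ref_cols)
  out <- b
  for (j in seq_len(ncol(b))) {
    obs <- which(!is.na(b[, j]))
    k <- length(obs)
    target <- if (k == n) ref else {
      approx(grid, ref, (seq_len(k) - 1) / (k - 1), rule = 2)$y
    }
    x <- b[obs, j]
    r_min <- rank(x, ties.method = "min")
    r_max <- rank(x, ties.method = "max")
    # ties receive the mean of the tied reference values
    cs <- c(0, cumsum(target))
    out[obs, j] <- (cs[r_max + 1L] - cs[r_min]) / (r_max - r_min + 1L)
  }
  meth_tibble(out)
}
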