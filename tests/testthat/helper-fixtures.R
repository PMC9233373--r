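# Shared fixtures and independent oracles, built in code at test time.

# minimal valid sample sheet: n_paired patients with both timepoints, plus
# optional pre-only / post-only patients
make_sheet <- function(n_paired = 3, n_pre_only = 0, n_post_only = 0,
                       survival_group = "survivor") {
  n <- n_paired + n_pre_only + n_post_only
  pid <- sprintf("P%02d", seq_len(n))
  status <- c(rep("paired", n_paired), rep("pre_only", n_pre_only),
              rep("post_only", n_post_only))
  rows <- list()
  for (i in seq_len(n)) {
    tps <- switch(status[i], paired = c("pre", "post"), pre_only = "pre",
                  post_only = "post")
    rows[[i]] <- tibble::tibble(
      sample_id = paste0(pid[i], "_", tps), patient_id = pid[i],
      timepoint = tps,
      survival_group = if (length(survival_group) == 1) survival_group else
        survival_group[i],
      survival_time = 10, event = 0
    )
  }
  validate_sample_sheet(dplyr::bind_rows(rows))
}

make_beta_tbl <- function(values, cpg_ids, sample_ids) {
  m <- matrix(values, nrow = length(cpg_ids),
              dimnames = list(cpg_ids, sample_ids))
  meth_tibble(m)
}

make_annot <- function(cpg_ids, gene = "GENE1", context = "promoter",
                       island = "cgi", probe_type = "II") {
  tibble::tibble(
    cpg_id = cpg_ids,
    gene = ifelse(rep_len(context, length(cpg_ids)) == "intergenic", "",
                  rep_len(gene, length(cpg_ids))),
    genomic_context = rep_len(context, length(cpg_ids)),
    island = rep_len(island, length(cpg_ids)),
    probe_type = rep_len(probe_type, length(cpg_ids))
  )
}

# cohorts are expensive; build once per session, keyed by config
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# ---- independent oracles ----------------------------------------------------

# dense-covariance GLS oracle: explicit V inversion, no whitening shortcut
oracle_gls <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- XtVi %*% X
  bh <- solve(A, XtVi %*% y)
  r <- y - X %*% bh
  n <- length(y)
  p <- ncol(X)
  list(effect = bh[p], sigma2 = as.numeric(t(r) %*% Vi %*% r) / (n - p),
       df = n - p, se_unit = sqrt(solve(A)[p, p]))
}

# block-equicorrelated covariance for a sheet (pre/post pairs)
oracle_block_V <- function(sheet, rho) {
  n <- nrow(sheet)
  V <- diag(n)
  pairs <- pairing_index(sheet)
  pairs <- pairs[pairs$paired, ]
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$pre[k], sheet$sample_id)
    j <- match(pairs$post[k], sheet$sample_id)
    V[i, j] <- rho
    V[j, i] <- rho
  }
  V
}

# brute-force log-rank: O/E table over pooled event times
oracle_logrank <- function(times, events, group) {
  g <- as.character(group)
  levs <- unique(g)
  stopifnot(length(levs) == 2)
  a <- g == levs[1]
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & a)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & a)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# direct step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
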