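# Delta-beta prognostic risk score: leave-one-out LASSO stability selection
# over the candidate CpGs, a frozen linear score
# R = sum_j w_j * (beta_post_j - beta_pre_j), and risk-group assignment
# either from the held-out LOO class predictions (discovery cohort) or a
# median score cutoff (external cohorts).

#' Per-patient methylation change at candidate CpGs
#'
#' Restricts to fully paired patients and computes
#' `delta beta = beta_post - beta_pre` per candidate CpG.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param candidate_cpgs CpG ids to use as columns.
#' @return A `delta_beta` tibble: `patient_id` plus one column per candidate
#'   CpG; unpaired patients are excluded and counted in the
#'   `n_excluded_unpaired` attribute.
#' @export
build_delta_beta <- function(beta, sheet, candidate_cpgs) {
  sheet <- validate_sample_sheet(sheet)
  b <- meth_matrix(beta)
  candidate_cpgs <- unique(as.character(candidate_cpgs))
  missing_ids <- setdiff(candidate_cpgs, rownames(b))
  if (length(missing_ids) > 0L) {
    abort(paste0("candidate CpGs absent from matrix: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  pairs <- pairing_index(sheet)
  unpaired <- sum(!pairs$paired)
  pairs <- pairs[pairs$paired, , drop = FALSE]
  if (nrow(pairs) == 0L) abort("no paired patients")
  delta <- t(b[candidate_cpgs, pairs$post, drop = FALSE] -
               b[candidate_cpgs, pairs$pre, drop = FALSE])
  out <- dplyr::bind_cols(tibble::tibble(patient_id = pairs$patient_id),
                          tibble::as_tibble(delta, .name_repair = "minimal"))
  attr(out, "n_excluded_unpaired") <- unpaired
  class(out) <- c("delta_beta", class(out))
  out
}

#' Five-year death indicator per paired patient
#'
#' @param sheet Sample sheet.
#' @param patients Patient ids (defaults to all in the sheet).
#' @return Named 0/1 vector: 1 = breast cancer death within 5 years
#'   (the `non_survivor` group).
#' @export
five_year_death <- function(sheet, patients = NULL) {
  sheet <- validate_sample_sheet(sheet)
  per_pat <- sheet |>
    dplyr::distinct(.data$patient_id, .data$survival_group)
  patients <- patients %||% per_pat$patient_id
  out <- as.numeric(
    per_pat$survival_group[match(patients, per_pat$patient_id)] ==
      "non_survivor")
  setNames(out, patients)
}

dm_as_matrix <- function(delta_beta) {
  m <- as.matrix(delta_beta[setdiff(names(delta_beta), "patient_id")])
  rownames(m) <- delta_beta$patient_id
  m
}

#' Leave-one-out LASSO stability selection
#'
#' For each held-out patient, an L1-penalised logistic regression of the
#' 5-year death indicator on the delta-beta candidates is fit on the
#' remaining patients, with lambda chosen by seeded inner 5-fold
#' cross-validated deviance; the held-out death probability is recorded.
#' The final model keeps CpGs nonzero in more than `stability_threshold` of
#' the completed LOO fits, with coefficients equal to the mean of their
#' nonzero values.
#'
#' @param delta_beta A [build_delta_beta()] result (>= 10 patients, both
#'   outcome classes).
#' @param outcome 0/1 vector (1 = death within 5 years), aligned with or
#'   named by the patients; see [five_year_death()].
#' @param stability_threshold Selection-frequency cutoff; default 0.8
#'   (strictly greater than).
#' @param lambda_rule `"1se"` (default: largest lambda within one standard
#'   error of the inner-CV deviance minimum) or `"min"` (the minimiser
#'   itself). The one-standard-error rule is the default because the plain
#'   minimiser admits spuriously stable covariates under permuted outcomes
#'   (see the methods vignette).
#' @param seed Integer seed controlling the inner fold assignments.
#' @return A list with `model` (a `risk_score_model`: selected CpGs, mean
#'   coefficients, selection frequencies, threshold, orientation note,
#'   `empty` flag) and `loo` (tibble of held-out predictions per patient).
#' @export
loo_lasso_select <- function(delta_beta, outcome, stability_threshold = 0.8,
                             lambda_rule = c("1se", "min"), seed = 1) {
  lambda_rule <- match.arg(lambda_rule)
  X <- dm_as_matrix(delta_beta)
  n <- nrow(X)
  if (n < 10L) abort("need at least 10 paired patients")
  if (!is.null(names(outcome))) outcome <- outcome[rownames(X)]
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) abort("outcome must be 0/1 per patient")
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")

  nonzero_count <- setNames(numeric(ncol(X)), colnames(X))
  coef_sum <- setNames(numeric(ncol(X)), colnames(X))
  prob <- lp <- train_median <- rep(NA_real_, n)
  n_done <- 0L
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    set.seed(derive_seed(seed, i))
    foldid <- sample(rep(seq_len(5L), length.out = n - 1L))
    cvfit <- glmnet::cv.glmnet(X[-i, , drop = FALSE], ytr,
                               family = "binomial", foldid = foldid)
    s <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    co <- as.numeric(coef(cvfit, s = s))[-1L]
    nz <- co != 0
    nonzero_count[nz] <- nonzero_count[nz] + 1
    coef_sum[nz] <- coef_sum[nz] + co[nz]
    lp_all <- as.numeric(predict(cvfit, X, s = s, type = "link"))
    prob[i] <- 1 / (1 + exp(-lp_all[i]))
    lp[i] <- lp_all[i]
    train_median[i] <- median(lp_all[-i])
    n_done <- n_done + 1L
  }
  if (n_done == 0L) abort("no leave-one-out fit could be completed")
  freq <- nonzero_count / n_done
  selected <- freq > stability_threshold & nonzero_count > 0
  coefs <- ifelse(nonzero_count > 0, coef_sum / nonzero_count, 0)
  model <- structure(
    list(
      cpgs = tibble::tibble(
        cpg_id = colnames(X)[selected],
        coefficient = unname(coefs[selected]),
        selection_frequency = unname(freq[selected])
      ),
      selection_frequency = tibble::tibble(
        cpg_id = colnames(X), frequency = unname(freq)),
      stability_threshold = stability_threshold,
      orientation = "delta_beta = post - pre",
      outcome_note = "outcome 1 = breast cancer death within 5 years",
      lambda_rule = lambda_rule,
      empty = !any(selected),
      n_loo_completed = n_done,
      n_loo_skipped = n_skipped
    ),
    class = "risk_score_model"
  )
  loo <- tibble::tibble(patient_id = rownames(X), outcome = y,
                        prob_death = prob, linear_predictor = lp,
                        train_median_lp = train_median)
  list(model = model, loo = loo)
}

#' @export
print.risk_score_model <- function(x, ...) {
  if (x$empty) {
    cat("Empty risk score model (no CpG passed stability selection);",
        "score is identically 0.\n")
  } else {
    cat(sprintf(
      "Risk score model: %d CpGs (selection frequency > %.2f over %d LOO fits)\n",
      nrow(x$cpgs), x$stability_threshold, x$n_loo_completed))
    print(x$cpgs)
  }
  invisible(x)
}

#' @method tidy risk_score_model
#' @export
tidy.risk_score_model <- function(x, ...) x$cpgs

#' @method glance risk_score_model
#' @export
glance.risk_score_model <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$cpgs),
    stability_threshold = x$stability_threshold,
    n_loo_completed = x$n_loo_completed,
    n_loo_skipped = x$n_loo_skipped,
    empty = x$empty
  )
}

#' Apply a frozen risk score to a delta-beta matrix
#'
#' `R_i = sum_j w_j * delta_beta_ij` over the model CpGs; an empty model
#' scores every patient 0.
#'
#' @param model A `risk_score_model`.
#' @param delta_beta A [build_delta_beta()] result containing every model
#'   CpG.
#' @return A tibble with `patient_id`, `risk_score`.
#' @export
apply_risk_score <- function(model, delta_beta) {
  X <- dm_as_matrix(delta_beta)
  if (model$empty) {
    return(tibble::tibble(patient_id = rownames(X), risk_score = 0))
  }
  missing_ids <- setdiff(model$cpgs$cpg_id, colnames(X))
  if (length(missing_ids) > 0L) {
    abort(paste0("model CpG missing from cohort: ",
                 paste(missing_ids, collapse = ", ")))
  }
  r <- as.numeric(X[, model$cpgs$cpg_id, drop = FALSE] %*%
                    model$cpgs$coefficient)
  tibble::tibble(patient_id = rownames(X), risk_score = r)
}

#' Risk groups from the held-out LOO predictions
#'
#' Two thresholding rules for the held-out prediction: `"probability"`
#' (default) calls a patient high risk iff the held-out death probability
#' is >= 0.5 (ties high); `"train_median"` calls high risk iff the held-out
#' linear predictor exceeds the median linear predictor of that fit's
#' training patients.
#'
#' @param loo The `loo` tibble from [loo_lasso_select()].
#' @param rule `"train_median"` or `"probability"`.
#' @return A tibble with `patient_id`, `group` (high/low), `provenance`.
#' @export
assign_groups_loo <- function(loo, rule = c("probability", "train_median")) {
  rule <- match.arg(rule)
  if (anyNA(loo$prob_death)) {
    abort(paste0("missing LOO prediction for patient ",
                 loo$patient_id[which(is.na(loo$prob_death))[1]]))
  }
  high <- if (rule == "probability") {
    loo$prob_death >= 0.5
  } else {
    loo$linear_predictor > loo$train_median_lp
  }
  tibble::tibble(
    patient_id = loo$patient_id,
    group = ifelse(high, "high", "low"),
    provenance = "loo_predicted"
  )
}

#' Risk groups by median score cutoff
#'
#' High risk iff the score exceeds the median; scores at the median go to
#' the low-risk group.
#'
#' @param scores Tibble with `patient_id`, `risk_score` (>= 2 patients).
#' @return A tibble with `patient_id`, `group`, `provenance`.
#' @export
assign_groups_median <- function(scores) {
  if (nrow(scores) < 2L) abort("need at least 2 patients")
  if (max(scores$risk_score) == min(scores$risk_score)) {
    abort("cutoff degenerate: all risk scores identical")
  }
  med <- median(scores$risk_score)
  tibble::tibble(
    patient_id = scores$patient_id,
    group = ifelse(scores$risk_score > med, "high", "low"),
    provenance = "median_cutoff"
  )
}

#' Serialise a risk score model to JSON
#'
#' @param model A `risk_score_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(
    list(
      cpgs = model$cpgs,
      stability_threshold = model$stability_threshold,
      orientation = model$orientation,
      outcome_note = model$outcome_note,
      lambda_rule = model$lambda_rule,
      empty = model$empty,
      n_loo_completed = model$n_loo_completed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a serialised risk score model
#'
#' @param path Path to a JSON file from [write_risk_model()].
#' @return A `risk_score_model`.
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpgs <- tibble::as_tibble(x$cpgs)
  if (nrow(cpgs) == 0L) {
    cpgs <- tibble::tibble(cpg_id = character(), coefficient = double(),
                           selection_frequency = double())
  } else {
    cpgs$coefficient <- as.double(cpgs$coefficient)
    cpgs$selection_frequency <- as.double(cpgs$selection_frequency)
  }
  x$cpgs <- cpgs
  x$selection_frequency <- NULL
  structure(x, class = "risk_score_model")
}
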