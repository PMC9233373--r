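# Product-limit survival curves, median survival and the log-rank test used
# to evaluate the methylation risk groups. The estimators are delegated to
# the survival package; this layer fixes the conventions (median = smallest
# time with S(t) <= 0.5; chi-square log-rank with 1 df) and the tabular
# interface.

#' Kaplan-Meier product-limit fit
#'
#' @param times Follow-up times (years, >= 0).
#' @param events Event indicators (1 = death, 0 = censored).
#' @return A `km_fit` object: tibble with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, plus `median` (smallest time with `S(t) <= 0.5`,
#'   NA when the curve never reaches 0.5) and `n` attributes.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) abort("empty survival input")
  if (any(times < 0)) abort("times must be >= 0")
  if (!all(events %in% c(0, 1))) abort("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  tab <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  med <- tab$time[tab$surv <= 0.5 + 1e-12]
  structure(tab,
            class = c("km_fit", class(tab)),
            median = if (length(med) > 0) min(med) else NA_real_,
            n = length(times), n_events = sum(events))
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "km_fit")
  out
}

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_events = attr(x, "n_events"),
    median_survival = attr(x, "median")
  )
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation of the product-limit estimate;
#' times beyond the last observed time return the last value with an
#' extrapolation flag.
#'
#' @param fit A `km_fit`.
#' @param t Time (>= 0).
#' @return A list with `surv` and `extrapolated`.
#' @export
survival_at <- function(fit, t) {
  assert_scalar_number(t, "t", lower = 0)
  steps <- tibble::as_tibble(fit)
  before <- steps$time <= t
  list(
    surv = if (any(before)) steps$surv[max(which(before))] else 1,
    extrapolated = t > max(steps$time)
  )
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic (1 df) over the
#' pooled event times with hypergeometric variance. With no events in
#' either group the statistic is 0 and p = 1.
#'
#' @param times,events Pooled follow-up times and event indicators.
#' @param group Two-level group labels aligned with `times`.
#' @return A list with `statistic` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.character(group)
  if (length(unique(group)) != 2L) abort("exactly two groups required")
  if (sum(events) == 0) return(list(statistic = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  stat <- sd$chisq
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier curves for the methylation risk groups
#'
#' Convenience wrapper: joins risk-group assignments with per-patient
#' survival, fits one curve per group and tests their separation by
#' log-rank.
#'
#' @param groups Tibble with `patient_id`, `group` (e.g. from
#'   [assign_groups_loo()] or [assign_groups_median()]).
#' @param sheet Sample sheet holding `survival_time` and `event` per
#'   patient.
#' @return A `risk_survival` list: per-group `fits` (named list of
#'   `km_fit`), the `logrank` result and the joined `data`.
#' @export
risk_group_survival <- function(groups, sheet) {
  sheet <- validate_sample_sheet(sheet)
  per_pat <- sheet |>
    dplyr::distinct(.data$patient_id, .data$survival_time, .data$event)
  data <- groups |>
    dplyr::inner_join(per_pat, by = "patient_id")
  if (nrow(data) < nrow(groups)) abort("patients missing from sample sheet")
  fits <- lapply(split(data, data$group), function(d) {
    km_fit(d$survival_time, d$event)
  })
  lr <- if (length(fits) == 2L) {
    logrank_test(data$survival_time, data$event, data$group)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  structure(list(fits = fits, logrank = lr, data = data),
            class = "risk_survival")
}

#' @export
print.risk_survival <- function(x, ...) {
  for (g in names(x$fits)) {
    gl <- glance(x$fits[[g]])
    cat(sprintf("%s risk: n = %d, events = %d, median survival = %s\n",
                g, gl$n, gl$n_events,
                ifelse(is.na(gl$median_survival), "not reached",
                       paste(format(gl$median_survival, digits = 4),
                             "years"))))
  }
  if (!is.na(x$logrank$p)) {
    cat(sprintf("log-rank chi-square = %.4g, p = %.4g\n",
                x$logrank$statistic, x$logrank$p))
  }
  invisible(x)
}

#' Step plot of the risk-group survival curves
#'
#' @param object A `risk_survival` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot risk_survival
#' @export
autoplot.risk_survival <- function(object, ...) {
  df <- dplyr::bind_rows(
    lapply(names(object$fits), function(g) {
      tidy(object$fits[[g]]) |>
        dplyr::mutate(group = g) |>
        dplyr::bind_rows(tibble::tibble(time = 0, surv = 1, group = g)) |>
        dplyr::arrange(.data$time)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "S(t)", colour = "risk group") +
    ggplot2::theme_minimal()
}
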