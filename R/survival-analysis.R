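#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator over the distinct observed times. With
#' censored-only input the curve stays flat at 1.
#'
#' @param time non-negative follow-up times (months).
#' @param event event indicator (1/TRUE = event observed, 0/FALSE =
#'   censored).
#' @return a tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; the total numbers of
#'   subjects and events are in attributes `n` and `n_events`.
#' @export
#' @examples
#' km_estimate(c(1, 2), c(1, 1))  # S = 0.5 on [1, 2), 0 afterwards
km_estimate <- function(time, event) {
  if (length(time) == 0) {
    abort("no subjects", class = "tmascore_domain_error")
  }
  if (anyNA(time) || any(time < 0)) {
    abort("times must be non-negative and non-missing",
          class = "tmascore_domain_error")
  }
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  attr(out, "n") <- length(time)
  attr(out, "n_events") <- sum(event)
  out
}

#' k-sample log-rank test
#'
#' Compares event-time distributions across two or more groups; tied event
#' times are handled by pooling the ties at each distinct time.
#'
#' @param time,event follow-up and event indicator as in [km_estimate()].
#' @param group group labels (two or more non-empty groups).
#' @return a one-row tibble: `statistic`, `df`, `p_value`, `n`, `method`.
#' @export
log_rank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) {
    abort("log-rank needs at least 2 non-empty groups",
          class = "tmascore_degenerate")
  }
  if (anyNA(group)) {
    abort("missing group labels", class = "tmascore_domain_error")
  }
  event <- as.integer(event)
  if (sum(event) == 0) {
    abort("no events observed; log-rank undefined",
          class = "tmascore_degenerate")
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- nlevels(group) - 1L
  tibble::tibble(
    statistic = unname(fit$chisq),
    df = df,
    p_value = pchisq(unname(fit$chisq), df, lower.tail = FALSE),
    n = length(time),
    method = "log-rank"
  )
}

#' Covariate-adjusted proportional-hazards fit
#'
#' Cox partial-likelihood fit with Efron handling of ties. The staining
#' category enters as a numeric ordinal score 0-3 by default (one
#' coefficient for the per-level log hazard-ratio increment); with
#' `category_coding = "factor"` each level above negative gets its own
#' coefficient.
#'
#' @param data a data frame with `time_months`, `event`, and the covariate
#'   columns (typically a scored cohort with simulated or recorded
#'   follow-up).
#' @param covariates character vector of covariate column names, e.g.
#'   `c("category", "pT", "pN")`.
#' @param category_coding `"numeric"` (default) or `"factor"`, how a
#'   `category` covariate is coded.
#' @return a tibble with one row per coefficient: `term`, `estimate`
#'   (log hazard ratio), `hr`, `se`, `z`, `p_value`; the fitted
#'   `survival::coxph` object is kept in attribute `fit`.
#' @export
cox_fit <- function(data, covariates,
                    category_coding = c("numeric", "factor")) {
  category_coding <- match.arg(category_coding)
  missing_cov <- setdiff(c("time_months", "event", covariates), names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("missing columns: ", paste(missing_cov, collapse = ", ")),
          class = "tmascore_schema_error")
  }
  df <- as.data.frame(data[, c("time_months", "event", covariates)])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0 || sum(df$event) == 0) {
    abort("no events among complete cases; cannot fit hazards model",
          class = "tmascore_degenerate")
  }
  if ("category" %in% covariates && category_coding == "numeric") {
    df$category <- as.integer(factor(as.character(df$category),
                                     levels = STAIN_LEVELS)) - 1L
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  coefs <- summary(fit)$coefficients
  if (any(abs(coefs[, "coef"]) > 10)) {
    warn(paste0(
      "possible monotone likelihood (separation); flagged coefficient(s): ",
      paste(rownames(coefs)[abs(coefs[, "coef"]) > 10], collapse = ", ")))
  }
  out <- tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, "coef"],
    hr = coefs[, "exp(coef)"],
    se = coefs[, "se(coef)"],
    z = coefs[, "z"],
    p_value = coefs[, "Pr(>|z|)"]
  )
  attr(out, "fit") <- fit
  out
}
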