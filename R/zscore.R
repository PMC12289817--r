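#' Expression z-scores relative to a normal reference
#'
#' For each tumor sample, `z = (x - mean(normal)) / sd(normal)` with the
#' sample (n-1) standard deviation of the normal reference. Inputs are
#' assumed already log-scaled (e.g. log RSEM); no transformation is applied.
#'
#' @param tumor numeric vector of tumor expression values.
#' @param normal numeric vector of reference (normal-tissue) values; at
#'   least two values with nonzero spread.
#' @return numeric vector of z-scores, one per tumor sample.
#' @export
#' @examples
#' zscore_vs_normal(12.5, c(9, 10, 11))
zscore_vs_normal <- function(tumor, normal) {
  if (length(normal) < 2) {
    abort("need at least 2 reference samples",
          class = "tmascore_domain_error")
  }
  if (anyNA(tumor) || anyNA(normal) || any(!is.finite(c(tumor, normal)))) {
    abort("expression values must be finite", class = "tmascore_domain_error")
  }
  s <- sd(normal)
  if (s == 0) {
    abort("reference has zero variance; z-scores undefined",
          class = "tmascore_degenerate")
  }
  (tumor - mean(normal)) / s
}

#' Dichotomize z-scores into expression-high and -low groups
#'
#' A sample is "high" when its z-score strictly exceeds the threshold
#' (boundary values go to "low"). One-sided by default — the high group is
#' the overexpressing tail; set `two_sided = TRUE` to call `|z| >
#' threshold` high.
#'
#' @param z numeric vector of z-scores.
#' @param threshold positive threshold, default 2.0.
#' @param two_sided if `TRUE`, use the absolute z-score.
#' @return factor with levels `low`, `high`.
#' @export
#' @examples
#' dichotomize_z(c(1.9, 2.0, 2.5))  # low, low, high
dichotomize_z <- function(z, threshold = 2.0, two_sided = FALSE) {
  if (threshold <= 0) {
    abort("threshold must be positive", class = "tmascore_domain_error")
  }
  val <- if (two_sided) abs(z) else z
  factor(ifelse(val > threshold, "high", "low"), levels = c("low", "high"))
}

#' Survival comparison between expression groups
#'
#' Log-rank comparison of survival between the dichotomized expression
#' groups; delegates to [log_rank()].
#'
#' @param groups group labels (e.g. from [dichotomize_z()]).
#' @param time,event follow-up and event indicator.
#' @return a one-row tibble as returned by [log_rank()].
#' @export
compare_groups_survival <- function(groups, time, event) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) {
    abort("need both expression groups non-empty",
          class = "tmascore_degenerate")
  }
  log_rank(time, event, groups)
}
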