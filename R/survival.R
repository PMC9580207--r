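#' Kaplan-Meier curves and log-rank test for a median-split feature
#'
#' Samples are split at the feature's median expression (values at or below
#' the median form the low group), Kaplan-Meier product-limit curves are
#' estimated per group, and the two-group log-rank test compares them.
#'
#' @param cohort A log2-scale [expression_cohort()] with survival records.
#' @param feature_id Feature to split on.
#' @param cutoff Either `"median"` or a numeric expression cutoff.
#' @return A list of class `km_result`: `group` (factor low/high per
#'   sample), `fit` (a [survival::survfit] object for the two groups),
#'   `chisq` (log-rank statistic), `p_value`.
#' @export
km_logrank <- function(cohort, feature_id, cutoff = "median") {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(cohort$survival))
    stop_mirmark("cohort has no survival records", class = "cohort_error")
  if (!feature_id %in% cohort$feature_ids)
    stop_mirmark("unknown feature: ", feature_id, class = "cohort_error")
  if (sum(cohort$survival$event) < 1)
    stop_mirmark("no events in the cohort", class = "cox_error")
  v <- cohort$values[, feature_id]
  cut <- if (identical(cutoff, "median")) median(v) else as.numeric(cutoff)
  group <- factor(ifelse(v <= cut, "low", "high"), levels = c("low", "high"))
  if (any(tabulate(group, 2) == 0))
    stop_mirmark("degenerate split: one expression group is empty",
                 class = "degenerate_split_error")
  dat <- data.frame(time = cohort$survival$time,
                    event = cohort$survival$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  structure(list(group = group, fit = fit, chisq = unname(sd_$chisq),
                 p_value = p, cutoff = cut, feature_id = feature_id),
            class = "km_result")
}

#' @method print km_result
#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %s split at %.3f: log-rank chisq = %.3f, p = %.4g\n",
              x$feature_id, x$cutoff, x$chisq, x$p_value))
  invisible(x)
}

#' Survival probabilities of a KM result at given times
#'
#' Step-function lookup of each group's product-limit estimate; probability
#' is 1 before the first event and non-increasing in time.
#'
#' @param km A [km_logrank()] result.
#' @param times Numeric vector of evaluation times.
#' @return A matrix (length(times) x 2) of survival probabilities, columns
#'   `low` and `high`.
#' @export
km_survival_at <- function(km, times) {
  sm <- summary(km$fit, times = times, extend = TRUE)
  grp <- sub("^group=", "", as.character(sm$strata))
  out <- matrix(NA_real_, length(times), 2,
                dimnames = list(NULL, c("low", "high")))
  for (g in c("low", "high"))
    out[, g] <- sm$surv[grp == g]
  out
}

#' Two-group expression difference test
#'
#' Compares a feature's expression between two subtypes with a two-sided
#' Wilcoxon rank-sum test (default) or Welch t-test.
#'
#' @param cohort An [expression_cohort()].
#' @param feature_id Feature to test.
#' @param subtype_a,subtype_b Subtype labels to compare.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return A list with `statistic` and `p_value`.
#' @export
expression_diff_test <- function(cohort, feature_id, subtype_a, subtype_b,
                                 method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!feature_id %in% cohort$feature_ids)
    stop_mirmark("unknown feature: ", feature_id, class = "cohort_error")
  va <- cohort$values[cohort$labels == subtype_a, feature_id]
  vb <- cohort$values[cohort$labels == subtype_b, feature_id]
  if (!length(va) || !length(vb))
    stop_mirmark("empty subtype group", class = "cohort_error")
  ht <- if (method == "wilcoxon")
    suppressWarnings(wilcox.test(va, vb, alternative = "two.sided")) else
      t.test(va, vb, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
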