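#' Multivariate Cox proportional-hazards fit on a feature panel
#'
#' Fits one Cox model jointly over all panel features (hazard
#' `h0(t) * exp(beta_1 x_1 + ... + beta_p x_p)`), with Efron handling of
#' tied event times. Covariates enter on their stored (log2) scale, so the
#' coefficient-magnitude threshold downstream applies to raw log-hazard
#' ratios per log2 expression unit.
#'
#' @param cohort A log2-scale [expression_cohort()] with survival records.
#' @param features A `feature_panel` or character vector of feature IDs.
#' @param ridge Optional non-negative ridge penalty for stabilizing
#'   ill-conditioned fits (0 = plain partial likelihood, the default).
#' @return A data frame of class `cox_report` with one row per feature:
#'   `feature_id`, `beta`, `hazard_ratio`, `p_value`.
#' @export
fit_cox <- function(cohort, features, ridge = 0) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(cohort$survival))
    stop_mirmark("cohort has no survival records", class = "cohort_error")
  if (sum(cohort$survival$event) < 1)
    stop_mirmark("no events in the cohort (all samples censored)",
                 class = "cox_error")
  ids <- if (inherits(features, "feature_panel")) features$selected else
    as.character(features)
  if (length(ids) == 0)
    stop_mirmark("empty feature panel", class = "empty_panel_error")
  missing <- setdiff(ids, cohort$feature_ids)
  if (length(missing))
    stop_mirmark("features absent from cohort: ",
                 paste(missing, collapse = ", "), class = "cohort_error")
  X <- cohort$values[, ids, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_mirmark("zero-variance covariate(s): ",
                 paste(ids[sds == 0], collapse = ", "), class = "cox_error")
  dat <- data.frame(time = cohort$survival$time,
                    event = cohort$survival$event, X, check.names = FALSE)
  covs <- paste0("`", ids, "`")
  if (ridge > 0)
    covs <- sprintf("ridge(%s, theta = %g, scale = TRUE)",
                    paste(covs, collapse = ", "), ridge)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covs, collapse = " + ")))
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = dat, ties = "efron"),
             error = function(e)
               stop_mirmark("Cox fit failed (", conditionMessage(e),
                            "); consider the ridge stabilization argument",
                            class = "cox_error")),
    warning = function(w) {
      if (grepl("did not converge|may be infinite", conditionMessage(w)))
        stop_mirmark("Cox fit unstable (", conditionMessage(w),
                     "); consider the ridge stabilization argument",
                     class = "cox_error")
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))[seq_along(ids)]
  se <- sqrt(diag(fit$var))[seq_along(ids)]
  p <- 2 * stats::pnorm(-abs(beta / se))  # Wald
  structure(data.frame(feature_id = ids, beta = beta,
                       hazard_ratio = hazard_ratio(beta), p_value = p,
                       row.names = NULL),
            class = c("cox_report", "data.frame"))
}

#' Hazard ratio of a Cox coefficient
#'
#' `exp(beta)`: the multiplicative change in instantaneous death risk per
#' unit increase of the covariate. Values above 1 increase risk; below 1
#' reduce it.
#'
#' @param beta Cox regression coefficient(s).
#' @return `exp(beta)`, vectorized.
#' @export
hazard_ratio <- function(beta) {
  if (any(!is.finite(beta)))
    stop_mirmark("beta must be finite", class = "cox_error")
  exp(beta)
}

#' Flag biomarkers by coefficient magnitude and significance
#'
#' A feature is flagged when `|beta| > coef_thresh` and
#' `p_value < p_thresh` (both strict). Rows are returned sorted by
#' decreasing `|beta|`.
#'
#' @param report A [fit_cox()] report (or any data frame with `beta` and
#'   `p_value` columns).
#' @param coef_thresh Minimum absolute Cox coefficient (default 0.2).
#' @param p_thresh Maximum Wald p-value (default 0.05).
#' @return The report with an added logical `is_biomarker` column and
#'   attributes `coef_thresh` / `p_thresh`, sorted by `|beta|` descending.
#' @export
filter_biomarkers <- function(report, coef_thresh = 0.2, p_thresh = 0.05) {
  stopifnot(all(c("beta", "p_value") %in% names(report)))
  report$is_biomarker <- abs(report$beta) > coef_thresh &
    report$p_value < p_thresh
  report <- report[order(-abs(report$beta)), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "coef_thresh") <- coef_thresh
  attr(report, "p_thresh") <- p_thresh
  report
}

#' Reference biomarker table (published TCGA breast-cancer miRNA panel)
#'
#' A 22-row table of multivariate Cox summaries (coefficient, hazard ratio,
#' Wald p-value) reported for miRNA biomarkers in a TCGA breast invasive
#' carcinoma cohort. Shipped as a plain-text fixture for validating the
#' hazard-ratio arithmetic and the biomarker filter against published
#' numbers.
#'
#' @return Data frame with columns `feature_id`, `beta`, `hazard_ratio`,
#'   `p_value`.
#' @export
reference_biomarker_table <- function() {
  read.delim(system.file("extdata", "tcga_brca_mirna_cox.tsv",
                         package = "mirmark"))
}
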