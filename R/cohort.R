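#' Subtype levels used throughout the package
#'
#' The five-class coding of breast-cancer intrinsic subtypes used by the
#' pipeline: Luminal A, Luminal B, HER2-enriched, Basal-like, and a control
#' class of normal samples. Integer class codes 1..5 follow this order.
#'
#' @return Character vector of the five subtype labels, in class-code order.
#' @export
subtype_levels <- function() c("LA", "LB", "H2", "BL", "control")

#' Construct an expression cohort
#'
#' Bundles a samples-by-features expression matrix with per-sample subtype
#' labels and right-censored survival records. This is the container every
#' pipeline stage consumes.
#'
#' @param values Numeric n x p matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers (length n).
#' @param feature_ids Character vector of unique feature identifiers (length p).
#' @param labels Per-sample subtype, either a factor/character with levels
#'   among [subtype_levels()] or integer codes 1..5.
#' @param survival Data frame with columns `time` (non-negative) and `event`
#'   (0 = censored, 1 = death), one row per sample, aligned to `sample_ids`.
#' @param scale Either `"log2"` (already log2-transformed, analysis-ready) or
#'   `"raw"` (non-negative raw expression, must pass through [preprocess()]
#'   before modelling).
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `labels` (factor), `survival`,
#'   and `scale`.
#' @export
expression_cohort <- function(values, sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              labels, survival = NULL,
                              scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != n)
    stop_mirmark("sample_ids length (", length(sample_ids),
                 ") does not match rows (", n, ")", class = "cohort_error")
  if (length(feature_ids) != p)
    stop_mirmark("feature_ids length (", length(feature_ids),
                 ") does not match columns (", p, ")", class = "cohort_error")
  if (anyDuplicated(sample_ids))
    stop_mirmark("duplicate sample IDs", class = "cohort_error")
  if (anyDuplicated(feature_ids))
    stop_mirmark("duplicate feature IDs", class = "cohort_error")
  if (scale == "log2" && anyNA(values))
    stop_mirmark("log2-scale cohort contains missing values; preprocess raw data first",
                 class = "cohort_error")
  labels <- coerce_labels(labels, n)
  if (!is.null(survival)) {
    survival <- as.data.frame(survival)
    if (!all(c("time", "event") %in% names(survival)))
      stop_mirmark("survival must have columns time and event", class = "cohort_error")
    if (nrow(survival) != n)
      stop_mirmark("survival rows (", nrow(survival),
                   ") do not match samples (", n, ")", class = "cohort_error")
    if (any(!is.finite(survival$time)) || any(survival$time < 0))
      stop_mirmark("survival time must be finite and non-negative",
                   class = "cohort_error")
    if (!all(survival$event %in% c(0, 1)))
      stop_mirmark("survival event must be 0 (censored) or 1 (death)",
                   class = "cohort_error")
    survival <- data.frame(time = as.double(survival$time),
                           event = as.integer(survival$event))
  }
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, labels = labels,
                 survival = survival, scale = scale),
            class = "expression_cohort")
}

coerce_labels <- function(labels, n) {
  lv <- subtype_levels()
  if (is.numeric(labels)) {
    if (!all(labels %in% seq_along(lv)))
      stop_mirmark("integer subtype codes must be in 1..", length(lv),
                   class = "cohort_error")
    labels <- lv[labels]
  }
  labels <- as.character(labels)
  if (length(labels) != n)
    stop_mirmark("labels length (", length(labels),
                 ") does not match samples (", n, ")", class = "cohort_error")
  bad <- setdiff(unique(labels), lv)
  if (length(bad))
    stop_mirmark("unknown subtype label(s): ", paste(bad, collapse = ", "),
                 class = "cohort_error")
  factor(labels, levels = lv)
}

#' @method print expression_cohort
#' @export
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", nrow(x$values), " samples x ",
      ncol(x$values), " features (", x$scale, " scale)\n", sep = "")
  cat("  subtypes:", paste(sprintf("%s=%d", levels(x$labels),
                                   tabulate(x$labels, 5)), collapse = " "), "\n")
  if (!is.null(x$survival))
    cat(sprintf("  survival: %d events, %.1f%% censored\n",
                sum(x$survival$event), 100 * mean(x$survival$event == 0)))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Subset a cohort by samples and/or features
#'
#' @param cohort An [expression_cohort()].
#' @param samples Sample index/logical/ID vector (default all).
#' @param features Feature index/logical/ID vector (default all).
#' @return A new `expression_cohort` restricted to the requested rows/columns.
#' @export
cohort_subset <- function(cohort, samples = NULL, features = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  si <- if (is.null(samples)) seq_along(cohort$sample_ids) else samples
  if (is.character(si)) si <- match(si, cohort$sample_ids)
  fi <- if (is.null(features)) seq_along(cohort$feature_ids) else features
  if (is.character(fi)) fi <- match(fi, cohort$feature_ids)
  if (anyNA(si)) stop_mirmark("unknown sample ID in subset", class = "cohort_error")
  if (anyNA(fi)) stop_mirmark("unknown feature ID in subset", class = "cohort_error")
  expression_cohort(cohort$values[si, fi, drop = FALSE],
                    cohort$sample_ids[si], cohort$feature_ids[fi],
                    labels = as.character(cohort$labels)[si],
                    survival = if (!is.null(cohort$survival))
                      cohort$survival[si, , drop = FALSE],
                    scale = cohort$scale)
}
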