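#' Write a cohort to the three standard pipeline TSV files
#'
#' Emits `expression.tsv` (first column `sample_id`, then one column per
#' feature), `labels.tsv` (`sample_id`, `subtype`) and `clinical.tsv`
#' (`sample_id`, `time`, `event`) into `dir`.
#'
#' @param cohort An [expression_cohort()] with survival records.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- data.frame(sample_id = cohort$sample_ids,
                     cohort$values, check.names = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  write_tsv(expr, paths[["expression"]])
  write_tsv(data.frame(sample_id = cohort$sample_ids,
                       subtype = as.character(cohort$labels)),
            paths[["labels"]])
  if (!is.null(cohort$survival))
    write_tsv(data.frame(sample_id = cohort$sample_ids, cohort$survival),
              paths[["clinical"]])
  invisible(paths)
}

#' Load a cohort from expression, label, and clinical TSV files
#'
#' Row order follows the expression file; label and clinical rows are matched
#' by `sample_id` and must cover every expression sample.
#'
#' @param expression_path TSV with a `sample_id` first column and one numeric
#'   column per feature.
#' @param labels_path TSV with columns `sample_id` and `subtype`.
#' @param clinical_path Optional TSV with columns `sample_id`, `time`, `event`.
#' @param scale Scale of the stored values; see [expression_cohort()].
#' @return An [expression_cohort()].
#' @export
load_cohort <- function(expression_path, labels_path, clinical_path = NULL,
                        scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  for (p in c(expression_path, labels_path, clinical_path))
    if (!file.exists(p)) stop_mirmark("file not found: ", p, class = "io_error")
  expr <- read.delim(expression_path, check.names = FALSE,
                     colClasses = c(sample_id = "character"))
  if (names(expr)[1] != "sample_id")
    stop_mirmark("expression file must start with a sample_id column",
                 class = "io_error")
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(expr[-1], is.numeric, logical(1)))[1]
    stop_mirmark("non-numeric expression column: ", names(expr)[-1][bad],
                 class = "io_error")
  }
  ids <- expr$sample_id

  lab <- read.delim(labels_path, colClasses = "character")
  missing_lab <- setdiff(ids, lab$sample_id)
  if (length(missing_lab))
    stop_mirmark("samples missing from labels file: ",
                 paste(missing_lab, collapse = ", "), class = "alignment_error")
  labels <- lab$subtype[match(ids, lab$sample_id)]

  survival <- NULL
  if (!is.null(clinical_path)) {
    cl <- read.delim(clinical_path, colClasses = c(sample_id = "character"))
    missing_cl <- setdiff(ids, cl$sample_id)
    if (length(missing_cl))
      stop_mirmark("samples missing from clinical file: ",
                   paste(missing_cl, collapse = ", "),
                   class = "alignment_error")
    cl <- cl[match(ids, cl$sample_id), ]
    survival <- data.frame(time = cl$time, event = cl$event)
  }
  expression_cohort(mat, ids, colnames(mat), labels, survival, scale = scale)
}

#' Filter low-expression features and log2-transform a raw cohort
#'
#' Features whose fraction of non-expressed entries (value <= 0 or missing)
#' exceeds `max_nonexpressed_frac` are removed (strict inequality), then the
#' remaining values are transformed to `log2(x + 1)`. Missing entries among
#' retained features are treated as zero expression before the transform.
#'
#' @param raw An [expression_cohort()] with `scale = "raw"`.
#' @param max_nonexpressed_frac Maximum tolerated fraction of non-expressed
#'   entries per feature; default 0.01 (features with *more than* 1%
#'   non-expressed samples are dropped).
#' @return A log2-scale `expression_cohort`; the IDs of removed features are
#'   attached as attribute `"removed_features"`.
#' @export
preprocess <- function(raw, max_nonexpressed_frac = 0.01) {
  stopifnot(inherits(raw, "expression_cohort"))
  if (raw$scale != "raw")
    stop_mirmark("preprocess() expects a raw-scale cohort; this one is already ",
                 raw$scale, class = "scale_error")
  v <- raw$values
  if (any(v < 0, na.rm = TRUE))
    stop_mirmark("raw expression must be non-negative", class = "io_error")
  nonexpr_frac <- colMeans(is.na(v) | v <= 0)
  drop <- nonexpr_frac > max_nonexpressed_frac
  if (all(drop))
    stop_mirmark("all features removed by the non-expression filter",
                 class = "empty_panel_error")
  keep <- v[, !drop, drop = FALSE]
  keep[is.na(keep)] <- 0
  out <- expression_cohort(log2(keep + 1), raw$sample_ids,
                           raw$feature_ids[!drop],
                           labels = as.character(raw$labels),
                           survival = raw$survival, scale = "log2")
  attr(out, "removed_features") <- raw$feature_ids[drop]
  out
}
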