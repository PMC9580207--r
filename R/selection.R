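#' Count nonzero-coefficient frequencies across an ensemble
#'
#' `counts[k, j]` is the number of ensemble models in which feature `k` has
#' a nonzero coefficient for class `j` (absolute value strictly above
#' `zero_tol`; the coordinate-descent solver emits exact zeros, so the
#' default tolerance is 0).
#'
#' @param ensemble An `ensemble_result`.
#' @param zero_tol Magnitude below or at which a coefficient counts as zero.
#' @return A list of class `frequency_table` with `counts` (p x 5 integer
#'   matrix, feature IDs as row names) and `M`.
#' @export
count_frequencies <- function(ensemble, zero_tol = 0) {
  if (length(ensemble$models) == 0)
    stop_mirmark("empty ensemble", class = "fit_error")
  W1 <- ensemble$models[[1]]$coefficients
  counts <- matrix(0L, nrow(W1), ncol(W1), dimnames = dimnames(W1))
  for (model in ensemble$models)
    counts <- counts + (abs(model$coefficients) > zero_tol)
  structure(list(counts = counts, M = length(ensemble$models)),
            class = "frequency_table")
}

#' Per-subtype feature sets by frequency threshold
#'
#' `D_j = { features with counts[k, j] >= threshold }` (or strictly `>` when
#' `comparator = ">"`). With an ensemble of 100 models the screening default
#' keeps features selected in at least half of them.
#'
#' @param freq A [count_frequencies()] result.
#' @param threshold Minimum selection count, in `0..M`.
#' @param comparator `">="` (default) or `">"`.
#' @return Named list of per-subtype feature-ID sets `D_1..D_K`.
#' @export
select_per_subtype <- function(freq, threshold = 50, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (threshold < 0 || threshold > freq$M)
    stop_mirmark("threshold must lie in 0..M", class = "config_error")
  cmp <- if (comparator == ">=") `>=` else `>`
  ids <- rownames(freq$counts)
  sets <- lapply(seq_len(ncol(freq$counts)),
                 function(j) ids[cmp(freq$counts[, j], threshold)])
  names(sets) <- colnames(freq$counts)
  sets
}

#' Cross-subtype participation filter
#'
#' Keeps features that belong to at least `min_subtypes` of the per-subtype
#' sets; a feature informative for at least half of the five subtypes
#' (`min_subtypes = 3`) is considered a cross-subtype marker.
#'
#' @param subtype_sets Named list of per-subtype feature-ID sets (from
#'   [select_per_subtype()]).
#' @param min_subtypes Minimum number of subtype sets a feature must appear
#'   in, between 1 and the number of sets.
#' @return A list of class `feature_panel` with `per_subtype_sets`,
#'   `selected` (the panel, ordered by decreasing participation), and
#'   `participation` (named integer vector over all participating features).
#' @export
select_features <- function(subtype_sets, min_subtypes = 3) {
  if (min_subtypes < 1 || min_subtypes > length(subtype_sets))
    stop_mirmark("min_subtypes must lie in 1..", length(subtype_sets),
                 class = "config_error")
  all_ids <- unique(unlist(subtype_sets, use.names = FALSE))
  part <- vapply(all_ids, function(id)
    sum(vapply(subtype_sets, function(s) id %in% s, logical(1))), integer(1))
  selected <- all_ids[part >= min_subtypes]
  selected <- selected[order(-part[selected], selected)]
  structure(list(per_subtype_sets = subtype_sets,
                 selected = selected,
                 participation = part,
                 min_subtypes = as.integer(min_subtypes)),
            class = "feature_panel")
}

#' @method print feature_panel
#' @export
print.feature_panel <- function(x, ...) {
  cat("<feature_panel> ", length(x$selected), " features in >= ",
      x$min_subtypes, " subtypes (of ",
      length(unique(unlist(x$per_subtype_sets))),
      " participating anywhere)\n", sep = "")
  invisible(x)
}

#' Per-subtype participating feature counts
#'
#' @param panel A [select_features()] result.
#' @return Named integer vector: the size of each per-subtype set `|D_j|`.
#' @export
subtype_participation_counts <- function(panel) {
  vapply(panel$per_subtype_sets, length, integer(1))
}

#' Write a feature panel as a TSV report
#'
#' One row per participating feature: its participation count, per-subtype
#' selection indicators, and whether it made the panel.
#'
#' @param panel A [select_features()] result.
#' @param freq The [count_frequencies()] table the panel was derived from.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, freq, path) {
  ids <- names(panel$participation)
  df <- data.frame(feature_id = ids,
                   participation = unname(panel$participation),
                   selected = ids %in% panel$selected)
  df <- cbind(df, freq$counts[ids, , drop = FALSE])
  write_tsv(df[order(-df$participation, df$feature_id), ], path)
}
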