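#' Stratified train/test split
#'
#' Draws, independently within each subtype, `round(train_frac * n_subtype)`
#' samples (round half up) uniformly without replacement into the training
#' set; the remainder form the test set. With the study's subtype sizes
#' (86, 39, 24, 41, 41) and `train_frac = 0.8` this yields per-subtype
#' training counts (69, 31, 19, 33, 33): 185 training and 46 test samples.
#'
#' @param labels Per-sample subtype labels (factor/character/integer codes).
#' @param train_frac Training fraction, strictly in (0, 1).
#' @param seed Integer seed; the split is deterministic given it.
#' @return A list of class `split_result` with `train_indices`,
#'   `test_indices`, `seed`, and `per_subtype_train_counts`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed) {
  labels <- coerce_labels(labels, length(labels))
  if (!(train_frac > 0 && train_frac < 1))
    stop_mirmark("train_frac must be strictly inside (0, 1)",
                 class = "config_error")
  sizes <- table(labels)
  present <- names(sizes)[sizes > 0]
  small <- names(sizes)[sizes > 0 & sizes < 2]
  if (length(small))
    stop_mirmark("subtype(s) with fewer than 2 samples: ",
                 paste(small, collapse = ", "), class = "stratification_error")
  train <- integer(0)
  counts <- integer(0)
  withr::with_seed(seed, {
    for (lv in present) {
      idx <- which(labels == lv)
      k <- as.integer(round_half_up(train_frac * length(idx)))
      train <- c(train, sort(sample(idx, k)))
      counts[lv] <- k
    }
  })
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_along(labels), train),
                 seed = as.integer(seed),
                 per_subtype_train_counts = counts),
            class = "split_result")
}

#' Per-subtype bootstrap resample of a training set
#'
#' For each subtype independently, draws with replacement a resample equal in
#' size to that subtype's training count, from that subtype's training
#' indices only, and concatenates the blocks. Resamples never cross subtype
#' boundaries, preserving the stratified class balance of the training set.
#'
#' @param split A [stratified_split()] result.
#' @param labels The label vector the split was built from.
#' @param seed Integer seed.
#' @return Integer vector of resampled training indices (length equal to the
#'   training set).
#' @export
bootstrap_per_subtype <- function(split, labels, seed) {
  stopifnot(inherits(split, "split_result"))
  labels <- coerce_labels(labels, length(labels))
  out <- integer(0)
  withr::with_seed(seed, {
    for (lv in names(split$per_subtype_train_counts)) {
      idx <- split$train_indices[labels[split$train_indices] == lv]
      out <- c(out, sample(idx, length(idx), replace = TRUE))
    }
  })
  out
}
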