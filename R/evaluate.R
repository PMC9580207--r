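#' Compare classifiers on competing feature sets under shared splits
#'
#' For each seed `1..n_seeds` one stratified 80/20 split is drawn and shared
#' by every (method, feature set) pair, so accuracy differences are never an
#' artifact of data division. Per pair, the average classification accuracy
#' (ACA), sample variance, and a t-based 95% confidence interval over the
#' seeds are reported.
#'
#' Built-in methods: `"MLR"` (unpenalized multinomial logistic regression,
#' nnet), `"MLR-R"` / `"MLR-L"` / `"MLR-EN"` (ridge / lasso / elastic-net
#' penalized, glmnet with seeded 10-fold CV for lambda), `"RF"`
#' (randomForest), `"SVM"` (e1071, radial kernel), `"NB"` (e1071 naive
#' Bayes). A method may also be supplied as a function
#' `function(x_train, y_train, x_test, seed)` returning predicted labels.
#'
#' @param cohort A log2-scale [expression_cohort()].
#' @param feature_sets Named list of feature-ID character vectors (use the
#'   full `cohort$feature_ids` for a whole-feature-set arm).
#' @param methods Character vector of built-in names and/or a named list
#'   mixing names and classifier functions.
#' @param n_seeds Number of shared splits (the comparison protocol uses 100).
#' @param train_frac Training fraction per split.
#' @param level Confidence level for the ACA interval.
#' @return A list of class `comparison_report` with `accuracies` (named
#'   list of per-pair accuracy vectors), `summary` (data frame: method,
#'   feature_set, aca, variance, ci_low, ci_high), and `split_hashes`
#'   (per-seed digest of the shared split, for audit).
#' @export
compare_methods <- function(cohort, feature_sets, methods = c("MLR-R"),
                            n_seeds = 100, train_frac = 0.8, level = 0.95) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(names(feature_sets)) || any(names(feature_sets) == ""))
    stop_mirmark("feature_sets must be a named list", class = "config_error")
  for (nm in names(feature_sets)) {
    bad <- setdiff(feature_sets[[nm]], cohort$feature_ids)
    if (length(bad))
      stop_mirmark("feature set '", nm, "' has unknown feature(s): ",
                   paste(head(bad, 3), collapse = ", "),
                   class = "config_error")
  }
  methods <- as.list(methods)
  if (is.null(names(methods)))
    names(methods) <- vapply(methods, function(m)
      if (is.character(m)) m else "custom", character(1))
  fitters <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    if (is.function(m)) m else builtin_classifier(m)
  })
  names(fitters) <- names(methods)

  pairs <- expand.grid(method = names(fitters),
                       feature_set = names(feature_sets),
                       stringsAsFactors = FALSE)
  acc <- matrix(NA_real_, n_seeds, nrow(pairs))
  split_hashes <- character(n_seeds)
  for (s in seq_len(n_seeds)) {
    split <- stratified_split(cohort$labels, train_frac, seed = s)
    split_hashes[s] <- paste(split$train_indices, collapse = ",")
    ytr <- droplevels(cohort$labels[split$train_indices])
    yte <- cohort$labels[split$test_indices]
    for (i in seq_len(nrow(pairs))) {
      ids <- feature_sets[[pairs$feature_set[i]]]
      xtr <- cohort$values[split$train_indices, ids, drop = FALSE]
      xte <- cohort$values[split$test_indices, ids, drop = FALSE]
      pred <- fitters[[pairs$method[i]]](xtr, ytr, xte, derive_seed(s, i))
      acc[s, i] <- mean(as.character(pred) == as.character(yte))
    }
  }
  accuracies <- setNames(lapply(seq_len(nrow(pairs)), function(i) acc[, i]),
                         paste(pairs$method, pairs$feature_set, sep = " | "))
  summ <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ci <- aca_ci(acc[, i], level = level)
    data.frame(method = pairs$method[i], feature_set = pairs$feature_set[i],
               aca = ci$mean, variance = ci$variance,
               ci_low = ci$ci_low, ci_high = ci$ci_high)
  }))
  structure(list(accuracies = accuracies, summary = summ,
                 split_hashes = split_hashes),
            class = "comparison_report")
}

builtin_classifier <- function(name) {
  glmnet_clf <- function(alpha_grid) function(xtr, ytr, xte, seed) {
    cfg <- penalty_config(alpha_grid = alpha_grid)
    par <- select_params(xtr, ytr, cfg, seed = seed)
    model <- fit_mlr_en(xtr, ytr, par$alpha0, par$lambda0, cfg)
    predict_class(model, xte)
  }
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop_mirmark("method requires the ", pkg, " package",
                   class = "config_error")
  }
  switch(name,
    "MLR-R" = glmnet_clf(0),
    "MLR-L" = glmnet_clf(1),
    "MLR-EN" = glmnet_clf(c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95)),
    "MLR" = function(xtr, ytr, xte, seed) {
      need("nnet")
      dat <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- withr::with_seed(seed, nnet::multinom(
        .y ~ ., data = dat, maxit = 500, MaxNWts = 1e5, trace = FALSE))
      predict(fit, newdata = data.frame(xte, check.names = TRUE),
              type = "class")
    },
    "RF" = function(xtr, ytr, xte, seed) {
      need("randomForest")
      fit <- withr::with_seed(seed, randomForest::randomForest(xtr, ytr))
      predict(fit, xte)
    },
    "SVM" = function(xtr, ytr, xte, seed) {
      need("e1071")
      fit <- withr::with_seed(seed, e1071::svm(xtr, ytr))
      predict(fit, xte)
    },
    "NB" = function(xtr, ytr, xte, seed) {
      need("e1071")
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    stop_mirmark("unknown method: ", name, class = "config_error"))
}

#' Mean accuracy with variance and t-interval
#'
#' @param accuracies Numeric vector of per-split accuracies (length >= 2).
#' @param level Confidence level.
#' @return List with `mean` (the ACA), `variance` (sample variance),
#'   `ci_low`, `ci_high` (t-interval for the mean; degenerates to a point
#'   when the variance is 0).
#' @export
aca_ci <- function(accuracies, level = 0.95) {
  n <- length(accuracies)
  if (n < 2) stop_mirmark("need at least 2 accuracy values",
                          class = "config_error")
  m <- mean(accuracies); v <- var(accuracies)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sqrt(v / n)
  list(mean = m, variance = v, ci_low = m - half, ci_high = m + half)
}

#' Two-sided t-test between two methods' accuracy vectors
#'
#' Paired by default (shared splits make per-seed differences the natural
#' unit); unpaired uses Welch's correction. Degenerate zero-variance cases
#' are guarded: identical vectors give p = 1, a constant nonzero difference
#' gives p = 0, each with a warning instead of an error.
#'
#' @param acc_a,acc_b Accuracy vectors (equal length if paired).
#' @param paired Use the paired test.
#' @return List with `t` and `p_value`.
#' @export
method_ttest <- function(acc_a, acc_b, paired = TRUE) {
  if (paired && length(acc_a) != length(acc_b))
    stop_mirmark("paired test needs equal-length vectors",
                 class = "config_error")
  degenerate <- if (paired) sd(acc_a - acc_b) == 0 else
    (sd(acc_a) == 0 && sd(acc_b) == 0)
  if (degenerate) {
    d <- mean(acc_a) - mean(acc_b)
    warning("zero-variance degenerate case in method_ttest")
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0))
  }
  ht <- t.test(acc_a, acc_b, paired = paired)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}
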