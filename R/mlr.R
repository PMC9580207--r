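#' Elastic-net tuning configuration
#'
#' @param alpha_grid Candidate elastic-net mixing values in `[0, 1]`
#'   (0 = ridge, 1 = lasso). The default grid
#'   `{0.05, 0.2, 0.4, 0.6, 0.8, 0.95}` spans nearly-ridge to nearly-lasso.
#' @param lambda_path_length Number of log-spaced penalty strengths per alpha.
#' @param cv_folds Cross-validation folds used to pick `lambda` per alpha.
#' @param convergence_tol Coordinate-descent convergence threshold.
#' @param max_iter Maximum solver iterations.
#' @param standardize Standardize features inside the solver (coefficients
#'   are always reported on the original scale).
#' @return A list of class `penalty_config`.
#' @export
penalty_config <- function(alpha_grid = c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95),
                           lambda_path_length = 100,
                           cv_folds = 10,
                           convergence_tol = 1e-7,
                           max_iter = 1e5,
                           standardize = TRUE) {
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop_mirmark("alpha_grid values must lie in [0, 1]", class = "config_error")
  if (cv_folds < 2)
    stop_mirmark("cv_folds must be at least 2", class = "config_error")
  structure(list(alpha_grid = alpha_grid,
                 lambda_path_length = as.integer(lambda_path_length),
                 cv_folds = as.integer(cv_folds),
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 standardize = standardize),
            class = "penalty_config")
}

as_model_response <- function(y) {
  y <- if (is.numeric(y)) factor(subtype_levels()[y],
                                 levels = subtype_levels()) else as.factor(y)
  droplevels(y)
}

#' Smallest penalty that zeroes every feature coefficient
#'
#' The entry point of the regularization path: for `lambda` at or above this
#' bound the penalized multinomial fit keeps all feature coefficients at
#' exactly zero (for `alpha > 0`) and predicts the training class
#' proportions. Computed from the null-model score
#' `max_(k,j) |<x_k, I(y=j) - p_j>| / (n * alpha)` with features centered
#' (and scaled when `standardize`).
#'
#' @param x Numeric n x p matrix.
#' @param y Class labels.
#' @param alpha Elastic-net mixing parameter, must be > 0.
#' @param standardize Match the solver's internal standardization.
#' @return The data-derived `lambda_max` bound.
#' @export
lambda_max <- function(x, y, alpha, standardize = TRUE) {
  if (alpha <= 0)
    stop_mirmark("lambda_max is unbounded for alpha <= 0", class = "config_error")
  y <- as_model_response(y)
  n <- nrow(x)
  xs <- scale(x, center = TRUE,
              scale = if (standardize) apply(x, 2, function(v)
                sqrt(sum((v - mean(v))^2) / n)) else FALSE)
  ind <- outer(as.character(y), levels(y), `==`) * 1
  resid <- sweep(ind, 2, colMeans(ind))
  max(abs(crossprod(xs, resid))) / (n * alpha)
}

#' Fit one penalized multinomial logistic regression model
#'
#' Minimizes the 1/n-scaled negative multinomial log-likelihood plus
#' `lambda * P_alpha(w)` where
#' `P_alpha(w) = (1 - alpha)/2 * sum(w^2) + alpha * sum(|w|)` runs over all
#' feature coefficients of all classes; intercepts are never penalized.
#' Solved by glmnet's coordinate descent, warm-started along a short path
#' ending at the requested `lambda` for solution accuracy.
#'
#' @param x Numeric n x p training matrix.
#' @param y Training class labels.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength (>= 0).
#' @param config A [penalty_config()].
#' @return A list of class `mlr_en`: `coefficients` (p x K matrix, one
#'   column per class), `intercepts`, `classes`, `alpha`, `lambda`, and
#'   `objective_value` (the attained penalized objective).
#' @export
fit_mlr_en <- function(x, y, alpha, lambda, config = penalty_config()) {
  y <- as_model_response(y)
  if (nlevels(y) < 2)
    stop_mirmark("training data contains a single class", class = "fit_error")
  if (nrow(x) != length(y))
    stop_mirmark("x rows and y length differ", class = "dimension_error")
  path <- fit_path(x, y, alpha, lambda, config)
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                        lambda = path, standardize = config$standardize,
                        thresh = config$convergence_tol,
                        maxit = config$max_iter)
  s_ix <- which.min(abs(fit$lambda - lambda))
  cf <- coef(fit, s = fit$lambda[s_ix])
  W <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1, , drop = FALSE]))
  b <- vapply(cf, function(m) as.matrix(m)[1, 1], numeric(1))
  colnames(W) <- levels(y)
  rownames(W) <- colnames(x)
  model <- structure(list(coefficients = W, intercepts = unname(b),
                          classes = levels(y), alpha = alpha, lambda = lambda,
                          objective_value = NA_real_),
                     class = "mlr_en")
  model$objective_value <- penalized_objective(model, x, y)
  model
}

# warm-start path from lambda_max down to the target lambda
fit_path <- function(x, y, alpha, lambda, config) {
  lmax <- if (alpha > 0) lambda_max(x, y, alpha, config$standardize) else
    lambda_max(x, y, 0.001, config$standardize) * 0.001
  if (lambda >= lmax) return(c(lambda * 1.001, lambda))
  path <- exp(seq(log(lmax), log(max(lambda, 1e-12)), length.out = 25))
  path[length(path)] <- lambda
  path
}

#' Multinomial log-likelihood of a fitted model on a data slice
#'
#' `sum_i [ (w_{y_i}' x_i + b_{y_i}) - log sum_j exp(w_j' x_i + b_j) ]`;
#' never positive, and invariant to adding a constant to every intercept.
#'
#' @param model An `mlr_en` model.
#' @param x Numeric matrix with `nrow(model$coefficients)` columns.
#' @param y True labels (must be among `model$classes`).
#' @return The log-likelihood (a scalar `<= 0`).
#' @export
multinomial_log_likelihood <- function(model, x, y) {
  P <- predict_proba(model, x, log = TRUE)
  y <- match(as.character(as_model_response(y)), model$classes)
  if (anyNA(y)) stop_mirmark("labels outside the model's classes",
                             class = "dimension_error")
  sum(P[cbind(seq_len(nrow(P)), y)])
}

#' Elastic-net penalty value
#'
#' `(1 - alpha)/2 * sum(w^2) + alpha * sum(|w|)` over every feature
#' coefficient (intercepts excluded by construction).
#'
#' @param coefficients Numeric matrix (or vector) of feature coefficients.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @return The penalty value.
#' @export
elastic_net_penalty <- function(coefficients, alpha) {
  if (alpha < 0 || alpha > 1)
    stop_mirmark("alpha must lie in [0, 1]", class = "config_error")
  (1 - alpha) / 2 * sum(coefficients^2) + alpha * sum(abs(coefficients))
}

penalized_objective <- function(model, x, y) {
  -multinomial_log_likelihood(model, x, y) / nrow(x) +
    model$lambda * elastic_net_penalty(model$coefficients, model$alpha)
}

#' Class probabilities from a fitted model
#'
#' Softmax over the class scores `x %*% W + b`; rows sum to one.
#'
#' @param model An `mlr_en` model.
#' @param x Numeric matrix with matching feature count.
#' @param log Return log-probabilities instead.
#' @return An n x K matrix of (log-)probabilities, columns named by class.
#' @export
predict_proba <- function(model, x, log = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$coefficients))
    stop_mirmark("feature count mismatch: model has ",
                 nrow(model$coefficients), ", data has ", ncol(x),
                 class = "dimension_error")
  scores <- sweep(x %*% model$coefficients, 2, model$intercepts, `+`)
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  lp <- scores - lse
  colnames(lp) <- model$classes
  if (log) lp else exp(lp)
}

#' Predicted class labels (argmax, ties to the smallest class index)
#'
#' @param model An `mlr_en` model.
#' @param x Numeric matrix.
#' @return Factor of predicted labels with levels `model$classes`.
#' @export
predict_class <- function(model, x) {
  P <- predict_proba(model, x)
  ix <- apply(P, 1, which.max)  # which.max: first maximum = smallest index
  factor(model$classes[ix], levels = model$classes)
}

#' Select the optimal (alpha, lambda) pair by cross-validation
#'
#' For each alpha on the grid, runs `cv_folds`-fold cross-validation (folds
#' stratified by class, seeded) over a log-spaced lambda path and records
#' the mean multinomial deviance; returns the pair minimizing it.
#'
#' @param x Numeric n x p training matrix.
#' @param y Training class labels.
#' @param config A [penalty_config()].
#' @param seed Integer seed controlling fold assignment.
#' @return A list with `alpha0`, `lambda0`, and `cv_table` (one row per
#'   alpha: the minimizing lambda, its mean CV deviance and SE, and the
#'   deviance at the top of the path).
#' @export
select_params <- function(x, y, config = penalty_config(), seed = 1) {
  y <- as_model_response(y)
  if (nlevels(y) < 2)
    stop_mirmark("cannot cross-validate a single-class response",
                 class = "fit_error")
  foldid <- stratified_folds(y, config$cv_folds, seed)
  rows <- lapply(config$alpha_grid, function(a) {
    cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = a,
                            foldid = foldid,
                            nlambda = config$lambda_path_length,
                            type.measure = "deviance",
                            standardize = config$standardize,
                            thresh = config$convergence_tol,
                            maxit = config$max_iter)
    i <- which.min(cv$cvm)
    data.frame(alpha = a, lambda = cv$lambda[i], deviance = cv$cvm[i],
               deviance_se = cv$cvsd[i], deviance_at_lambda_max = cv$cvm[1])
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$deviance)
  list(alpha0 = tab$alpha[best], lambda0 = tab$lambda[best], cv_table = tab)
}

# class-stratified fold ids: shuffle within class, deal folds round-robin
stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      if (length(idx) < k)
        warning("class ", lv, " has fewer samples (", length(idx),
                ") than folds (", k, ")")
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Karush-Kuhn-Tucker residual of a fitted elastic-net model
#'
#' For a model fitted with `standardize = FALSE`, computes the stationarity
#' residual of the penalized objective at the returned coefficients: for
#' zero coefficients the smooth-part gradient must not exceed
#' `lambda * alpha` in absolute value; for active coefficients the
#' subgradient must vanish. Returns the largest violation (0 = exact
#' stationarity).
#'
#' @param model An `mlr_en` model fitted without internal standardization.
#' @param x,y The training data the model was fitted on.
#' @return Maximum KKT violation over all feature coefficients.
#' @export
kkt_violation <- function(model, x, y) {
  y <- as_model_response(y)
  n <- nrow(x)
  P <- predict_proba(model, x)
  Yind <- outer(as.character(y), model$classes, `==`) * 1
  G <- crossprod(x, P - Yind) / n +
    model$lambda * (1 - model$alpha) * model$coefficients
  la <- model$lambda * model$alpha
  W <- model$coefficients
  viol_zero <- pmax(abs(G[W == 0]) - la, 0)
  viol_active <- abs(G[W != 0] + la * sign(W[W != 0]))
  max(c(0, viol_zero, viol_active))
}
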