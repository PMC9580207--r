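make_xy <- function(seed = 1, n = 60, p = 4, K = 5) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- factor(subtype_levels()[sample.int(K, n, replace = TRUE)],
                levels = subtype_levels()[1:K])
    for (j in 1:K) x[as.integer(y) == j, 1] <- x[as.integer(y) == j, 1] + j
    list(x = x, y = y)
  })
}

test_that("log-likelihood closed forms: uniform model, shift invariance, hand softmax", {
  d <- make_xy(1)
  zero <- structure(list(coefficients = matrix(0, 4, 5,
                                               dimnames = list(colnames(d$x),
                                                               subtype_levels())),
                         intercepts = rep(0, 5), classes = subtype_levels(),
                         alpha = 0.5, lambda = 0.1), class = "mlr_en")
  expect_equal(multinomial_log_likelihood(zero, d$x, d$y),
               nrow(d$x) * log(1 / 5))

  shifted <- zero
  shifted$intercepts <- zero$intercepts + 3.7
  expect_equal(multinomial_log_likelihood(shifted, d$x, d$y),
               multinomial_log_likelihood(zero, d$x, d$y), tolerance = 1e-10)

  # single sample, intercept-only model b = (10, 0, 0, 0, 0), true class LA
  one <- zero
  one$intercepts <- c(10, 0, 0, 0, 0)
  x1 <- matrix(0, 1, 4)
  hand <- 10 - log(exp(10) + 4)
  expect_equal(multinomial_log_likelihood(one, x1, factor("LA", subtype_levels())),
               hand, tolerance = 1e-12)
})

test_that("elastic-net penalty closed forms", {
  expect_equal(elastic_net_penalty(matrix(0, 3, 5), 0.5), 0)
  expect_equal(elastic_net_penalty(2, 1), 2)   # pure L1
  expect_equal(elastic_net_penalty(2, 0), 2)   # 0.5 * 2^2
  expect_equal(elastic_net_penalty(c(1, -2), 0.4),
               0.6 * 0.5 * 5 + 0.4 * 3)
  expect_error(elastic_net_penalty(1, 1.5), class = "config_error")
})

test_that("lambda at or above lambda_max zeroes all feature coefficients", {
  d <- make_xy(2)
  for (a in c(0.2, 0.95)) {
    lm_ <- lambda_max(d$x, d$y, a)
    fit <- fit_mlr_en(d$x, d$y, a, lm_ * 1.0001)
    expect_true(all(fit$coefficients == 0))
    # prediction reduces to training-class priors
    pr <- predict_proba(fit, d$x[1:3, , drop = FALSE])
    prior <- as.numeric(table(d$y) / length(d$y))
    expect_equal(unname(pr[1, ]), prior, tolerance = 1e-6)
    # and just below the bound, something activates
    fit2 <- fit_mlr_en(d$x, d$y, a, lm_ * 0.8)
    expect_gt(sum(fit2$coefficients != 0), 0)
  }
})

test_that("a separable two-class problem is fit to training accuracy 1", {
  withr::with_seed(3, {
    n <- 40
    x <- cbind(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
               f2 = rnorm(n))
    y <- rep(c("LA", "LB"), each = n / 2)
  })
  fit <- fit_mlr_en(x, y, alpha = 0.5, lambda = 1e-4)
  expect_equal(mean(as.character(predict_class(fit, x)) == y), 1)
})

test_that("ridge fit matches an independent BFGS solver within 1e-4", {
  withr::with_seed(4, {
    n <- 20; p <- 3
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- factor(rep(subtype_levels(), each = 4), levels = subtype_levels())
    x[, 1] <- x[, 1] + as.integer(y)
  })
  lambda <- 0.5
  cfg <- penalty_config(standardize = FALSE, convergence_tol = 1e-12)
  fit <- fit_mlr_en(x, y, alpha = 0, lambda = lambda, config = cfg)
  oracle <- ridge_multinomial_oracle(x, y, lambda)
  expect_lt(max(abs(fit$coefficients - oracle$W)), 1e-4)
})

test_that("KKT subgradient conditions hold at elastic-net solutions", {
  for (s in 1:3) {
    d <- make_xy(10 + s, n = 50, p = 6)
    cfg <- penalty_config(standardize = FALSE, convergence_tol = 1e-12)
    fit <- fit_mlr_en(d$x, d$y, alpha = 0.5,
                      lambda = 0.3 * lambda_max(d$x, d$y, 0.5, FALSE),
                      config = cfg)
    expect_gt(sum(fit$coefficients == 0), 0)  # fixture really is sparse
    expect_lt(kkt_violation(fit, d$x, d$y), 1e-4)
  }
})

test_that("smooth loss decreases as lambda decreases along the path", {
  d <- make_xy(6, n = 80)
  lm_ <- lambda_max(d$x, d$y, 0.5)
  lambdas <- lm_ * c(0.5, 0.1, 0.02)
  losses <- vapply(lambdas, function(l) {
    fit <- fit_mlr_en(d$x, d$y, 0.5, l)
    -multinomial_log_likelihood(fit, d$x, d$y) / nrow(d$x)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("near-zero penalty agrees with an unpenalized multinomial fit", {
  skip_if_not_installed("nnet")
  withr::with_seed(7, {
    n <- 150
    x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- factor(subtype_levels()[1 + (x[, 1] + 0.5 * rnorm(n) > 0) +
                                   (x[, 2] + 0.5 * rnorm(n) > 0)],
                levels = subtype_levels())
  })
  fit <- fit_mlr_en(x, y, alpha = 0, lambda = 0,
                    config = penalty_config(standardize = FALSE,
                                            convergence_tol = 1e-12))
  dat <- data.frame(y = y, x)
  nn <- nnet::multinom(y ~ f1 + f2, dat, trace = FALSE, reltol = 1e-14)
  # coefficients are not identified at lambda = 0 (softmax shift); compare
  # the fitted class probabilities instead
  p1 <- predict_proba(fit, x)[, levels(droplevels(y))]
  p2 <- predict(nn, dat, type = "probs")
  expect_lt(max(abs(p1 - p2)), 1e-3)
})

test_that("probability readout: rows sum to 1, argmax consistent, ties break low", {
  d <- make_xy(8)
  fit <- fit_mlr_en(d$x, d$y, 0.3, 0.05)
  P <- predict_proba(fit, d$x)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  cl <- predict_class(fit, d$x)
  expect_identical(as.integer(cl), unname(apply(P, 1, which.max)))

  zero <- fit
  zero$coefficients[] <- 0
  zero$intercepts[] <- 0
  P0 <- predict_proba(zero, d$x[1:2, , drop = FALSE])
  expect_equal(unname(P0), matrix(0.2, 2, 5))
  expect_identical(as.character(predict_class(zero, d$x[1:2, , drop = FALSE])),
                   c("LA", "LA"))  # all-tied rows resolve to the first class
  expect_error(predict_proba(fit, d$x[, 1:2]), class = "dimension_error")
})

test_that("cross-validated parameter selection is deterministic and grid-respecting", {
  d <- make_xy(9, n = 80)
  cfg <- penalty_config(alpha_grid = 0.4, lambda_path_length = 40)
  p1 <- select_params(d$x, d$y, cfg, seed = 5)
  expect_equal(p1$alpha0, 0.4)
  p2 <- select_params(d$x, d$y, cfg, seed = 5)
  expect_identical(p1, p2)
})

test_that("on pure noise the null end of the path is competitive", {
  withr::with_seed(12, {
    n <- 60
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y <- factor(subtype_levels()[sample.int(5, n, replace = TRUE)],
                levels = subtype_levels())
  })
  cfg <- penalty_config(alpha_grid = 0.5, lambda_path_length = 40)
  sel <- select_params(x, y, cfg, seed = 2)
  tab <- sel$cv_table
  # CV deviance at lambda_max within one SE of the minimum
  expect_lte(tab$deviance_at_lambda_max, tab$deviance + tab$deviance_se)
})
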