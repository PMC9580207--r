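tiny_config <- function() penalty_config(alpha_grid = c(0.2, 0.8),
                                         lambda_path_length = 25,
                                         cv_folds = 3)

test_that("vote tallies conserve M and fractions sum to one", {
  g <- small_cohort(seed = 21)
  sp <- stratified_split(g$cohort$labels, 0.8, seed = 1)
  ens <- train_ensemble(g$cohort, sp, M = 4, config = tiny_config(), seed = 2)
  expect_length(ens$models, 4)
  expect_true(all(rowSums(ens$vote_matrix) == 4))
  pred <- vote_predict(ens, g$cohort$values[sp$test_indices, , drop = FALSE])
  expect_equal(unname(rowSums(pred$vote_fractions)),
               rep(1, length(sp$test_indices)))
})

test_that("ensemble training is reproducible given the master seed", {
  g <- small_cohort(seed = 22, n_per = c(12, 8, 6, 8, 8), n_features = 20,
                    informative = 2, multi = 3)
  sp <- stratified_split(g$cohort$labels, 0.8, seed = 1)
  e1 <- train_ensemble(g$cohort, sp, M = 2, config = tiny_config(), seed = 7)
  e2 <- train_ensemble(g$cohort, sp, M = 2, config = tiny_config(), seed = 7)
  expect_identical(lapply(e1$models, `[[`, "coefficients"),
                   lapply(e2$models, `[[`, "coefficients"))
  expect_identical(e1$vote_matrix, e2$vote_matrix)
})

test_that("strong-signal ensembles beat the prior-class accuracy on held-out data", {
  g <- small_cohort(seed = 23, n_per = c(24, 16, 12, 16, 16),
                    n_features = 40, informative = 3, multi = 6, effect = 2)
  sp <- stratified_split(g$cohort$labels, 0.8, seed = 1)
  ens <- train_ensemble(g$cohort, sp, M = 6, config = tiny_config(), seed = 3)
  pred <- vote_predict(ens, g$cohort$values[sp$test_indices, , drop = FALSE])
  truth <- g$cohort$labels[sp$test_indices]
  prior_acc <- max(table(g$cohort$labels)) / length(g$cohort$labels)
  expect_gt(mean(pred$labels == truth), prior_acc)
})

test_that("majority vote follows documented tie-breaks", {
  W <- matrix(0, 3, 5, dimnames = list(paste0("f", 1:3), subtype_levels()))
  # two models voting H2 via intercepts, one model voting BL
  mk <- function(b) structure(list(coefficients = W, intercepts = b,
                                   classes = subtype_levels(),
                                   alpha = 0.5, lambda = 0.1),
                              class = "mlr_en")
  ens <- fake_ensemble(list(W, W, W))
  ens$models <- list(mk(c(0, 0, 5, 0, 0)), mk(c(0, 0, 5, 0, 0)),
                     mk(c(0, 0, 5, 0, 0)))
  x <- matrix(rnorm(6), 2, 3)
  pred <- vote_predict(ens, x)
  expect_identical(as.character(pred$labels), c("H2", "H2"))
  expect_equal(unname(pred$vote_fractions[1, ]), c(0, 0, 1, 0, 0))

  # 50/50 split between classes 1 and 2 resolves to class 1
  ens$models <- list(mk(c(5, 0, 0, 0, 0)), mk(c(0, 5, 0, 0, 0)))
  ens$M <- 2L
  pred <- vote_predict(ens, x)
  expect_identical(as.character(pred$labels), c("LA", "LA"))

  ens$models <- list()
  expect_error(vote_predict(ens, x), class = "fit_error")
})

test_that("cross-entropy closed forms, floor, and bounds", {
  vf <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))
  expect_equal(cross_entropy(vf, c(1, 2)), 0)

  vf0 <- rbind(c(0, 1, 0, 0, 0))
  expect_equal(cross_entropy(vf0, 1), -log(0.001), tolerance = 1e-12)
  expect_equal(cross_entropy(vf0, 1), 6.9078, tolerance = 1e-4)

  vf2 <- rbind(c(0.5, 0.5, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(cross_entropy(vf2, c(1, 1)),
               (-log(0.5) - log(0.25)) / 2, tolerance = 1e-12)
  expect_equal(cross_entropy(vf2, c(1, 1)), 1.0397, tolerance = 1e-4)

  # non-negativity with equality iff all true-class fractions are 1
  withr::with_seed(1, {
    vf3 <- matrix(runif(50), 10, 5)
    vf3 <- vf3 / rowSums(vf3)
  })
  expect_gt(cross_entropy(vf3, rep(1, 10)), 0)
  expect_error(cross_entropy(vf, c(1, 6)), class = "label_error")
  expect_error(cross_entropy(vf, c(1, 2), floor = 0), class = "config_error")
  # label names are accepted too
  expect_equal(cross_entropy(vf2, c("LA", "LA")),
               cross_entropy(vf2, c(1, 1)))
})

test_that("seed search ranks by accuracy then cross-entropy", {
  g <- small_cohort(seed = 24, n_per = c(6, 5, 4, 5, 5), n_features = 8,
                    informative = 1, multi = 0, n_prog = 0)
  stub <- function(scores) {
    i <- 0
    function(cohort, seed) {
      i <<- i + 1
      list(accuracy = scores$acc[i], cross_entropy = scores$ce[i])
    }
  }
  r1 <- seed_search(g$cohort, n_repeats = 3,
                    eval_fn = stub(list(acc = c(0.5, 0.9, 0.7),
                                        ce = c(1, 1, 1))))
  expect_equal(r1$best_seed, 2)
  expect_equal(r1$per_seed$accuracy, c(0.5, 0.9, 0.7))

  r2 <- seed_search(g$cohort, n_repeats = 2,
                    eval_fn = stub(list(acc = c(0.9, 0.9), ce = c(0.6, 0.4))))
  expect_equal(r2$best_seed, 2)

  r3 <- seed_search(g$cohort, n_repeats = 1,
                    eval_fn = function(cohort, seed)
                      list(accuracy = 0.5, cross_entropy = 1))
  expect_equal(r3$best_seed, 1)
})

test_that("a failed repeat is recorded with a warning, not dropped", {
  g <- small_cohort(seed = 25, n_per = c(6, 5, 4, 5, 5), n_features = 8,
                    informative = 1, multi = 0, n_prog = 0)
  flaky <- function(cohort, seed)
    if (seed == 1) stop("boom") else list(accuracy = 0.6, cross_entropy = 1)
  expect_warning(res <- seed_search(g$cohort, n_repeats = 2,
                                    eval_fn = flaky), "boom")
  expect_true(is.na(res$per_seed$accuracy[1]))
  expect_equal(res$best_seed, 2)
})

test_that("ensemble vote accuracy is no worse than a typical member (10 seeds)", {
  wins <- 0
  for (s in 1:10) {
    g <- small_cohort(seed = 30 + s, n_per = c(14, 10, 8, 10, 10),
                      n_features = 24, informative = 2, multi = 4)
    sp <- stratified_split(g$cohort$labels, 0.8, seed = s)
    ens <- train_ensemble(g$cohort, sp, M = 5, config = tiny_config(),
                          seed = s)
    xte <- g$cohort$values[sp$test_indices, , drop = FALSE]
    truth <- g$cohort$labels[sp$test_indices]
    vote_acc <- mean(vote_predict(ens, xte)$labels == truth)
    member_acc <- vapply(ens$models, function(m)
      mean(predict_class(m, xte) == truth), numeric(1))
    if (vote_acc >= median(member_acc)) wins <- wins + 1
  }
  expect_gte(wins / 10, 0.8)
})
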