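#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the structure of a TCGA breast-invasive-carcinoma style
#' miRNA-seq cohort: 231 samples over five subtypes (86 LA, 39 LB, 24 H2,
#' 41 BL, 41 control) and 296 log2-scale features.
#'
#' Planted signal has two layers: each subtype gets
#' `informative_per_subtype` features shifted by `+effect_size` in that
#' subtype only, and `n_multisubtype_features` additional features are each
#' shifted in 3 to 5 subtypes with subtype-varying signed magnitudes
#' (`effect_size * Uniform(0.5, 1.5)`, random sign). The variation is what
#' makes these cross-subtype markers learnable: a shift identical across
#' several classes cancels in the softmax and carries no class signal. Survival times follow an
#' exponential proportional-hazards model driven by `n_prognostic` features
#' drawn from the multisubtype pool with coefficients of alternating sign
#' `prognostic_beta`, and are independently exponentially censored at a rate
#' solved numerically to meet `censoring_rate_target`.
#'
#' @param n_per_subtype Integer vector of 5 subtype sample sizes.
#' @param n_features Total number of features.
#' @param informative_per_subtype Subtype-specific informative features per
#'   subtype (disjoint across subtypes).
#' @param n_multisubtype_features Features informative in >= 3 subtypes.
#' @param effect_size Mean shift (log2 units) added to informative features.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param n_prognostic Number of features with planted survival effects.
#' @param prognostic_beta Magnitude of the planted Cox log-hazard ratio per
#'   standardized unit of expression; signs alternate across features.
#' @param baseline_hazard_rate Exponential baseline hazard (events per time
#'   unit at zero risk score).
#' @param censoring_rate_target Desired censored fraction, strictly in (0,1).
#' @param seed Integer seed; the generator is fully reproducible given it.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_subtype = c(86, 39, 24, 41, 41),
                              n_features = 296,
                              informative_per_subtype = 8,
                              n_multisubtype_features = 30,
                              effect_size = 2,
                              noise_sd = 1,
                              n_prognostic = 8,
                              prognostic_beta = 0.8,
                              baseline_hazard_rate = 0.1,
                              censoring_rate_target = 0.4,
                              seed = 1) {
  cfg <- list(n_per_subtype = as.integer(n_per_subtype),
              n_features = as.integer(n_features),
              informative_per_subtype = as.integer(informative_per_subtype),
              n_multisubtype_features = as.integer(n_multisubtype_features),
              effect_size = effect_size, noise_sd = noise_sd,
              n_prognostic = as.integer(n_prognostic),
              prognostic_beta = prognostic_beta,
              baseline_hazard_rate = baseline_hazard_rate,
              censoring_rate_target = censoring_rate_target,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop_mirmark("invalid simulation config: ", field, " ", msg,
                          class = "config_error")
  }
  chk(length(cfg$n_per_subtype) == 5 && all(cfg$n_per_subtype >= 1),
      "n_per_subtype", "must be 5 positive integers")
  chk(cfg$n_features >= 1, "n_features", "must be positive")
  chk(cfg$informative_per_subtype >= 1, "informative_per_subtype",
      "must be positive")
  chk(cfg$n_multisubtype_features >= 0, "n_multisubtype_features",
      "must be non-negative")
  chk(cfg$noise_sd > 0, "noise_sd", "must be positive")
  chk(cfg$n_prognostic >= 0, "n_prognostic", "must be non-negative")
  chk(cfg$baseline_hazard_rate > 0, "baseline_hazard_rate", "must be positive")
  chk(cfg$censoring_rate_target > 0 && cfg$censoring_rate_target < 1,
      "censoring_rate_target", "must be strictly inside (0, 1)")
  n_inform <- 5L * cfg$informative_per_subtype + cfg$n_multisubtype_features
  chk(n_inform <= cfg$n_features, "n_multisubtype_features",
      paste0("informative pool (", n_inform, ") exceeds n_features (",
             cfg$n_features, ")"))
  chk(cfg$n_prognostic <= cfg$n_features, "n_prognostic",
      "exceeds n_features")
  invisible(cfg)
}

#' Generate a synthetic subtype/survival cohort with known ground truth
#'
#' Expression of feature k in sample i of subtype j is
#' `baseline_k + shift_jk + N(0, noise_sd)` with per-feature baselines
#' drawn once from Uniform(2, 12) on the log2 scale; `shift_jk` is
#' `effect_size` for subtype-specific informative pairs, a signed
#' subtype-varying multiple of `effect_size` for multisubtype markers, and
#' 0 otherwise (see [simulation_config()]). Survival times are exponential with hazard
#' `baseline_hazard_rate * exp(sum_k beta_k z_ik)` over the planted
#' prognostic features (standardized covariates), censored by an independent
#' exponential clock whose rate is solved so the expected censored fraction
#' equals `censoring_rate_target`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `cohort` (an [expression_cohort()], log2
#'   scale) and `truth`, a list with `informative_features` (per-subtype
#'   feature-ID sets), `multisubtype_features`, `prognostic_features`
#'   (named vector of planted betas), and `planted_shifts` (matrix of the
#'   per-subtype mean shifts of all informative features).
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  lv <- subtype_levels()
  n <- sum(cfg$n_per_subtype)
  p <- cfg$n_features
  feature_ids <- sprintf("mir-%03d", seq_len(p))
  sample_ids <- sprintf("S%03d", seq_len(n))
  labels <- rep(lv, times = cfg$n_per_subtype)

  # planted structure: disjoint subtype-specific blocks with a uniform
  # +effect_size shift, then a multisubtype pool whose members are
  # informative in 3-5 randomly chosen subtypes. Multisubtype shifts carry
  # subtype-varying signed magnitudes (effect_size * Uniform(0.5, 1.5),
  # random sign): a shift common to several classes cancels in the softmax,
  # so a cross-subtype marker is only learnable when its shifts differ
  # between the subtypes it marks.
  pool <- sample.int(p, 5L * cfg$informative_per_subtype +
                       cfg$n_multisubtype_features)
  specific <- matrix(pool[seq_len(5L * cfg$informative_per_subtype)], ncol = 5)
  multi <- pool[-seq_len(5L * cfg$informative_per_subtype)]
  informative <- lapply(1:5, function(j) specific[, j])
  names(informative) <- lv
  shift <- matrix(0, p, 5)
  for (j in 1:5) shift[specific[, j], j] <- cfg$effect_size
  for (k in multi) {
    in_subtypes <- sample.int(5, sample(3:5, 1))
    for (j in in_subtypes) {
      informative[[j]] <- c(informative[[j]], k)
      shift[k, j] <- cfg$effect_size * runif(1, 0.5, 1.5) *
        sample(c(-1, 1), 1)
    }
  }

  baseline <- runif(p, 2, 12)
  values <- matrix(rnorm(n * p, sd = cfg$noise_sd), n, p)
  values <- sweep(values, 2, baseline, `+`)
  for (j in 1:5) {
    rows <- which(labels == lv[j])
    values[rows, ] <- sweep(values[rows, , drop = FALSE], 2, shift[, j], `+`)
  }

  # survival: exponential PH over standardized prognostic covariates
  prognostic <- integer(0)
  beta <- numeric(0)
  if (cfg$n_prognostic > 0) {
    pool_prog <- if (length(multi) >= cfg$n_prognostic) multi else
      unique(c(multi, unlist(informative), seq_len(p)))
    prognostic <- sample(pool_prog, cfg$n_prognostic)
    beta <- cfg$prognostic_beta * (-1)^(seq_len(cfg$n_prognostic) + 1)
  }
  eta <- if (length(prognostic)) {
    z <- scale(values[, prognostic, drop = FALSE])
    drop(z %*% beta)
  } else rep(0, n)
  hazard <- cfg$baseline_hazard_rate * exp(eta)
  event_time <- rexp(n, rate = hazard)
  cens_rate <- solve_censoring_rate(hazard, cfg$censoring_rate_target)
  cens_time <- rexp(n, rate = cens_rate)
  survival <- data.frame(time = pmin(event_time, cens_time),
                         event = as.integer(event_time <= cens_time))

  cohort <- expression_cohort(values, sample_ids, feature_ids, labels,
                              survival, scale = "log2")
  dimnames(shift) <- list(feature_ids, lv)
  truth <- list(
    informative_features = lapply(informative, function(ix) feature_ids[ix]),
    multisubtype_features = feature_ids[multi],
    prognostic_features = setNames(beta, feature_ids[prognostic]),
    planted_shifts = shift[rowSums(shift != 0) > 0, , drop = FALSE])
  list(cohort = cohort, truth = truth)
}

# With T_i ~ Exp(h_i) and C ~ Exp(c) independent, P(censored_i) = c/(c+h_i);
# solve mean_i c/(c+h_i) = target for c on the log scale.
solve_censoring_rate <- function(hazard, target) {
  f <- function(logc) mean(exp(logc) / (exp(logc) + hazard)) - target
  exp(uniroot(f, lower = log(min(hazard)) - 20,
              upper = log(max(hazard)) + 20)$root)
}

#' Fraction of censored samples in a cohort
#'
#' @param cohort An [expression_cohort()] with survival records.
#' @return The fraction of samples with `event == 0`, in `[0, 1]`.
#' @export
realized_censoring <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.null(cohort$survival) || nrow(cohort$survival) == 0)
    stop_mirmark("cohort has no survival records", class = "cohort_error")
  mean(cohort$survival$event == 0)
}

#' Write generator ground truth as JSON
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
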