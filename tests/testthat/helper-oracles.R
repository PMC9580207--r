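# Independent oracles and fixture builders shared across tests.

# Small synthetic cohort for fast tests
small_cohort <- function(seed = 1, n_per = c(24, 16, 12, 16, 16),
                         n_features = 40, informative = 3, multi = 6,
                         effect = 2, n_prog = 3, beta = 1,
                         cens = 0.4) {
  generate_cohort(simulation_config(
    n_per_subtype = n_per, n_features = n_features,
    informative_per_subtype = informative, n_multisubtype_features = multi,
    effect_size = effect, noise_sd = 1, n_prognostic = n_prog,
    prognostic_beta = beta, baseline_hazard_rate = 0.1,
    censoring_rate_target = cens, seed = seed))
}

# Efron partial log-likelihood for a single covariate, brute force from the
# definition: events grouped by tied time, risk set = {time >= t}.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D]) -
      sum(vapply(0:(d - 1), function(l) log(sumR - (l / d) * sumD),
                 numeric(1)))
  }
  ll
}

# Grid/line-search maximizer of the Efron partial likelihood
efron_mle <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) efron_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Exhaustive nonzero-count oracle: triple loop over (model, feature, class)
count_frequencies_oracle <- function(models, zero_tol = 0) {
  W1 <- models[[1]]$coefficients
  counts <- matrix(0L, nrow(W1), ncol(W1), dimnames = dimnames(W1))
  for (m in seq_along(models))
    for (k in seq_len(nrow(W1)))
      for (j in seq_len(ncol(W1)))
        if (abs(models[[m]]$coefficients[k, j]) > zero_tol)
          counts[k, j] <- counts[k, j] + 1L
  counts
}

# Wrap raw coefficient matrices as a minimal ensemble_result
fake_ensemble <- function(coef_list, classes = subtype_levels()) {
  models <- lapply(coef_list, function(W) {
    colnames(W) <- classes[seq_len(ncol(W))]
    if (is.null(rownames(W))) rownames(W) <- paste0("f", seq_len(nrow(W)))
    structure(list(coefficients = W,
                   intercepts = rep(0, ncol(W)),
                   classes = colnames(W), alpha = 0.5, lambda = 0.1),
              class = "mlr_en")
  })
  structure(list(models = models, M = length(models),
                 classes = classes, split = NULL, vote_matrix = NULL),
            class = "ensemble_result")
}

# Independent ridge-penalized multinomial solver: BFGS with analytic
# gradient on the 1/n-scaled objective (no standardization).
ridge_multinomial_oracle <- function(x, y, lambda, reltol = 1e-14) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y); n <- nrow(x); p <- ncol(x)
  Y <- outer(as.character(y), levels(y), `==`) * 1
  unpack <- function(par) list(W = matrix(par[1:(p * K)], p, K),
                               b = par[p * K + 1:K])
  fn <- function(par) {
    th <- unpack(par)
    S <- sweep(x %*% th$W, 2, th$b, `+`)
    lse <- apply(S, 1, function(r) {m <- max(r); m + log(sum(exp(r - m)))})
    -(sum(S[cbind(1:n, match(y, levels(y)))] - lse)) / n +
      lambda * 0.5 * sum(th$W^2)
  }
  gr <- function(par) {
    th <- unpack(par)
    S <- sweep(x %*% th$W, 2, th$b, `+`)
    P <- exp(S - apply(S, 1, function(r) {m <- max(r); m + log(sum(exp(r - m)))}))
    GW <- crossprod(x, P - Y) / n + lambda * th$W
    gb <- colSums(P - Y) / n
    c(as.vector(GW), gb)
  }
  fit <- stats::optim(rep(0, p * K + K), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = reltol))
  th <- unpack(fit$par)
  colnames(th$W) <- levels(y)
  th
}

# Kaplan-Meier product-limit estimate at given times (no package calls)
km_oracle <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- function(tt) {
    s <- 1
    for (t in ut[ut <= tt]) {
      d <- sum(time == t & event == 1)
      r <- sum(time >= t)
      s <- s * (1 - d / r)
    }
    s
  }
  vapply(at, surv, numeric(1))
}
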