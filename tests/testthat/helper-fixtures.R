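# Shared fixture builders. Everything is generated in code at test time.

# Small study: fast to simulate, big enough for the statistical checks.
small_config <- function(seed = 3, ...) {
  synthetic_config(
    n_scenarios = 40, n_raters_per_scenario = 8, scenarios_per_rater = 20,
    n_participants = 20, trials_per_participant = 25,
    embedding_dim = 16, n_semantic_clusters = 5, seed = seed, ...
  )
}

# QC-exactness fixture: every rater rates every scenario with no rater bias,
# so honest rater-question means coincide and the 3-sigma outlier rule cannot
# fire naturally; agents are deterministic deciders with small biases and
# near-even weights (beta 4-6, |b| <= 0.2, w_cost 0.3-0.7) whose choice
# probabilities traverse several WTH bins, so nobody straight-lines naturally
# (verified clean over 40 generator seeds).
exact_qc_config <- function(seed = 11, n_scenarios = 40, n_raters = 12,
                            n_participants = 30) {
  synthetic_config(
    n_scenarios = n_scenarios, n_raters_per_scenario = n_raters,
    scenarios_per_rater = n_scenarios, n_participants = n_participants,
    trials_per_participant = n_scenarios,
    rating_noise_sd = 0, rater_bias_sd = 0,
    agent_param_dists = list(beta = c(4, 6), w_cost = c(0.3, 0.7),
                             b = c(-0.2, 0.2)),
    embedding_dim = 8, n_semantic_clusters = 4, seed = seed
  )
}

# Random scenario scores for model-level tests.
random_scores <- function(n = 100, seed = 1) {
  set.seed(seed)
  data.frame(cost = stats::runif(n), benefit = stats::runif(n),
             urgency = stats::rbinom(n, 1, 0.5))
}

# Independent per-trial loop oracle for the Bernoulli likelihood.
nll_loop_oracle <- function(params, data, model_id) {
  params <- as.list(params)
  total <- 0
  for (i in seq_len(nrow(data))) {
    u <- switch(model_id,
      "1.0" = params$b,
      "2.0" = -params$w_cost * data$cost[i] +
        (1 - params$w_cost) * data$benefit[i] + params$b,
      "3.0" = -params$w_cost * data$cost[i] +
        params$w_benefit * data$benefit[i] + params$b,
      "2.1" = -params$w_cost * data$cost[i]^params$alpha +
        (1 - params$w_cost) * data$benefit[i] + params$b,
      "2.2" = -params$w_cost * data$cost[i] +
        (1 - params$w_cost) * data$benefit[i]^params$alpha + params$b,
      "2.3" = -params$w_cost * data$cost[i] +
        (1 - params$w_cost) * data$benefit[i] +
        params$w_cb * data$cost[i] * data$benefit[i] + params$b,
      "2.4" = -params$w_cost * data$cost[i] +
        (1 - params$w_cost) * data$benefit[i] +
        params$w_u * data$urgency[i] + params$b
    )
    p <- 1 / (1 + exp(-params$beta * u))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    total <- total - (data$help[i] * log(p) + (1 - data$help[i]) * log(1 - p))
  }
  total
}

# Draw a random admissible parameter set for a model.
random_params <- function(model_id, seed) {
  set.seed(seed)
  spec <- model_spec(model_id)
  theta <- lapply(spec$params, function(b) stats::runif(1, b[1], b[2]))
  theta$beta <- stats::runif(1, 0.5, 6)
  theta
}

# Naive double-loop oracle for the decision-space dissimilarity.
decision_rdm_oracle <- function(wth) {
  ns <- ncol(wth)
  out <- matrix(0, ns, ns)
  for (x in seq_len(ns)) {
    for (y in seq_len(ns)) {
      joint <- which(!is.na(wth[, x]) & !is.na(wth[, y]))
      n <- length(joint)
      s_abs <- 0; s_sign <- 0
      for (i in joint) {
        d <- wth[i, x] - wth[i, y]
        s_abs <- s_abs + abs(d)
        s_sign <- s_sign + d
      }
      out[x, y] <- (0.5 * s_abs + 0.5 * abs(s_sign)) / n
    }
  }
  out
}

# Independent eigenvalue-comparison oracle for parallel analysis.
parallel_oracle <- function(X, n_sim, seed) {
  obs <- eigen(stats::cor(X), only.values = TRUE)$values
  set.seed(seed)
  sims <- replicate(n_sim, {
    eigen(stats::cor(matrix(stats::rnorm(nrow(X) * ncol(X)), nrow(X))),
          only.values = TRUE)$values
  })
  ref <- rowMeans(sims)
  n <- 0L
  for (j in seq_along(obs)) {
    if (obs[j] > ref[j]) n <- n + 1L else break
  }
  n
}
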