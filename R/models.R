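#' Utility model catalogue
#'
#' Seven candidate models of the subjective utility of helping. All models
#' share the softmax choice rule \eqn{P(help) = 1 / (1 + e^{-\beta U})} with
#' inverse temperature \eqn{\beta \in (0, 10]}; they differ in how the utility
#' U combines the scenario's normalized Cost and Benefit (both in \[0, 1\]),
#' a binary Urgency indicator, and a dispositional helping bias b:
#'
#' \describe{
#'   \item{1.0}{fixed bias: U = b}
#'   \item{2.0}{single weight: U = -w_cost Cost + (1 - w_cost) Benefit + b}
#'   \item{3.0}{double weight: U = -w_cost Cost + w_benefit Benefit + b}
#'   \item{2.1}{nonlinear cost: U = -w_cost Cost^alpha + (1 - w_cost) Benefit + b}
#'   \item{2.2}{nonlinear benefit: U = -w_cost Cost + (1 - w_cost) Benefit^alpha + b}
#'   \item{2.3}{interactive: model 2.0 plus w_cb Cost Benefit}
#'   \item{2.4}{urgency bonus: model 2.0 plus w_u Urgency}
#' }
#'
#' @param model_id one of "1.0", "2.0", "3.0", "2.1", "2.2", "2.3", "2.4".
#' @return a list with `model_id`, `params` (named parameter list with `lower`
#'   and `upper` bounds) and `k` (number of free parameters).
#' @export
model_spec <- function(model_id) {
  model_id <- as.character(model_id)
  bounds <- list(
    beta      = c(1e-6, 10),
    w_cost    = c(0, 1),
    w_benefit = c(0, 1),
    b         = c(-10, 10),
    alpha     = c(1e-6, 10),
    w_cb      = c(-5, 5),
    w_u       = c(0, 5)
  )
  pars <- switch(model_id,
    "1.0" = c("beta", "b"),
    "2.0" = c("beta", "w_cost", "b"),
    "3.0" = c("beta", "w_cost", "w_benefit", "b"),
    "2.1" = c("beta", "w_cost", "b", "alpha"),
    "2.2" = c("beta", "w_cost", "b", "alpha"),
    "2.3" = c("beta", "w_cost", "b", "w_cb"),
    "2.4" = c("beta", "w_cost", "b", "w_u"),
    stop(sprintf("unknown model_id '%s'", model_id), call. = FALSE)
  )
  list(
    model_id = model_id,
    params = bounds[pars],
    k = length(pars)
  )
}

#' Subjective utility of helping
#'
#' Evaluates the utility formula of one model for vectors of scenarios.
#'
#' @param model_id model identifier, see [model_spec()].
#' @param params named numeric vector/list with the model's parameters
#'   (the softmax `beta` may be present but is not used here).
#' @param cost,benefit normalized scenario scores in \[0, 1\].
#' @param urgency binary (0/1) urgency indicator, only used by model 2.4.
#' @return numeric vector of utilities.
#' @export
utility <- function(model_id, params, cost, benefit, urgency = 0) {
  model_id <- as.character(model_id)
  spec <- model_spec(model_id)
  params <- as.list(params)
  need <- setdiff(names(spec$params), "beta")
  missing <- need[!need %in% names(params)]
  if (length(missing) > 0) {
    stop(sprintf("utility: missing parameter(s) %s for model %s",
                 paste(missing, collapse = ", "), model_id), call. = FALSE)
  }
  if (model_id != "1.0") {
    if (any(cost < -1e-9 | cost > 1 + 1e-9) ||
        any(benefit < -1e-9 | benefit > 1 + 1e-9)) {
      stop("utility: cost/benefit must be within [0, 1]", call. = FALSE)
    }
  }
  b <- params$b
  switch(model_id,
    "1.0" = rep(b, length.out = max(length(cost), 1L)),
    "2.0" = -params$w_cost * cost + (1 - params$w_cost) * benefit + b,
    "3.0" = -params$w_cost * cost + params$w_benefit * benefit + b,
    "2.1" = -params$w_cost * cost^params$alpha +
            (1 - params$w_cost) * benefit + b,
    "2.2" = -params$w_cost * cost +
            (1 - params$w_cost) * benefit^params$alpha + b,
    "2.3" = -params$w_cost * cost + (1 - params$w_cost) * benefit +
            params$w_cb * cost * benefit + b,
    "2.4" = -params$w_cost * cost + (1 - params$w_cost) * benefit +
            params$w_u * urgency + b
  )
}

#' Softmax choice probability
#'
#' Logistic transform of the utility, numerically stable for large
#' \eqn{|\beta U|}.
#'
#' @param U utility (numeric vector).
#' @param beta inverse temperature in (0, 10].
#' @return probability of helping, strictly inside (0, 1) up to floating point.
#' @export
choice_prob <- function(U, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta > 10) {
    stop("choice_prob: beta must be a scalar in (0, 10]", call. = FALSE)
  }
  stats::plogis(beta * U)
}

#' Negative log-likelihood of binary helping decisions
#'
#' Bernoulli negative log-likelihood of observed help/not-help choices under
#' one utility model. Probabilities are clipped at 1e-12 so the value stays
#' finite under complete separation.
#'
#' @param params named numeric vector including `beta` and the utility
#'   parameters of `model_id`.
#' @param data data frame with columns `help` (0/1), `cost`, `benefit` and
#'   (for model 2.4) `urgency`.
#' @param model_id model identifier.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(params, data, model_id) {
  if (is.null(data) || nrow(data) == 0) {
    stop("neg_log_likelihood: empty data", call. = FALSE)
  }
  params <- as.list(params)
  U <- utility(model_id, params, data$cost, data$benefit,
               data$urgency %||% 0)
  p <- choice_prob(U, params$beta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- data$help
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# Latin-hypercube start values within the box bounds of a model.
lhs_starts <- function(spec, n_restarts, seed) {
  set.seed(seed)
  grid <- lhs::randomLHS(n_restarts, spec$k)
  colnames(grid) <- names(spec$params)
  for (p in names(spec$params)) {
    lo <- spec$params[[p]][1]
    hi <- spec$params[[p]][2]
    # keep starts off the very edges of open bounds
    grid[, p] <- lo + (0.02 + 0.96 * grid[, p]) * (hi - lo)
  }
  grid
}

#' Fit one participant's decisions by maximum likelihood
#'
#' Bounded quasi-Newton optimization (L-BFGS-B) of the Bernoulli likelihood
#' from multiple Latin-hypercube starting points; the best (lowest) negative
#' log-likelihood wins, ties broken by the smallest parameter norm.
#'
#' @param data data frame of one participant's trials with columns `help`,
#'   `cost`, `benefit` and optionally `urgency`.
#' @param model_id model identifier.
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed for the restart draw.
#' @param participant_id optional identifier stored in the result.
#' @return an object of class `helpcb_fit`: a list with parameter estimates,
#'   `logLik`, `pseudo_R2`, `AIC`, `BIC`, `n_trials`, `n_restarts_used`,
#'   `converged` and a `low_data` flag (fewer than k + 5 trials).
#' @export
fit_participant <- function(data, model_id, n_restarts = 10, seed = 1,
                            participant_id = NA_character_) {
  spec <- model_spec(model_id)
  if (is.null(data) || nrow(data) == 0) {
    stop("fit_participant: empty data", call. = FALSE)
  }
  starts <- lhs_starts(spec, n_restarts, seed)
  lower <- vapply(spec$params, `[`, numeric(1), 1)
  upper <- vapply(spec$params, `[`, numeric(1), 2)
  obj <- function(theta) {
    names(theta) <- names(spec$params)
    neg_log_likelihood(theta, data, model_id)
  }
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         sum(fit$par^2) < sum(best$par^2))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop(sprintf("fit_participant: all %d restarts failed for model %s",
                 n_restarts, model_id), call. = FALSE)
  }
  est <- as.list(best$par)
  names(est) <- names(spec$params)
  ll <- -best$value
  n <- nrow(data)
  out <- c(
    list(participant_id = participant_id, model_id = model_id),
    est,
    diagnostics(ll, spec$k, n),
    list(
      logLik = ll,
      n_trials = n,
      n_restarts_used = n_ok,
      converged = best$convergence == 0,
      low_data = n < spec$k + 5
    )
  )
  class(out) <- "helpcb_fit"
  out
}

#' @export
print.helpcb_fit <- function(x, ...) {
  cat(sprintf("<helpcb_fit> model %s, participant %s\n",
              x$model_id, x$participant_id))
  pars <- model_spec(x$model_id)$params
  est <- unlist(x[names(pars)])
  cat("  parameters:",
      paste(sprintf("%s = %.3f", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  logLik %.3f | pseudo-R2 %.3f | AIC %.2f | BIC %.2f | n %d\n",
              x$logLik, x$pseudo_R2, x$AIC, x$BIC, x$n_trials))
  invisible(x)
}

#' Model-fit diagnostics
#'
#' Pseudo-R2 against a coin-flip (p = 0.5) null so that every model, including
#' the bias-only model, has a defined value; AIC and BIC from the maximized
#' log-likelihood.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of trials.
#' @return list with `pseudo_R2`, `AIC`, `BIC`.
#' @export
diagnostics <- function(logLik, k, n) {
  ll_chance <- n * log(0.5)
  list(
    pseudo_R2 = 1 - logLik / ll_chance,
    AIC = 2 * k - 2 * logLik,
    BIC = k * log(n) - 2 * logLik
  )
}

#' Leave-one-out prediction accuracy
#'
#' For every trial: refit the model on the remaining trials, predict the
#' held-out choice as "help" iff the predicted probability is at least the
#' tie threshold (default 0.5, ties predicting help), and average the hits.
#'
#' @param data one participant's trials (see [fit_participant()]).
#' @param model_id model identifier.
#' @param n_restarts restarts per refit (default 5; each fold is a small,
#'   well-conditioned problem).
#' @param seed integer seed.
#' @param tie equal-probability prediction, "help" (default) or "nothelp".
#' @return mean out-of-sample accuracy in \[0, 1\].
#' @export
loo_accuracy <- function(data, model_id, n_restarts = 5, seed = 1,
                         tie = c("help", "nothelp")) {
  tie <- match.arg(tie)
  spec <- model_spec(model_id)
  n <- nrow(data)
  if (n < spec$k + 6) {
    stop("loo_accuracy: too few trials for leave-one-out refits", call. = FALSE)
  }
  urg <- data$urgency %||% rep(0, n)
  hits <- logical(0)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_participant(data[-i, , drop = FALSE], model_id,
                      n_restarts = n_restarts, seed = seed + i),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning(sprintf("loo_accuracy: fold %d refit failed, skipped", i))
      next
    }
    pars <- fit[names(spec$params)]
    U <- utility(model_id, pars, data$cost[i], data$benefit[i], urg[i])
    p <- choice_prob(U, fit$beta)
    pred <- if (tie == "help") as.integer(p >= 0.5) else as.integer(p > 0.5)
    hits <- c(hits, pred == data$help[i])
  }
  mean(hits)
}

#' Fit a set of participants under a set of models
#'
#' @param data decision data frame with `participant_id`, `help`, `cost`,
#'   `benefit`, optionally `urgency` and `wth_code`.
#' @param model_ids character vector of model identifiers.
#' @param n_restarts,seed passed to [fit_participant()].
#' @param loo if TRUE also compute leave-one-out accuracy per fit (slow).
#' @return data frame, one row per participant x model.
#' @export
fit_all <- function(data, model_ids = c("1.0", "2.0", "3.0",
                                        "2.1", "2.2", "2.3", "2.4"),
                    n_restarts = 10, seed = 1, loo = FALSE) {
  ids <- unique(data$participant_id)
  rows <- list()
  for (m in model_ids) {
    spec <- model_spec(m)
    for (pid in ids) {
      d <- data[data$participant_id == pid, , drop = FALSE]
      fit <- fit_participant(d, m, n_restarts = n_restarts,
                             seed = sub_seed(seed, match(pid, ids)),
                             participant_id = pid)
      row <- data.frame(
        participant_id = pid, model_id = m,
        beta = fit$beta, w_cost = fit$w_cost %||% NA_real_,
        w_benefit = fit$w_benefit %||% NA_real_, b = fit$b,
        alpha = fit$alpha %||% NA_real_, w_cb = fit$w_cb %||% NA_real_,
        w_u = fit$w_u %||% NA_real_,
        logLik = fit$logLik, pseudo_R2 = fit$pseudo_R2,
        AIC = fit$AIC, BIC = fit$BIC, n_trials = fit$n_trials,
        converged = fit$converged, low_data = fit$low_data,
        stringsAsFactors = FALSE
      )
      if (loo) {
        row$loo_accuracy <- loo_accuracy(d, m, seed = sub_seed(seed, 7000))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Group-level model comparison
#'
#' Mean and standard error of AIC, BIC, pseudo-R2 (and LOO accuracy when
#' present) per model, with a best-model flag per criterion (lowest mean
#' AIC/BIC; highest pseudo-R2/accuracy).
#'
#' @param fits data frame from [fit_all()] covering every participant under
#'   every model.
#' @return data frame, one row per model.
#' @export
compare_models <- function(fits) {
  models <- unique(fits$model_id)
  ids <- unique(fits$participant_id)
  counts <- table(fits$model_id)
  if (any(counts != length(ids))) {
    gaps <- names(counts)[counts != length(ids)]
    stop(sprintf("compare_models: incomplete fits for model(s) %s",
                 paste(gaps, collapse = ", ")), call. = FALSE)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- do.call(rbind, lapply(models, function(m) {
    f <- fits[fits$model_id == m, ]
    out <- data.frame(
      model_id = m,
      mean_AIC = mean(f$AIC), se_AIC = se(f$AIC),
      mean_BIC = mean(f$BIC), se_BIC = se(f$BIC),
      mean_pseudo_R2 = mean(f$pseudo_R2), se_pseudo_R2 = se(f$pseudo_R2),
      stringsAsFactors = FALSE
    )
    if ("loo_accuracy" %in% names(f)) {
      out$mean_loo_accuracy <- mean(f$loo_accuracy)
      out$se_loo_accuracy <- se(f$loo_accuracy)
    }
    out
  }))
  agg$best_AIC <- agg$mean_AIC == min(agg$mean_AIC)
  agg$best_BIC <- agg$mean_BIC == min(agg$mean_BIC)
  agg$best_pseudo_R2 <- agg$mean_pseudo_R2 == max(agg$mean_pseudo_R2)
  if ("mean_loo_accuracy" %in% names(agg)) {
    agg$best_loo <- agg$mean_loo_accuracy == max(agg$mean_loo_accuracy)
  }
  agg
}

#' Simulate choices from a known parameterization
#'
#' Forward run of one utility model: computes the softmax probability per
#' scenario and draws Bernoulli choices.
#'
#' @param model_id model identifier.
#' @param params named parameter vector/list including `beta`.
#' @param scores data frame with `cost`, `benefit` and optionally `urgency`.
#' @param seed integer seed.
#' @return `scores` with added `U`, `p_help`, `help` columns.
#' @export
simulate_choices <- function(model_id, params, scores, seed = 1) {
  params <- as.list(params)
  U <- utility(model_id, params, scores$cost, scores$benefit,
               scores$urgency %||% 0)
  p <- choice_prob(U, params$beta)
  set.seed(seed)
  scores$U <- U
  scores$p_help <- p
  scores$help <- as.integer(stats::runif(nrow(scores)) < p)
  scores
}

# Draw one set of generating parameters uniformly within ranges.
draw_params <- function(spec, ranges) {
  theta <- vapply(names(spec$params), function(p) {
    r <- ranges[[p]] %||% spec$params[[p]]
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  as.list(theta)
}

#' Parameter-recovery simulation
#'
#' Draws sets of generating parameters, simulates one dataset per set, refits
#' the model, and correlates generating with recovered values per parameter.
#' The whole procedure is repeated `n_reps` times; per-repetition and pooled
#' correlations are returned.
#'
#' @param model_id model identifier.
#' @param scores scenario scores (`cost`, `benefit`, optionally `urgency`);
#'   each simulated dataset samples `n_trials` of these without replacement.
#' @param n_sets parameter sets per repetition (default 100).
#' @param n_reps repetitions (default 10).
#' @param n_trials trials per simulated participant (default 50).
#' @param param_ranges named list of c(min, max) sampling ranges; defaults to
#'   beta in \[1, 5\], w_cost in \[0.1, 0.9\], b in \[-1, 1\], and the full
#'   box for any other parameter.
#' @param n_restarts,seed fitting controls.
#' @return list of class `helpcb_recovery` with `per_rep` (matrix reps x
#'   parameters) and `pooled` (named vector) Pearson correlations; a parameter
#'   drawn with zero variance is reported as NA.
#' @export
parameter_recovery <- function(model_id, scores, n_sets = 100, n_reps = 10,
                               n_trials = 50,
                               param_ranges = list(beta = c(1, 5),
                                                   w_cost = c(0.1, 0.9),
                                                   b = c(-1, 1)),
                               n_restarts = 10, seed = 1) {
  spec <- model_spec(model_id)
  pnames <- names(spec$params)
  per_rep <- matrix(NA_real_, n_reps, spec$k, dimnames = list(NULL, pnames))
  sim_all <- rec_all <- NULL
  for (rep in seq_len(n_reps)) {
    set.seed(sub_seed(seed, 1000 * rep))
    sim <- matrix(NA_real_, n_sets, spec$k, dimnames = list(NULL, pnames))
    rec <- sim
    for (s in seq_len(n_sets)) {
      theta <- draw_params(spec, param_ranges)
      sim[s, ] <- unlist(theta)[pnames]
      idx <- sample.int(nrow(scores), n_trials, replace = n_trials > nrow(scores))
      d <- simulate_choices(model_id, theta, scores[idx, , drop = FALSE],
                            seed = sub_seed(seed, 1000 * rep + s))
      fit <- fit_participant(d, model_id, n_restarts = n_restarts,
                             seed = sub_seed(seed, 5e5 + 1000 * rep + s))
      rec[s, ] <- unlist(fit[pnames])
    }
    for (p in pnames) {
      if (stats::sd(sim[, p]) > 0) {
        per_rep[rep, p] <- stats::cor(sim[, p], rec[, p])
      }
    }
    sim_all <- rbind(sim_all, sim)
    rec_all <- rbind(rec_all, rec)
  }
  pooled <- vapply(pnames, function(p) {
    if (stats::sd(sim_all[, p]) > 0) stats::cor(sim_all[, p], rec_all[, p])
    else NA_real_
  }, numeric(1))
  structure(
    list(model_id = model_id, per_rep = per_rep, pooled = pooled,
         n_sets = n_sets, n_reps = n_reps, n_trials = n_trials),
    class = "helpcb_recovery"
  )
}

#' @export
print.helpcb_recovery <- function(x, ...) {
  cat(sprintf("<helpcb_recovery> model %s: %d sets x %d reps, %d trials\n",
              x$model_id, x$n_sets, x$n_reps, x$n_trials))
  cat("  pooled r(true, recovered):",
      paste(sprintf("%s = %.3f", names(x$pooled), x$pooled), collapse = ", "),
      "\n")
  invisible(x)
}

#' Continuous rating model (robustness check)
#'
#' Refits a utility model to the ordinal willingness-to-help codes (-5..5)
#' instead of the binary choices: the predicted rating is `scale * U` (no
#' softmax) and the parameters, including the positive scaling factor,
#' minimize the mean squared error against the observed codes.
#'
#' @param data data frame with `wth_code`, `cost`, `benefit`, optionally
#'   `urgency`.
#' @param model_id model identifier.
#' @param n_restarts,seed optimization controls.
#' @return list with estimated parameters (incl. `scale`), `mse`, `n_trials`
#'   and a `degenerate` flag (zero-variance ratings).
#' @export
fit_rating_model <- function(data, model_id, n_restarts = 10, seed = 1) {
  spec <- model_spec(model_id)
  upars <- setdiff(names(spec$params), "beta")
  lower <- c(scale = 1e-6,
             vapply(spec$params[upars], `[`, numeric(1), 1))
  upper <- c(scale = 20,
             vapply(spec$params[upars], `[`, numeric(1), 2))
  names(lower) <- names(upper) <- c("scale", upars)
  degenerate <- stats::sd(data$wth_code) == 0
  obj <- function(theta) {
    names(theta) <- c("scale", upars)
    U <- utility(model_id, as.list(theta), data$cost, data$benefit,
                 data$urgency %||% 0)
    mean((theta[["scale"]] * U - data$wth_code)^2)
  }
  set.seed(seed)
  grid <- lhs::randomLHS(n_restarts, length(lower))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    start <- lower + (0.02 + 0.96 * grid[i, ]) * (upper - lower)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("fit_rating_model: optimization failed", call. = FALSE)
  est <- as.list(best$par)
  names(est) <- c("scale", upars)
  c(est, list(mse = best$value, model_id = model_id,
              n_trials = nrow(data), degenerate = degenerate))
}
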