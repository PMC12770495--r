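test_that("utility formulas match hand evaluations", {
  expect_equal(utility("2.0", list(w_cost = 0.5, b = 0), 0.4, 0.4), 0)
  expect_equal(utility("2.0", list(w_cost = 0.3, b = 0.1), 0.2, 0.8), 0.60)
  expect_equal(
    utility("2.4", list(w_cost = 0.4, b = 0, w_u = 0.3), 0.5, 0.5, urgency = 1),
    0.40
  )
  expect_equal(
    utility("2.4", list(w_cost = 0.4, b = 0, w_u = 0.3), 0.5, 0.5, urgency = 0),
    0.10
  )
  expect_equal(utility("1.0", list(b = 1.7), 0.2, 0.9), 1.7)
})

test_that("utility validates inputs", {
  expect_error(utility("2.0", list(b = 0), 0.5, 0.5), "missing parameter")
  expect_error(utility("2.0", list(w_cost = 0.5, b = 0), 1.5, 0.5),
               "within \\[0, 1\\]")
  expect_error(utility("9.9", list(b = 0), 0.5, 0.5), "unknown model")
})

test_that("model catalogue has the documented parameter counts", {
  ks <- c("1.0" = 2, "2.0" = 3, "3.0" = 4, "2.1" = 4, "2.2" = 4,
          "2.3" = 4, "2.4" = 4)
  for (m in names(ks)) expect_equal(model_spec(m)$k, unname(ks[m]))
})

test_that("softmax choice probability is correct and saturates stably", {
  expect_equal(choice_prob(0, 5), 0.5)
  expect_equal(choice_prob(0.5, 2), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(choice_prob(1e6, 10), 1)
  expect_equal(choice_prob(-1e6, 10), 0)
  expect_error(choice_prob(0, 0), "scalar in")
  expect_error(choice_prob(0, 11), "scalar in")
})

test_that("model 2.0 utility is monotone in cost and benefit", {
  grid <- seq(0, 1, length.out = 25)
  for (w in c(0.2, 0.5, 0.8)) {
    u_cost <- utility("2.0", list(w_cost = w, b = 0.3), grid, 0.5)
    u_ben <- utility("2.0", list(w_cost = w, b = 0.3), 0.5, grid)
    expect_true(all(diff(u_cost) < 0))
    expect_true(all(diff(u_ben) > 0))
  }
})

test_that("nesting identities reproduce model 2.0 exactly on a grid", {
  set.seed(42)
  n <- 1000
  cost <- runif(n); benefit <- runif(n); urg <- rbinom(n, 1, 0.5)
  base <- list(w_cost = 0.37, b = -0.21)
  u0 <- utility("2.0", base, cost, benefit)
  expect_equal(max(abs(utility("2.1", c(base, alpha = 1), cost, benefit) - u0)), 0)
  expect_equal(max(abs(utility("2.2", c(base, alpha = 1), cost, benefit) - u0)), 0)
  expect_equal(max(abs(utility("2.3", c(base, w_cb = 0), cost, benefit) - u0)), 0)
  expect_equal(max(abs(utility("2.4", c(base, w_u = 0), cost, benefit, urg) - u0)), 0)
})

test_that("vectorized likelihood equals the per-trial loop oracle", {
  models <- c("1.0", "2.0", "3.0", "2.1", "2.2", "2.3", "2.4")
  for (rep in 1:20) {
    m <- models[(rep - 1) %% 7 + 1]
    theta <- random_params(m, seed = 100 + rep)
    set.seed(200 + rep)
    d <- data.frame(cost = runif(15), benefit = runif(15),
                    urgency = rbinom(15, 1, 0.5), help = rbinom(15, 1, 0.5))
    expect_equal(neg_log_likelihood(theta, d, m),
                 nll_loop_oracle(theta, d, m), tolerance = 1e-10)
  }
})

test_that("likelihood handles the textbook cases", {
  d <- data.frame(cost = rep(0.5, 10), benefit = rep(0.5, 10),
                  help = rep(1, 10))
  # U = 0 under symmetric weights and b = 0 => P = 0.5 per trial
  expect_equal(neg_log_likelihood(list(beta = 2, w_cost = 0.5, b = 0), d, "2.0"),
               10 * log(2), tolerance = 1e-12)
  # saturation: all-help with a huge positive bias
  expect_lt(neg_log_likelihood(list(beta = 10, b = 10), d, "1.0"), 1e-3)
  expect_error(neg_log_likelihood(list(beta = 2, b = 0), d[0, ], "1.0"),
               "empty data")
})

test_that("maximum-likelihood fit agrees with the logistic-GLM oracle", {
  # model 2.0 is a reparameterized logistic regression:
  # logit P = beta*b + beta*(1-w_cost)*benefit - beta*w_cost*cost,
  # so beta = coef_benefit - coef_cost, w_cost = -coef_cost / beta.
  scores <- random_scores(100, seed = 1)
  d <- simulate_choices("2.0", list(beta = 3, w_cost = 0.7, b = 0.2),
                        scores[sample(1:100, 500, replace = TRUE), ], seed = 2)
  fit <- fit_participant(d, "2.0", seed = 5)
  glm_fit <- glm(help ~ benefit + cost, family = binomial(), data = d)
  cf <- coef(glm_fit)
  beta_hat <- unname(cf["benefit"] - cf["cost"])
  w_hat <- unname(-cf["cost"] / beta_hat)
  b_hat <- unname(cf["(Intercept)"] / beta_hat)
  expect_equal(fit$beta, beta_hat, tolerance = 1e-2)
  expect_equal(fit$w_cost, w_hat, tolerance = 1e-2)
  expect_equal(fit$b, b_hat, tolerance = 1e-2)
  expect_lte(-fit$logLik, -as.numeric(logLik(glm_fit)) + 1e-4)
  # the generating parameters are inside 3 glm standard errors
  se <- sqrt(diag(vcov(glm_fit)))
  expect_lt(abs(cf["cost"] - (-3 * 0.7)), 3 * se["cost"])
  expect_lt(abs(cf["benefit"] - 3 * 0.3), 3 * se["benefit"])
})

test_that("refits from different restart seeds reach the same optimum", {
  scores <- random_scores(60, seed = 3)
  d <- simulate_choices("2.0", list(beta = 2.5, w_cost = 0.4, b = 0.1),
                        scores, seed = 4)
  f1 <- fit_participant(d, "2.0", seed = 11)
  f2 <- fit_participant(d, "2.0", seed = 97)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("an all-help participant saturates the bias-only model", {
  d <- data.frame(cost = runif(30), benefit = runif(30), help = rep(1L, 30))
  fit <- fit_participant(d, "1.0", seed = 2)
  # complete separation: the likelihood plateaus with P(help) ~ 1, the bias
  # pushed far into the saturated region
  expect_gt(fit$b, 2)
  expect_gt(choice_prob(fit$b, fit$beta), 0.999)
  expect_lt(-fit$logLik, 0.1)
})

test_that("diagnostics implement the stated formulas", {
  dg <- diagnostics(logLik = -20, k = 3, n = 50)
  expect_equal(dg$AIC, 46)
  expect_equal(dg$BIC, 3 * log(50) + 40)
  expect_equal(diagnostics(50 * log(0.5), 2, 50)$pseudo_R2, 0)
  # extra parameter: same LL => BIC penalty grows by exactly ln(n)
  expect_equal(diagnostics(-20, 4, 50)$BIC - dg$BIC, log(50))
})

test_that("leave-one-out accuracy matches an explicit-loop reimplementation", {
  scores <- random_scores(20, seed = 6)
  d <- simulate_choices("2.0", list(beta = 4, w_cost = 0.3, b = 0.3),
                        scores, seed = 7)
  got <- loo_accuracy(d, "2.0", n_restarts = 3, seed = 9)
  naive <- mean(vapply(seq_len(nrow(d)), function(i) {
    f <- fit_participant(d[-i, ], "2.0", n_restarts = 3, seed = 9 + i)
    u <- utility("2.0", f[c("w_cost", "b")], d$cost[i], d$benefit[i])
    (choice_prob(u, f$beta) >= 0.5) == (d$help[i] == 1)
  }, logical(1)))
  expect_equal(got, naive)
})

test_that("deterministic choices give perfect leave-one-out accuracy", {
  # wide utility margin and maximal inverse temperature
  d <- data.frame(cost = rep(c(0.05, 0.95), each = 8),
                  benefit = rep(c(0.95, 0.05), each = 8),
                  help = rep(c(1L, 0L), each = 8))
  expect_equal(loo_accuracy(d, "2.0", n_restarts = 4, seed = 3), 1.0)
})

test_that("model comparison flags the generating model's scores", {
  fits <- data.frame(
    participant_id = rep(c("a", "b"), 2),
    model_id = rep(c("1.0", "2.0"), each = 2),
    AIC = c(100, 110, 90, 95), BIC = c(105, 115, 96, 101),
    pseudo_R2 = c(0.1, 0.12, 0.3, 0.28)
  )
  cmp <- compare_models(fits)
  expect_equal(cmp$model_id[cmp$best_BIC], "2.0")
  expect_equal(cmp$model_id[cmp$best_pseudo_R2], "2.0")
  expect_error(compare_models(fits[-1, ]), "incomplete fits")
})

test_that("identical fits with equal k produce identical AIC and BIC", {
  d1 <- diagnostics(-33.3, 4, 60)
  d2 <- diagnostics(-33.3, 4, 60)
  expect_identical(d1$AIC, d2$AIC)
  expect_identical(d1$BIC, d2$BIC)
})

test_that("rating model recovers a planted scale and parameters", {
  scores <- random_scores(80, seed = 12)
  theta <- list(w_cost = 0.6, b = 0.4)
  U <- utility("2.0", theta, scores$cost, scores$benefit)
  d <- scores
  d$wth_code <- 2 * U
  fit <- fit_rating_model(d, "2.0", seed = 8)
  expect_lt(fit$mse, 1e-6)
  expect_equal(fit$scale, 2, tolerance = 1e-2)
  expect_equal(fit$w_cost, 0.6, tolerance = 1e-2)
  expect_false(fit$degenerate)
})

test_that("bias-only rating model reduces to a least-squares constant", {
  set.seed(5)
  d <- data.frame(cost = runif(40), benefit = runif(40),
                  wth_code = rnorm(40, 1, 2))
  fit <- fit_rating_model(d, "1.0", seed = 2)
  # optimum prediction is the mean rating; MSE is the (biased) variance
  expect_equal(fit$scale * fit$b, mean(d$wth_code), tolerance = 1e-3)
  expect_equal(fit$mse, mean((d$wth_code - mean(d$wth_code))^2),
               tolerance = 1e-6)
})

test_that("rating-model w_cost tracks the decision-model w_cost across agents", {
  scores <- random_scores(60, seed = 21)
  set.seed(22)
  w_true <- runif(12, 0.1, 0.9)
  w_dec <- w_rat <- numeric(12)
  for (i in seq_along(w_true)) {
    d <- simulate_choices("2.0", list(beta = 4, w_cost = w_true[i], b = 0.2),
                          scores, seed = 30 + i)
    d$wth_code <- code_wth(helpcb:::wth_level_from_p(d$p_help, d$help))$wth_code
    w_dec[i] <- fit_participant(d, "2.0", n_restarts = 5, seed = i)$w_cost
    w_rat[i] <- fit_rating_model(d, "2.0", n_restarts = 5, seed = i)$w_cost
  }
  expect_gt(cor(w_dec, w_rat), 0.7)
})
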