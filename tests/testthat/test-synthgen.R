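test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_scenarios = 0), "n_scenarios")
  expect_error(synthetic_config(trials_per_participant = 101), "exceeds")
  expect_error(synthetic_config(loading_matrix = matrix(0, 3, 2)),
               "12 x 2")
  expect_error(synthetic_config(rating_noise_sd = -1), ">= 0")
  expect_error(
    synthetic_config(trait_param_corr = data.frame(
      param = "b", trait = "svo", rho = 1)),
    "rho"
  )
})

test_that("scenario generation is deterministic and partitions clusters", {
  cfg <- synthetic_config(seed = 1)
  s1 <- gen_scenarios(cfg)
  s2 <- gen_scenarios(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_equal(length(unique(s1$cluster_id)), 14)
  expect_equal(sum(table(s1$cluster_id)), 100)
  one <- gen_scenarios(synthetic_config(n_semantic_clusters = 1, seed = 2))
  expect_true(all(one$cluster_id == 1))
})

test_that("whole-study generation is reproducible byte for byte", {
  cfg <- small_config(seed = 8)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
})

test_that("noiseless ratings are identical across raters of a scenario", {
  cfg <- small_config(seed = 4, rating_noise_sd = 0, rater_bias_sd = 0)
  scen <- gen_scenarios(cfg)
  rat <- gen_motivation_ratings(scen, cfg)
  rat <- rat[rat$attention_item == 0, ]
  for (q in c("q01", "q05", "q09")) {
    spread <- tapply(rat[[q]], rat$scenario_id, function(x) max(x) - min(x))
    expect_true(all(spread == 0))
  }
})

test_that("every scenario reaches the configured rater count", {
  cfg <- synthetic_config(n_scenarios = 100, n_raters_per_scenario = 25,
                          n_participants = 5, seed = 6)
  rat <- gen_motivation_ratings(gen_scenarios(cfg), cfg)
  counts <- table(rat$scenario_id[rat$attention_item == 0])
  expect_true(all(counts >= 25))
})

test_that("consensus of factor-1 questions tracks the latent benefit", {
  cfg <- synthetic_config(seed = 5, n_participants = 5)
  scen <- gen_scenarios(cfg)
  rat <- gen_motivation_ratings(scen, cfg)
  rat <- rat[rat$attention_item == 0, ]
  for (q in c("q01", "q03", "q06")) {
    cons <- tapply(rat[[q]], rat$scenario_id, mean)
    expect_gt(cor(cons[scen$scenario_id], scen$benefit_true), 0.9)
  }
  cons5 <- tapply(rat$q05, rat$scenario_id, mean)
  expect_gt(cor(cons5[scen$scenario_id], scen$cost_true), 0.9)
})

test_that("trait coupling hits the target correlation at large n", {
  cfg <- synthetic_config(
    n_participants = 2000, seed = 9,
    trait_param_corr = data.frame(param = "b", trait = "bfi_agreeableness",
                                  rho = 0.5))
  ag <- gen_agents(cfg)
  expect_equal(cor(ag$agents$b, ag$traits$bfi_agreeableness), 0.5,
               tolerance = 0.05)
})

test_that("zero coupling leaves traits independent of parameters", {
  cfg <- synthetic_config(
    n_participants = 2000, seed = 9,
    trait_param_corr = data.frame(param = character(0), trait = character(0),
                                  rho = numeric(0)))
  ag <- gen_agents(cfg)
  cors <- cor(ag$agents[, c("beta", "w_cost", "b")],
              ag$traits[, c("iri_ec", "svo", "rr", "bis",
                            "bfi_agreeableness")])
  expect_lt(max(abs(cors)), 0.1)
})

test_that("a point-mass parameter distribution is honored", {
  cfg <- small_config(seed = 2,
                      agent_param_dists = list(beta = c(1, 5),
                                               w_cost = c(0.5, 0.5),
                                               b = c(-1, 1)))
  ag <- gen_agents(cfg)
  expect_true(all(ag$agents$w_cost == 0.5))
  expect_true(all(ag$agents$beta > 0 & ag$agents$beta <= 10))
})

test_that("an infeasible coupling matrix is rejected", {
  bad <- data.frame(param = c("b", "b", "w_cost"),
                    trait = c("svo", "rr", "svo"),
                    rho = c(0.99, 0.99, -0.99))
  expect_error(gen_agents(small_config(trait_param_corr = bad)),
               "positive semi-definite")
})

test_that("saturated agents always help and symmetric agents split evenly", {
  cfg <- small_config(seed = 7,
                      agent_param_dists = list(beta = c(10, 10),
                                               w_cost = c(0, 0),
                                               b = c(5, 5)))
  st <- simulate_study(cfg)
  main <- st$decisions[st$decisions$attention_item == 0, ]
  expect_true(all(main$help_true == 1))
  expect_true(all(main$wth_level >= 4))

  cfg2 <- synthetic_config(
    n_scenarios = 100, n_participants = 20, trials_per_participant = 100,
    n_raters_per_scenario = 2, embedding_dim = 4, n_semantic_clusters = 2,
    seed = 17,
    agent_param_dists = list(beta = c(2, 2), w_cost = c(0.5, 0.5),
                             b = c(0, 0)))
  scen2 <- gen_scenarios(cfg2)
  # force Cost = Benefit so U = 0 on every trial
  scen2$cost_true <- scen2$benefit_true
  dec <- gen_decisions(gen_agents(cfg2)$agents, scen2, cfg2)
  main2 <- dec[dec$attention_item == 0 & dec$repeat_tag == "", ]
  expect_true(all(main2$p_help == 0.5))
  expect_equal(mean(main2$help_true), 0.5, tolerance = 0.04)
})

test_that("binary decisions match a brute-force replay of the seed stream", {
  cfg <- synthetic_config(n_scenarios = 30, n_participants = 5,
                          trials_per_participant = 20, embedding_dim = 4,
                          n_semantic_clusters = 2, seed = 13)
  scen <- gen_scenarios(cfg)
  ag <- gen_agents(cfg)$agents
  dec <- gen_decisions(ag, scen, cfg)
  C <- min_max(scen$cost_true); B <- min_max(scen$benefit_true)
  for (a in seq_len(nrow(ag))) {
    set.seed(helpcb:::sub_seed(13, 404 + a))
    idx <- sample.int(30, 20)
    U <- -ag$w_cost[a] * C[idx] + (1 - ag$w_cost[a]) * B[idx] + ag$b[a]
    p <- 1 / (1 + exp(-ag$beta[a] * U))
    h <- as.integer(runif(20) < p)
    got <- dec[dec$participant_id == ag$participant_id[a] &
                 dec$repeat_tag == "" & dec$attention_item == 0, ]
    expect_identical(got$help_true, h)
    expect_identical(got$scenario_id, scen$scenario_id[idx])
  }
})

test_that("ordinal levels are consistent with the binary decision", {
  st <- simulate_study(small_config(seed = 19))
  main <- st$decisions[st$decisions$attention_item == 0, ]
  expect_true(all((main$wth_level >= 4) == (main$help_true == 1)))
})

test_that("empirical help frequency converges to the softmax mean", {
  cfg <- synthetic_config(
    n_scenarios = 100, n_participants = 2, trials_per_participant = 100,
    n_raters_per_scenario = 2, embedding_dim = 4, n_semantic_clusters = 2,
    seed = 23)
  scen <- gen_scenarios(cfg)
  ag <- gen_agents(cfg)$agents
  # 10000 trials via 100 independent replays of the scenario set
  scores <- data.frame(cost = min_max(scen$cost_true),
                       benefit = min_max(scen$benefit_true))
  theta <- list(beta = ag$beta[1], w_cost = ag$w_cost[1], b = ag$b[1])
  sims <- do.call(rbind, lapply(1:100, function(r) {
    simulate_choices("2.0", theta, scores, seed = 1000 + r)
  }))
  mc_se <- sqrt(mean(sims$p_help * (1 - sims$p_help)) / nrow(sims))
  expect_lt(abs(mean(sims$help) - mean(sims$p_help)), 3 * mc_se)
})

test_that("a pure cost-weighter helps less as cost rises", {
  cfg <- synthetic_config(
    n_scenarios = 100, n_participants = 1, trials_per_participant = 100,
    n_raters_per_scenario = 2, embedding_dim = 4, n_semantic_clusters = 2,
    seed = 29,
    agent_param_dists = list(beta = c(5, 5), w_cost = c(1, 1), b = c(0.5, 0.5)))
  scen <- gen_scenarios(cfg)
  scores <- data.frame(cost = min_max(scen$cost_true),
                       benefit = min_max(scen$benefit_true))
  sims <- do.call(rbind, lapply(1:5, function(r) {
    simulate_choices("2.0", list(beta = 5, w_cost = 1, b = 0.5),
                     scores, seed = 40 + r)
  }))
  ter <- cut(sims$cost, quantile(sims$cost, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  rates <- tapply(sims$help, ter, mean)
  expect_true(rates["lo"] > rates["mid"] && rates["mid"] > rates["hi"])
})

test_that("planted violations are written as specified", {
  st <- simulate_study(small_config(seed = 31),
                       violations = list(s1_straightline = 4))
  sl <- st$truth$participants$participant_id
  expect_length(sl, 4)
  for (pid in sl) {
    d <- st$decisions[st$decisions$participant_id == pid &
                        st$decisions$attention_item == 0, ]
    expect_lt(sd(d$wth_level), 0.5)
  }
  clean <- simulate_study(small_config(seed = 31), violations = list())
  expect_equal(nrow(clean$truth$participants), 0)
  expect_equal(nrow(clean$truth$rater_questions), 0)
})

test_that("excess violation counts are rejected", {
  expect_error(
    simulate_study(small_config(seed = 1),
                   violations = list(s1_straightline = 100)),
    "more decision-survey violations"
  )
})
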