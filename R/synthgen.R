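# Names of the 12 motivation questions entering the factor analysis (the
# urgency question q02 and the two summary questions q11, q15 are generated
# too but kept out of the factor structure).
efa_questions <- function() {
  c("q01", "q03", "q04", "q05", "q06", "q07",
    "q08", "q09", "q10", "q12", "q13", "q14")
}

default_loading_matrix <- function() {
  qs <- efa_questions()
  L <- matrix(0, nrow = 12, ncol = 2,
              dimnames = list(qs, c("benefit", "cost")))
  L[, "benefit"] <- 0.85
  L["q05", ] <- c(0, 0.85)  # self cost dominates the second factor
  # cost-tinged affective items carry secondary cost loadings; without them
  # the cost factor would be a single-indicator factor (population eigenvalue
  # 1) that no retention rule could separate from noise
  L[c("q09", "q12", "q13", "q14"), "cost"] <- 0.45
  L
}

default_trait_param_corr <- function() {
  data.frame(
    param = c("b", "b", "b", "w_cost", "w_cost"),
    trait = c("bfi_agreeableness", "iri_ec", "svo", "bis", "rr"),
    rho   = c(0.3, 0.3, 0.3, 0.3, -0.3),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic study
#'
#' Collects every knob of the synthetic-data generator. The defaults mirror
#' the study design this package emulates: 100 everyday helping scenarios,
#' each rated on 15 motivational dimensions by ~28 independent raters who each
#' rate 20 scenarios; 215 decision-making agents who each rate 50 scenarios on
#' a 6-level willingness-to-help scale; a 2-factor motivation structure with
#' 11 benefit-type questions and one self-cost question; agents generated from
#' the single-weight cost-benefit model with trait scores coupled to the model
#' parameters.
#'
#' @param n_scenarios number of scenarios (default 100).
#' @param n_raters_per_scenario raters rating each scenario (default 28).
#' @param scenarios_per_rater scenarios per rater in the rating survey
#'   (default 20).
#' @param n_participants decision-survey agents (default 215).
#' @param trials_per_participant scenarios per agent (default 50); must not
#'   exceed `n_scenarios`.
#' @param loading_matrix 12 x 2 matrix mapping (benefit, cost) latents to the
#'   12 factor-analysed questions.
#' @param rating_noise_sd,rater_bias_sd rating noise components (default 0.5
#'   and 0.3 rating points).
#' @param agent_param_dists named list of c(min, max) uniform ranges for the
#'   agent parameters; min == max gives a point mass.
#' @param trait_param_corr data frame (param, trait, rho) of target Gaussian
#'   copula correlations between agent parameters and trait scores.
#' @param generating_model_id utility model generating the decisions
#'   (default "2.0").
#' @param embedding_dim dimension of the synthetic scenario text embeddings
#'   (default 256).
#' @param n_semantic_clusters number of semantic clusters planted in the
#'   embeddings (default 14).
#' @param embedding_cluster_sd,embedding_noise_sd scale of cluster centroids
#'   and of within-cluster isotropic noise (defaults 10 and 1, i.e. well
#'   separated clusters).
#' @param seed global integer seed; every table derives its own sub-stream
#'   from it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_scenarios = 100,
                             n_raters_per_scenario = 28,
                             scenarios_per_rater = 20,
                             n_participants = 215,
                             trials_per_participant = 50,
                             loading_matrix = default_loading_matrix(),
                             rating_noise_sd = 0.5,
                             rater_bias_sd = 0.3,
                             agent_param_dists = list(beta = c(1, 5),
                                                      w_cost = c(0.1, 0.9),
                                                      b = c(-1, 1),
                                                      w_benefit = c(0.1, 0.9),
                                                      alpha = c(0.5, 2),
                                                      w_cb = c(-1, 1),
                                                      w_u = c(0, 1)),
                             trait_param_corr = default_trait_param_corr(),
                             generating_model_id = "2.0",
                             embedding_dim = 256,
                             n_semantic_clusters = 14,
                             embedding_cluster_sd = 10,
                             embedding_noise_sd = 1,
                             seed = 1) {
  cfg <- list(
    n_scenarios = as.integer(n_scenarios),
    n_raters_per_scenario = as.integer(n_raters_per_scenario),
    scenarios_per_rater = as.integer(scenarios_per_rater),
    n_participants = as.integer(n_participants),
    trials_per_participant = as.integer(trials_per_participant),
    loading_matrix = loading_matrix,
    rating_noise_sd = rating_noise_sd,
    rater_bias_sd = rater_bias_sd,
    agent_param_dists = agent_param_dists,
    trait_param_corr = trait_param_corr,
    generating_model_id = as.character(generating_model_id),
    embedding_dim = as.integer(embedding_dim),
    n_semantic_clusters = as.integer(n_semantic_clusters),
    embedding_cluster_sd = embedding_cluster_sd,
    embedding_noise_sd = embedding_noise_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_scenarios", "n_raters_per_scenario", "scenarios_per_rater",
              "n_participants", "trials_per_participant", "embedding_dim",
              "n_semantic_clusters")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      stop(sprintf("synthetic_config: `%s` must be a count >= 1", f),
           call. = FALSE)
    }
  }
  if (cfg$trials_per_participant > cfg$n_scenarios) {
    stop("synthetic_config: `trials_per_participant` exceeds `n_scenarios`",
         call. = FALSE)
  }
  if (!is.matrix(cfg$loading_matrix) ||
      !all(dim(cfg$loading_matrix) == c(12, 2)) ||
      any(!is.finite(cfg$loading_matrix))) {
    stop("synthetic_config: `loading_matrix` must be a finite 12 x 2 matrix",
         call. = FALSE)
  }
  if (cfg$rating_noise_sd < 0 || cfg$rater_bias_sd < 0) {
    stop("synthetic_config: `rating_noise_sd`/`rater_bias_sd` must be >= 0",
         call. = FALSE)
  }
  if (any(abs(cfg$trait_param_corr$rho) >= 1)) {
    stop("synthetic_config: `trait_param_corr` rho values must lie in (-1, 1)",
         call. = FALSE)
  }
  model_spec(cfg$generating_model_id)  # validates the id
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate scenario latents
#'
#' Draws the per-scenario ground truth the rest of the generator works from:
#' latent benefit and cost (independent standard normals), a uniform urgency
#' level, a semantic cluster assignment, and a text-embedding-like vector
#' (cluster centroid plus isotropic noise).
#'
#' @param config a [synthetic_config()].
#' @return data frame with `scenario_id`, `benefit_true`, `cost_true`,
#'   `urgency_true`, `cluster_id` and embedding columns `e1..e_d`.
#' @export
gen_scenarios <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 101))
  n <- config$n_scenarios
  k <- config$n_semantic_clusters
  d <- config$embedding_dim
  cluster_id <- sample(rep_len(seq_len(k), n))
  centroids <- matrix(stats::rnorm(k * d, sd = config$embedding_cluster_sd),
                      k, d)
  emb <- centroids[cluster_id, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = config$embedding_noise_sd), n, d)
  colnames(emb) <- paste0("e", seq_len(d))
  out <- data.frame(
    scenario_id = sprintf("S%03d", seq_len(n)),
    benefit_true = stats::rnorm(n),
    cost_true = stats::rnorm(n),
    urgency_true = stats::runif(n),
    cluster_id = cluster_id,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(emb))
}

# Discretize a continuous rating to the 1..5 Likert scale.
likert5 <- function(x) pmin(pmax(round(x), 1), 5)

#' Generate the motivation-rating survey
#'
#' Raters are organized in waves: each wave partitions the scenario set into
#' blocks of `scenarios_per_rater`, one block per rater, so each scenario ends
#' up rated by exactly `n_raters_per_scenario` raters. A rater's rating of
#' question q on scenario s is the loading-weighted combination of the
#' scenario's latent benefit and cost, plus a rater bias and Gaussian noise,
#' discretized to 1..5. The urgency question (q02) tracks the latent urgency;
#' the summary questions q11 (of q07-q10) and q15 (of q13-q14) are noisy
#' copies of their constituents' means. Three attention-check rows per rater
#' are appended (correct answer 3).
#'
#' @param latents output of [gen_scenarios()].
#' @param config a [synthetic_config()].
#' @return data frame with `rater_id`, `scenario_id`, `attention_item`,
#'   `attention_response`, `q01`..`q15`, `cant_imagine`.
#' @export
gen_motivation_ratings <- function(latents, config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$loading_matrix
  if (!all(rownames(L) == efa_questions())) {
    rownames(L) <- efa_questions()
  }
  set.seed(sub_seed(config$seed, 202))
  n <- config$n_scenarios
  per <- min(config$scenarios_per_rater, n)
  raters_per_wave <- ceiling(n / per)
  rows <- list()
  rid <- 0L
  for (wave in seq_len(config$n_raters_per_scenario)) {
    ord <- sample.int(n)
    for (blk in seq_len(raters_per_wave)) {
      idx <- ord[(((blk - 1) * per) + 1):min(blk * per, n)]
      rid <- rid + 1L
      rows[[rid]] <- data.frame(rater_idx = rid, scen_idx = idx)
    }
  }
  asg <- do.call(rbind, rows)
  n_raters <- rid
  bias <- stats::rnorm(n_raters, sd = config$rater_bias_sd)
  noise_sd <- config$rating_noise_sd

  qs <- efa_questions()
  m <- nrow(asg)
  ratings <- matrix(NA_real_, m, 15,
                    dimnames = list(NULL, sprintf("q%02d", 1:15)))
  lat_b <- latents$benefit_true[asg$scen_idx]
  lat_c <- latents$cost_true[asg$scen_idx]
  for (q in qs) {
    mu <- 3 + L[q, 1] * lat_b + L[q, 2] * lat_c + bias[asg$rater_idx]
    ratings[, q] <- likert5(mu + stats::rnorm(m, sd = noise_sd))
  }
  mu_u <- 1 + 4 * latents$urgency_true[asg$scen_idx] + bias[asg$rater_idx]
  ratings[, "q02"] <- likert5(mu_u + stats::rnorm(m, sd = noise_sd))
  ratings[, "q11"] <- likert5(rowMeans(ratings[, c("q07", "q08", "q09", "q10")]) +
                                stats::rnorm(m, sd = noise_sd))
  ratings[, "q15"] <- likert5(rowMeans(ratings[, c("q13", "q14")]) +
                                stats::rnorm(m, sd = noise_sd))

  main <- data.frame(
    rater_id = sprintf("R%04d", asg$rater_idx),
    scenario_id = latents$scenario_id[asg$scen_idx],
    attention_item = 0L,
    attention_response = NA_real_,
    stringsAsFactors = FALSE
  )
  main <- cbind(main, as.data.frame(ratings))
  main$cant_imagine <- 0L

  att <- data.frame(
    rater_id = rep(sprintf("R%04d", seq_len(n_raters)), each = 3),
    scenario_id = NA_character_,
    attention_item = 1L,
    attention_response = 3,
    stringsAsFactors = FALSE
  )
  att[sprintf("q%02d", 1:15)] <- NA_real_
  att$cant_imagine <- 0L
  out <- rbind(main, att)
  rownames(out) <- NULL
  out
}

#' Generate agents and coupled trait scores
#'
#' Agent decision parameters and questionnaire trait scores are drawn jointly
#' from a Gaussian copula whose correlation matrix places the requested
#' `trait_param_corr` values between parameter and trait marginals (all other
#' cross-correlations zero). Parameters then get uniform marginals within
#' their configured ranges; traits get questionnaire-like normal marginals.
#' Uncoupled demographics (sex, gender, age, race, ethnicity, education,
#' income) are appended to the trait table.
#'
#' @param config a [synthetic_config()].
#' @return list with `agents` (participant_id, model parameters, model_id)
#'   and `traits` (participant_id, trait scores, demographics).
#' @export
gen_agents <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- model_spec(config$generating_model_id)
  pnames <- names(spec$params)
  traits <- c("iri_ec", "svo", "rr", "bis", "bfi_agreeableness",
              "bfi_extraversion", "bfi_conscientiousness",
              "bfi_neuroticism", "bfi_openness")
  vars <- c(pnames, traits)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  tpc <- config$trait_param_corr
  for (i in seq_len(nrow(tpc))) {
    p <- tpc$param[i]; t <- tpc$trait[i]
    if (p %in% vars && t %in% vars) {
      R[p, t] <- R[t, p] <- tpc$rho[i]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("gen_agents: trait_param_corr implies a non positive semi-definite
         correlation matrix", call. = FALSE)
  }
  set.seed(sub_seed(config$seed, 303))
  np <- config$n_participants
  Z <- matrix(stats::rnorm(np * length(vars)), np) %*%
    chol(R + diag(1e-10, length(vars)))
  colnames(Z) <- vars
  U <- stats::pnorm(Z)

  agents <- data.frame(participant_id = sprintf("P%04d", seq_len(np)),
                       stringsAsFactors = FALSE)
  for (p in pnames) {
    r <- config$agent_param_dists[[p]] %||% spec$params[[p]]
    agents[[p]] <- if (r[1] == r[2]) rep(r[1], np) else
      stats::qunif(U[, p], r[1], r[2])
  }
  if (config$generating_model_id %in% c("1.0", "2.0", "2.1", "2.2",
                                        "2.3", "2.4") &&
      "w_cost" %in% pnames) {
    agents$w_benefit <- 1 - agents$w_cost
  }
  agents$model_id <- config$generating_model_id

  # questionnaire-like marginals: location/scale per instrument
  scales <- list(
    iri_ec = c(15, 4), svo = c(25, 15), rr = c(17, 3), bis = c(19, 4),
    bfi_agreeableness = c(7, 1.8), bfi_extraversion = c(6, 2),
    bfi_conscientiousness = c(7, 1.8), bfi_neuroticism = c(6, 2),
    bfi_openness = c(7, 1.8)
  )
  tt <- data.frame(participant_id = agents$participant_id,
                   stringsAsFactors = FALSE)
  for (t in traits) {
    tt[[t]] <- round(scales[[t]][1] + scales[[t]][2] * Z[, t], 2)
  }
  tt$sex <- sample(c("male", "female"), np, replace = TRUE)
  tt$gender <- sample(c("man", "woman", "nonbinary"), np, replace = TRUE,
                      prob = c(0.485, 0.485, 0.03))
  tt$age <- sample(18:65, np, replace = TRUE)
  tt$race <- sample(c("white", "black", "asian", "native", "multiracial"),
                    np, replace = TRUE, prob = c(0.57, 0.23, 0.1, 0.03, 0.07))
  tt$ethnicity <- sample(c("hispanic", "non-hispanic"), np, replace = TRUE,
                         prob = c(0.12, 0.88))
  tt$education <- sample(c("less-hs", "hs", "some-college", "associate",
                           "bachelor", "graduate"), np, replace = TRUE)
  tt$income <- sample(c("<25k", "<50k", "<75k", "<100k", "<150k", ">150k"),
                      np, replace = TRUE)
  list(agents = agents, traits = tt)
}

# Map a helping probability and the drawn binary decision to a 6-level
# willingness-to-help rating. Levels 4-6 iff help; within each side the level
# tracks the probability through fixed equal-probability bins with the
# help/not-help boundary at P = 0.5.
wth_level_from_p <- function(p, help) {
  ifelse(help == 1,
         4L + findInterval(p, c(2 / 3, 5 / 6)),
         1L + findInterval(p, c(1 / 6, 1 / 3)))
}

#' Generate the decision survey
#'
#' For each agent, samples `trials_per_participant` scenarios without
#' replacement, runs the generating utility model forward (on the same
#' min-max-normalized benefit/cost and median-split urgency the analysis
#' uses), draws binary help decisions from the softmax probability, and
#' derives the 6-level willingness-to-help rating from the probability
#' consistently with the binary draw. Three repeated-scenario rows (responses
#' copied, hence consistent) and three attention-check rows (correct answer 4)
#' per participant provide the quality-control slots.
#'
#' Each agent uses its own seed sub-stream (`seed + 404 + agent index`) so
#' single agents can be re-simulated independently.
#'
#' @param agents agent table from [gen_agents()].
#' @param latents scenario table from [gen_scenarios()].
#' @param config a [synthetic_config()].
#' @return data frame with `participant_id`, `trial`, `scenario_id`,
#'   `wth_level`, `attention_item`, `attention_response`, `repeat_tag`,
#'   `cant_imagine`, plus generator-truth columns `p_help` and `help_true`.
#' @export
gen_decisions <- function(agents, latents, config) {
  stopifnot(inherits(config, "synthetic_config"))
  scores <- data.frame(
    scenario_id = latents$scenario_id,
    cost = min_max(latents$cost_true),
    benefit = min_max(latents$benefit_true),
    urgency = as.integer(latents$urgency_true >
                           stats::median(latents$urgency_true)),
    stringsAsFactors = FALSE
  )
  spec <- model_spec(config$generating_model_id)
  pnames <- names(spec$params)
  absent <- setdiff(pnames, names(agents))
  if (length(absent) > 0) {
    stop(sprintf("gen_decisions: agent table lacks parameter(s) %s for model %s",
                 paste(absent, collapse = ", "), config$generating_model_id),
         call. = FALSE)
  }
  nt <- config$trials_per_participant
  out <- vector("list", nrow(agents))
  for (a in seq_len(nrow(agents))) {
    theta <- as.list(agents[a, pnames])
    missing <- pnames[!vapply(theta, function(x) is.numeric(x) && !is.na(x),
                              logical(1))]
    if (length(missing) > 0) {
      stop(sprintf("gen_decisions: agent %s lacks parameter(s) %s for model %s",
                   agents$participant_id[a], paste(missing, collapse = ", "),
                   config$generating_model_id), call. = FALSE)
    }
    set.seed(sub_seed(config$seed, 404 + a))
    idx <- sample.int(nrow(scores), nt)
    sc <- scores[idx, ]
    U <- utility(config$generating_model_id, theta, sc$cost, sc$benefit,
                 sc$urgency)
    p <- choice_prob(U, theta$beta)
    help <- as.integer(stats::runif(nt) < p)
    d <- data.frame(
      participant_id = agents$participant_id[a],
      trial = seq_len(nt),
      scenario_id = sc$scenario_id,
      wth_level = wth_level_from_p(p, help),
      attention_item = 0L,
      attention_response = NA_real_,
      repeat_tag = "",
      cant_imagine = 0L,
      p_help = p,
      help_true = help,
      stringsAsFactors = FALSE
    )
    # three repeated scenarios: same response, appended after the main block
    rep_rows <- d[sample.int(nt, min(3L, nt)), ]
    rep_rows$repeat_tag <- rep_rows$scenario_id
    rep_rows$trial <- nt + seq_len(nrow(rep_rows))
    att <- d[rep(1, 3), ]
    att$trial <- nt + nrow(rep_rows) + 1:3
    att$scenario_id <- NA_character_
    att$attention_item <- 1L
    att$attention_response <- 4
    att$wth_level <- NA_integer_
    att$repeat_tag <- ""
    att$p_help <- NA_real_
    att$help_true <- NA_integer_
    out[[a]] <- rbind(d, rep_rows, att)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant quality-control violations
#'
#' Contaminates clean synthetic survey tables with known violations of the
#' exclusion rules, returning the contaminated tables together with the
#' ground-truth exclusion lists. Rule keys: `s1_attention`, `s1_inconsistent`,
#' `s1_straightline`, `s1_cant_imagine` (decision survey, participant level);
#' `s2_attention` (rating survey, rater level); `s2_low_sd`, `s2_outlier`
#' (rating survey, rater-question level).
#'
#' @param decisions decision table from [gen_decisions()].
#' @param ratings rating table from [gen_motivation_ratings()].
#' @param violations named list of counts per rule (missing keys mean 0).
#' @param seed integer seed for victim selection.
#' @return list with `decisions`, `ratings`, and `truth`: a list with
#'   `participants` (participant_id, rule), `raters` (rater_id, rule) and
#'   `rater_questions` (rater_id, question, rule) data frames.
#' @export
inject_qc_violations <- function(decisions, ratings,
                                 violations = list(), seed = 1) {
  v <- function(key) as.integer(violations[[key]] %||% 0L)
  set.seed(sub_seed(seed, 505))
  pids <- unique(decisions$participant_id)
  need_p <- v("s1_attention") + v("s1_inconsistent") +
    v("s1_straightline") + v("s1_cant_imagine")
  if (need_p > length(pids)) {
    stop("inject_qc_violations: more decision-survey violations than
         participants", call. = FALSE)
  }
  victims <- sample(pids, need_p)
  take <- function(k) {
    if (k == 0) return(character(0))
    out <- victims[seq_len(k)]
    victims <<- victims[-seq_len(k)]
    out
  }
  truth_p <- data.frame(participant_id = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  mark <- function(ids, rule) {
    if (length(ids) > 0) {
      truth_p <<- rbind(truth_p, data.frame(participant_id = ids, rule = rule,
                                            stringsAsFactors = FALSE))
    }
  }

  ids <- take(v("s1_attention"))
  for (pid in ids) {
    att <- which(decisions$participant_id == pid & decisions$attention_item == 1)
    decisions$attention_response[att[1:2]] <- 1
  }
  mark(ids, "attention")

  ids <- take(v("s1_inconsistent"))
  for (pid in ids) {
    reps <- which(decisions$participant_id == pid & decisions$repeat_tag != "")
    for (r in reps[1:2]) {
      orig <- which(decisions$participant_id == pid &
                      decisions$scenario_id == decisions$repeat_tag[r] &
                      decisions$repeat_tag == "" &
                      decisions$attention_item == 0)
      decisions$wth_level[r] <- if (decisions$wth_level[orig[1]] >= 4) 2L else 5L
    }
  }
  mark(ids, "inconsistent")

  ids <- take(v("s1_straightline"))
  for (pid in ids) {
    rws <- which(decisions$participant_id == pid & decisions$attention_item == 0)
    decisions$wth_level[rws] <- 4L
  }
  mark(ids, "straightline")

  ids <- take(v("s1_cant_imagine"))
  for (pid in ids) {
    rws <- which(decisions$participant_id == pid &
                   decisions$attention_item == 0 & decisions$repeat_tag == "")
    decisions$cant_imagine[rws[seq_len(min(10, length(rws)))]] <- 1L
  }
  mark(ids, "cant_imagine")

  # rating survey
  rids <- unique(ratings$rater_id)
  need_r <- v("s2_attention") + v("s2_low_sd") + v("s2_outlier")
  if (need_r > length(rids)) {
    stop("inject_qc_violations: more rating-survey violations than raters",
         call. = FALSE)
  }
  rvictims <- sample(rids, need_r)
  rtake <- function(k) {
    if (k == 0) return(character(0))
    out <- rvictims[seq_len(k)]
    rvictims <<- rvictims[-seq_len(k)]
    out
  }
  truth_r <- data.frame(rater_id = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  truth_rq <- data.frame(rater_id = character(0), question = character(0),
                         rule = character(0), stringsAsFactors = FALSE)

  ids <- rtake(v("s2_attention"))
  for (rid in ids) {
    att <- which(ratings$rater_id == rid & ratings$attention_item == 1)
    ratings$attention_response[att[1:2]] <- 1
  }
  if (length(ids) > 0) {
    truth_r <- rbind(truth_r, data.frame(rater_id = ids, rule = "attention",
                                         stringsAsFactors = FALSE))
  }

  # Victims of the two rater-question rules are spread over different
  # questions: several outliers planted on the same question would mask each
  # other in the group mean/SD that the outlier rule is computed from.
  low_sd_qs <- c("q03", "q04", "q07", "q01", "q13")
  ids <- rtake(v("s2_low_sd"))
  for (i in seq_along(ids)) {
    rid <- ids[i]
    q <- low_sd_qs[(i - 1) %% length(low_sd_qs) + 1]
    rws <- which(ratings$rater_id == rid & ratings$attention_item == 0)
    ratings[rws, q] <- 3
    truth_rq <- rbind(truth_rq,
                      data.frame(rater_id = rid, question = q,
                                 rule = "low_sd", stringsAsFactors = FALSE))
  }

  outlier_qs <- c("q06", "q08", "q10", "q12", "q14")
  ids <- rtake(v("s2_outlier"))
  for (i in seq_along(ids)) {
    rid <- ids[i]
    q <- outlier_qs[(i - 1) %% length(outlier_qs) + 1]
    rws <- which(ratings$rater_id == rid & ratings$attention_item == 0)
    # alternate 5/4 keeps the per-question SD above the low-variability
    # threshold while shifting the rater's mean far from the group
    ratings[rws, q] <- rep_len(c(5, 4), length(rws))
    truth_rq <- rbind(truth_rq,
                      data.frame(rater_id = rid, question = q,
                                 rule = "outlier", stringsAsFactors = FALSE))
  }

  list(decisions = decisions, ratings = ratings,
       truth = list(participants = truth_p, raters = truth_r,
                    rater_questions = truth_rq))
}

#' One-call synthetic study
#'
#' Convenience wrapper running the full generator: scenarios, motivation
#' ratings, agents + traits, decisions, and optional planted QC violations.
#'
#' @param config a [synthetic_config()].
#' @param violations passed to [inject_qc_violations()] (NULL for none).
#' @return list with `scenarios`, `ratings`, `agents`, `traits`, `decisions`,
#'   `truth` (exclusion ground truth; empty tables when nothing was planted).
#' @export
simulate_study <- function(config = synthetic_config(), violations = NULL) {
  scen <- gen_scenarios(config)
  ratings <- gen_motivation_ratings(scen, config)
  ag <- gen_agents(config)
  decisions <- gen_decisions(ag$agents, scen, config)
  truth <- list(
    participants = data.frame(participant_id = character(0),
                              rule = character(0), stringsAsFactors = FALSE),
    raters = data.frame(rater_id = character(0), rule = character(0),
                        stringsAsFactors = FALSE),
    rater_questions = data.frame(rater_id = character(0),
                                 question = character(0), rule = character(0),
                                 stringsAsFactors = FALSE)
  )
  if (!is.null(violations)) {
    inj <- inject_qc_violations(decisions, ratings, violations,
                                seed = config$seed)
    decisions <- inj$decisions
    ratings <- inj$ratings
    truth <- inj$truth
  }
  list(scenarios = scen, ratings = ratings, agents = ag$agents,
       traits = ag$traits, decisions = decisions, truth = truth)
}
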