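test_that("willingness-to-help coding follows the 6-point scale", {
  coded <- code_wth(1:6)
  expect_equal(coded$wth_code, c(-5, -3, -1, 1, 3, 5))
  expect_equal(coded$help, c(0, 0, 0, 1, 1, 1))
  expect_equal(code_wth(4)$help, 1)  # "somewhat likely" counts as help
  expect_equal(code_wth(3)$help, 0)  # "somewhat unlikely" does not
  expect_error(code_wth(0), "1..6")
  expect_error(code_wth(7), "1..6")
})

test_that("planted decision-survey violations are recovered exactly", {
  viol <- list(s1_attention = 2, s1_inconsistent = 2, s1_straightline = 3,
               s1_cant_imagine = 2)
  st <- simulate_study(exact_qc_config(seed = 11), violations = viol)
  res <- apply_decision_qc(st$decisions)
  got <- res$report$excluded[order(res$report$excluded$participant_id), ]
  want <- st$truth$participants[order(st$truth$participants$participant_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # excluded participants leave no trials behind
  expect_false(any(res$decisions$participant_id %in% want$participant_id))
})

test_that("planted rating-survey violations are recovered exactly", {
  viol <- list(s2_attention = 1, s2_low_sd = 2, s2_outlier = 2)
  st <- simulate_study(exact_qc_config(seed = 12), violations = viol)
  res <- apply_rating_qc(st$ratings)
  expect_identical(
    res$report$excluded_raters[order(res$report$excluded_raters$rater_id), ],
    st$truth$raters[order(st$truth$raters$rater_id), ]
  )
  got <- res$report$excluded_pairs[order(res$report$excluded_pairs$rater_id), ]
  want <- st$truth$rater_questions[order(st$truth$rater_questions$rater_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("decision QC agrees with a naive rule-by-rule oracle", {
  st <- simulate_study(small_config(seed = 3),
                       violations = list(s1_attention = 1, s1_straightline = 1))
  raw <- st$decisions
  res <- apply_decision_qc(raw)
  oracle <- character(0)
  for (pid in unique(raw$participant_id)) {
    d <- raw[raw$participant_id == pid, ]
    att <- d[d$attention_item == 1, ]
    fail_att <- sum(att$attention_response != 4, na.rm = TRUE) >= 2
    reps <- d[d$repeat_tag != "" & d$attention_item == 0, ]
    incons <- 0
    for (i in seq_len(nrow(reps))) {
      orig <- d[d$scenario_id == reps$repeat_tag[i] & d$repeat_tag == "" &
                  d$attention_item == 0, ][1, ]
      if ((orig$wth_level >= 4) != (reps$wth_level[i] >= 4)) incons <- incons + 1
    }
    rate <- d[d$attention_item == 0, ]
    if (fail_att || incons >= 2 || sd(rate$wth_level) < 0.5 ||
        sum(rate$cant_imagine) >= 10) {
      oracle <- c(oracle, pid)
    }
  }
  expect_setequal(res$report$excluded$participant_id, oracle)
})

test_that("QC is idempotent on already-clean data", {
  st <- simulate_study(exact_qc_config(seed = 21))
  d1 <- apply_decision_qc(st$decisions)
  expect_equal(nrow(d1$report$excluded), 0)
  r1 <- apply_rating_qc(st$ratings)
  expect_equal(nrow(r1$report$excluded_raters), 0)
  expect_equal(nrow(r1$report$excluded_pairs), 0)
  # a second pass over the cleaned decision trials removes nothing
  redo <- st$decisions[st$decisions$participant_id %in%
                         d1$decisions$participant_id, ]
  d2 <- apply_decision_qc(redo)
  expect_equal(nrow(d2$report$excluded), 0)
  expect_equal(nrow(d2$decisions), nrow(d1$decisions))
})

test_that("outlier rule fires on a hand-built case", {
  # group mean 3.0, sd 0.2 across rater means; one rater at 3.7 (> 3 sigma)
  set.seed(1)
  n_raters <- 50
  base <- rep(3, 10)
  rows <- list()
  for (r in seq_len(n_raters)) {
    shift <- if (r == 1) 0.7 else qnorm((r - 0.5) / n_raters, 0, 0.15)
    vals <- pmin(pmax(base + shift + rep(c(-0.5, 0.5), 5), 1), 5)
    rows[[r]] <- data.frame(
      rater_id = sprintf("R%02d", r), scenario_id = sprintf("S%02d", 1:10),
      attention_item = 0L, attention_response = NA_real_,
      q01 = vals, cant_imagine = 0L)
  }
  raw <- do.call(rbind, rows)
  res <- apply_rating_qc(raw)
  expect_true(any(res$report$excluded_pairs$rater_id == "R01" &
                    res$report$excluded_pairs$rule == "outlier"))
})

test_that("constant raters and identical raters behave as documented", {
  mk <- function(vals_fun) {
    do.call(rbind, lapply(1:6, function(r) {
      data.frame(rater_id = sprintf("R%02d", r),
                 scenario_id = sprintf("S%02d", 1:20),
                 attention_item = 0L, attention_response = NA_real_,
                 q01 = vals_fun(r), cant_imagine = 0L)
    }))
  }
  # one rater constant on the question -> that pair excluded
  raw <- mk(function(r) if (r == 1) rep(3, 20) else rep(1:5, 4))
  res <- apply_rating_qc(raw)
  expect_identical(res$report$excluded_pairs$rater_id, "R01")
  expect_identical(res$report$excluded_pairs$rule, "low_sd")
  # all raters identical (non-constant) -> nothing excluded
  raw2 <- mk(function(r) rep(1:5, 4))
  res2 <- apply_rating_qc(raw2)
  expect_equal(nrow(res2$report$excluded_pairs), 0)
})

test_that("consensus means and counts are exact and order-invariant", {
  raw <- data.frame(
    rater_id = c("a", "b"), scenario_id = "S01",
    attention_item = 0L, attention_response = NA_real_,
    q01 = c(2, 4), cant_imagine = 0L)
  out <- compute_consensus(raw, min_raters = 0)
  expect_equal(out$mean_q01, 3.0)
  expect_equal(out$n_q01, 2L)
  out2 <- compute_consensus(raw[2:1, ], min_raters = 0)
  expect_equal(out, out2)
})

test_that("noiseless synthetic consensus equals the discretized truth", {
  cfg <- exact_qc_config(seed = 5)
  scen <- gen_scenarios(cfg)
  rat <- gen_motivation_ratings(scen, cfg)
  clean <- apply_rating_qc(rat)$ratings
  cons <- suppressWarnings(compute_consensus(clean, min_raters = 0))
  L <- cfg$loading_matrix
  want <- pmin(pmax(round(3 + L["q01", 1] * scen$benefit_true +
                            L["q01", 2] * scen$cost_true), 1), 5)
  expect_equal(cons$mean_q01[match(scen$scenario_id, cons$scenario_id)], want)
})

test_that("dropping one scenario's ratings only touches that scenario", {
  cfg <- exact_qc_config(seed = 6, n_scenarios = 10)
  scen <- gen_scenarios(cfg)
  rat <- gen_motivation_ratings(scen, cfg)
  rat <- rat[rat$attention_item == 0, ]
  flagged <- rat
  drop_idx <- which(flagged$scenario_id == "S003")[1:3]
  flagged <- flagged[-drop_idx, ]
  c1 <- compute_consensus(rat, min_raters = 0)
  c2 <- compute_consensus(flagged, min_raters = 0)
  changed <- which(c1$n_q01 != c2$n_q01)
  expect_equal(c1$scenario_id[changed], "S003")
  expect_equal(c1[c1$scenario_id != "S003", ], c2[c2$scenario_id != "S003", ])
})

test_that("ICC(A,k) handles the canonical desk cases", {
  set.seed(2)
  scen_eff <- rnorm(10, 0, 1)
  perfect <- rbind(scen_eff, scen_eff, scen_eff)
  expect_equal(icc_a_k(perfect)$icc, 1)
  # constant offset: absolute agreement is penalized
  offset <- rbind(scen_eff, scen_eff + 1)
  r <- icc_a_k(offset)
  expect_lt(r$icc, 1)
  expect_gt(r$icc, 0)
  # hand evaluation on the 2 x 10 offset matrix
  n <- 10
  ms_r <- 2 * sum((colMeans(offset) - mean(offset))^2) / (n - 1)
  ms_c <- n * sum((rowMeans(offset) - mean(offset))^2) / (2 - 1)
  expect_equal(r$icc, ms_r / (ms_r + ms_c / n), tolerance = 1e-12)
})

test_that("pure-noise raters give near-zero ICC", {
  # a single 30 x 100 draw has Monte-Carlo sd ~ sqrt(2/99) ~ 0.14, so the
  # near-zero property is checked on the Monte-Carlo mean
  set.seed(7)
  iccs <- replicate(15, icc_a_k(matrix(rnorm(30 * 100), 30, 100))$icc)
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("ICC is shift-invariant and decreases under added noise", {
  set.seed(8)
  scen_eff <- rnorm(40, 0, 2)
  m <- outer(rep(1, 6), scen_eff) + matrix(rnorm(240, 0, 0.5), 6)
  base <- icc_a_k(m)$icc
  expect_equal(icc_a_k(m + 100)$icc, base, tolerance = 1e-9)
  noisy <- m + matrix(rnorm(240, 0, 2), 6)
  expect_lt(icc_a_k(noisy)$icc, base)
})

test_that("incomplete matrices work through the pairwise estimator", {
  set.seed(9)
  scen_eff <- rnorm(30)
  m <- outer(rep(1, 8), scen_eff) + matrix(rnorm(240, 0, 0.3), 8)
  m[sample(length(m), 60)] <- NA
  r <- icc_a_k(m, use = "pairwise")
  expect_true(r$icc > 0.5 && r$icc <= 1)
  expect_error(icc_a_k(matrix(c(1, NA, NA, 2), 2), use = "pairwise"),
               "not enough overlapping")
})
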