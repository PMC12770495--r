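# Correct answers planted in the synthetic attention-check items.
ATT_CORRECT_DECISION <- 4
ATT_CORRECT_RATING <- 3

#' Code a willingness-to-help level
#'
#' Maps the 6-point willingness-to-help (WTH) level to its signed code on the
#' -5..5 scale and to the binary help decision: levels 1..6 map to codes
#' (-5, -3, -1, 1, 3, 5); levels 4 and above ("somewhat likely" upward) count
#' as help.
#'
#' @param wth_level integer vector of levels in 1..6.
#' @return data frame with `wth_code` and `help` columns.
#' @export
code_wth <- function(wth_level) {
  if (any(!wth_level %in% 1:6)) {
    stop("code_wth: levels must be integers in 1..6", call. = FALSE)
  }
  codes <- c(-5L, -3L, -1L, 1L, 3L, 5L)
  data.frame(wth_code = codes[wth_level],
             help = as.integer(wth_level >= 4))
}

#' Decision-survey quality control
#'
#' Applies the four participant-level exclusion rules of the decision survey,
#' in this documented precedence order (each participant counted once, under
#' the first rule that fires):
#' \enumerate{
#'   \item failed >= 2 of the 3 attention-check questions;
#'   \item >= 2 of the 3 repeated scenarios got an inconsistent binarized
#'     (help vs not-help) response;
#'   \item straight-line responding: SD of all non-attention WTH ratings
#'     < 0.5;
#'   \item flagged "can't understand/imagine" on >= 10 scenarios.
#' }
#' For surviving participants, flagged trials are dropped, repeated-scenario
#' duplicates and attention rows are removed, and `wth_code`/`help` columns
#' are added.
#'
#' @param raw decision table in the [gen_decisions()] schema.
#' @return list with `decisions` (clean per-trial data) and `report`
#'   (`excluded` data frame, counts per rule, dropped-trial count).
#' @export
apply_decision_qc <- function(raw) {
  need <- c("participant_id", "scenario_id", "wth_level", "attention_item",
            "attention_response", "repeat_tag", "cant_imagine")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("apply_decision_qc: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  excluded <- data.frame(participant_id = character(0), rule = character(0),
                         stringsAsFactors = FALSE)
  for (pid in unique(raw$participant_id)) {
    d <- raw[raw$participant_id == pid, ]
    att <- d[d$attention_item == 1, ]
    n_att_fail <- sum(att$attention_response != ATT_CORRECT_DECISION,
                      na.rm = TRUE)
    reps <- d[d$repeat_tag != "" & d$attention_item == 0, ]
    n_incons <- 0L
    for (i in seq_len(nrow(reps))) {
      orig <- d[d$scenario_id == reps$repeat_tag[i] & d$repeat_tag == "" &
                  d$attention_item == 0, ]
      if (nrow(orig) > 0 &&
          (orig$wth_level[1] >= 4) != (reps$wth_level[i] >= 4)) {
        n_incons <- n_incons + 1L
      }
    }
    rate <- d[d$attention_item == 0, ]
    sd_resp <- stats::sd(rate$wth_level)
    n_cant <- sum(rate$cant_imagine == 1)
    rule <- if (n_att_fail >= 2) "attention"
      else if (n_incons >= 2) "inconsistent"
      else if (is.finite(sd_resp) && sd_resp < 0.5) "straightline"
      else if (n_cant >= 10) "cant_imagine"
      else NA_character_
    if (!is.na(rule)) {
      excluded <- rbind(excluded,
                        data.frame(participant_id = pid, rule = rule,
                                   stringsAsFactors = FALSE))
    }
  }
  keep <- raw[!raw$participant_id %in% excluded$participant_id &
                raw$attention_item == 0 & raw$repeat_tag == "", ]
  n_flagged <- sum(keep$cant_imagine == 1)
  keep <- keep[keep$cant_imagine == 0, ]
  coded <- code_wth(keep$wth_level)
  keep$wth_code <- coded$wth_code
  keep$help <- coded$help
  rownames(keep) <- NULL
  list(
    decisions = keep,
    report = list(
      excluded = excluded,
      counts = table(factor(excluded$rule,
                            levels = c("attention", "inconsistent",
                                       "straightline", "cant_imagine"))),
      n_trials_dropped = n_flagged
    )
  )
}

#' Rating-survey quality control
#'
#' Applies the rating-survey exclusion rules: raters failing >= 2 attention
#' checks are dropped entirely; ratings of scenarios flagged as not
#' understood/imagined are dropped; then, per rater and question, the rater's
#' ratings of that question are excluded (set to NA) if their SD across the
#' rater's scenarios is below 0.1 (low variability; checked first) or if the
#' rater's mean is more than 3 group-level standard deviations from the group
#' mean of rater means on that question (outlier). Pairs with fewer than two
#' ratings are skipped with a warning (SD undefined).
#'
#' @param raw rating table in the [gen_motivation_ratings()] schema.
#' @return list with `ratings` (clean rows, excluded cells NA) and `report`
#'   (`excluded_raters`, `excluded_pairs` data frames, dropped-row count).
#' @export
apply_rating_qc <- function(raw) {
  need <- c("rater_id", "scenario_id", "attention_item", "attention_response",
            "cant_imagine")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("apply_rating_qc: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  qs <- grep("^q[0-9]{2}$", names(raw), value = TRUE)
  excluded_raters <- data.frame(rater_id = character(0), rule = character(0),
                                stringsAsFactors = FALSE)
  for (rid in unique(raw$rater_id)) {
    att <- raw[raw$rater_id == rid & raw$attention_item == 1, ]
    if (sum(att$attention_response != ATT_CORRECT_RATING, na.rm = TRUE) >= 2) {
      excluded_raters <- rbind(excluded_raters,
                               data.frame(rater_id = rid, rule = "attention",
                                          stringsAsFactors = FALSE))
    }
  }
  clean <- raw[raw$attention_item == 0 &
                 !raw$rater_id %in% excluded_raters$rater_id, ]
  n_dropped <- sum(clean$cant_imagine == 1)
  clean <- clean[clean$cant_imagine == 0, ]

  excluded_pairs <- data.frame(rater_id = character(0), question = character(0),
                               rule = character(0), stringsAsFactors = FALSE)
  # group distribution of rater means per question, on post-attention data
  rater_means <- lapply(qs, function(q) {
    tapply(clean[[q]], clean$rater_id, mean, na.rm = TRUE)
  })
  names(rater_means) <- qs
  for (q in qs) {
    mns <- rater_means[[q]]
    g_mean <- mean(mns, na.rm = TRUE)
    g_sd <- stats::sd(mns, na.rm = TRUE)
    for (rid in names(mns)) {
      vals <- clean[[q]][clean$rater_id == rid]
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2) {
        warning(sprintf(
          "apply_rating_qc: rater %s has < 2 ratings on %s, pair skipped",
          rid, q))
        next
      }
      rule <- if (stats::sd(vals) < 0.1) "low_sd"
        else if (is.finite(g_sd) && abs(mns[[rid]] - g_mean) > 3 * g_sd)
          "outlier"
        else NA_character_
      if (!is.na(rule)) {
        excluded_pairs <- rbind(excluded_pairs,
                                data.frame(rater_id = rid, question = q,
                                           rule = rule,
                                           stringsAsFactors = FALSE))
        clean[[q]][clean$rater_id == rid] <- NA_real_
      }
    }
  }
  rownames(clean) <- NULL
  list(
    ratings = clean,
    report = list(excluded_raters = excluded_raters,
                  excluded_pairs = excluded_pairs,
                  n_rows_dropped = n_dropped)
  )
}

#' Consensus ratings per scenario
#'
#' Arithmetic mean and rater count per scenario and question over the
#' quality-checked ratings, optionally augmented with the mean WTH code and
#' percent help per scenario from a clean decision table.
#'
#' @param ratings clean rating table from [apply_rating_qc()].
#' @param decisions optional clean decision table from [apply_decision_qc()].
#' @param min_raters warn when any scenario-question cell has fewer raters
#'   than this (default 25, the design target; set 0 to silence).
#' @return data frame, one row per scenario: `mean_q01..`, `n_q01..`, and when
#'   decisions are given `mean_wth` and `pct_help`.
#' @export
compute_consensus <- function(ratings, decisions = NULL, min_raters = 25) {
  qs <- grep("^q[0-9]{2}$", names(ratings), value = TRUE)
  scen <- sort(unique(ratings$scenario_id))
  out <- data.frame(scenario_id = scen, stringsAsFactors = FALSE)
  empty <- character(0)
  for (q in qs) {
    mns <- tapply(ratings[[q]], ratings$scenario_id, mean, na.rm = TRUE)
    cnt <- tapply(!is.na(ratings[[q]]), ratings$scenario_id, sum)
    out[[paste0("mean_", q)]] <- as.numeric(mns[scen])
    out[[paste0("n_", q)]] <- as.integer(cnt[scen])
    zero <- scen[is.na(cnt[scen]) | cnt[scen] == 0]
    if (length(zero) > 0) {
      empty <- c(empty, paste(zero, q, sep = ":"))
    }
  }
  if (length(empty) > 0) {
    stop(sprintf("compute_consensus: cell(s) with zero surviving raters: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  if (min_raters > 0) {
    counts <- as.matrix(out[, paste0("n_", qs)])
    if (min(counts) < min_raters) {
      warning(sprintf(
        "compute_consensus: %d scenario-question cell(s) have fewer than %d raters",
        sum(counts < min_raters), min_raters))
    }
  }
  if (!is.null(decisions)) {
    coded <- if ("wth_code" %in% names(decisions)) decisions else {
      cbind(decisions, code_wth(decisions$wth_level))
    }
    mw <- tapply(coded$wth_code, coded$scenario_id, mean)
    ph <- tapply(coded$help, coded$scenario_id, mean)
    out$mean_wth <- as.numeric(mw[scen])
    out$pct_help <- 100 * as.numeric(ph[scen])
  }
  out
}

#' Intraclass correlation ICC(A,k)
#'
#' Two-way random-effects intraclass correlation for absolute agreement of
#' the average of k raters (McGraw & Wong case A, average measures):
#' \deqn{ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)}
#' with \eqn{MS_R} the scenario (row) mean square, \eqn{MS_C} the rater
#' (column) mean square, \eqn{MS_E} the interaction/error mean square and n
#' the number of scenarios. For incomplete matrices the default keeps the
#' complete sub-matrix (raters without missing cells); `use = "pairwise"`
#' estimates the mean squares from all available cells through the additive
#' two-way ANOVA instead.
#'
#' @param mat numeric matrix, raters x scenarios, NAs allowed.
#' @param use "complete" (default) or "pairwise".
#' @return list with `icc`, `ms_r`, `ms_c`, `ms_e`, `n_raters`, `n_scenarios`.
#' @export
icc_a_k <- function(mat, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (use == "complete") {
    keep <- stats::complete.cases(mat)
    m <- mat[keep, , drop = FALSE]
    keep_s <- colSums(is.na(m)) == 0
    m <- m[, keep_s, drop = FALSE]
    if (nrow(m) < 2 || ncol(m) < 2) {
      stop("icc_a_k: fewer than 2 complete raters/scenarios; use = 'pairwise'
           handles incomplete matrices", call. = FALSE)
    }
    k <- nrow(m)      # raters
    n <- ncol(m)      # scenarios
    grand <- mean(m)
    row_means <- rowMeans(m)   # rater means
    col_means <- colMeans(m)   # scenario means
    ms_c <- n * sum((row_means - grand)^2) / (k - 1)
    ms_r <- k * sum((col_means - grand)^2) / (n - 1)
    resid <- m - outer(row_means, rep(1, n)) -
      outer(rep(1, k), col_means) + grand
    ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  } else {
    df <- data.frame(
      y = as.vector(mat),
      rater = factor(rep(seq_len(nrow(mat)), times = ncol(mat))),
      scen = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
    )
    df <- df[!is.na(df$y), ]
    if (nrow(df) < 4 || nlevels(droplevels(df$rater)) < 2 ||
        nlevels(droplevels(df$scen)) < 2) {
      stop("icc_a_k: not enough overlapping ratings", call. = FALSE)
    }
    fit <- stats::aov(y ~ scen + rater, data = df)
    tab <- summary(fit)[[1]]
    ms_r <- tab["scen", "Mean Sq"]
    ms_c <- tab["rater", "Mean Sq"]
    ms_e <- tab["Residuals", "Mean Sq"]
    n <- nlevels(droplevels(df$scen))
    k <- nlevels(droplevels(df$rater))
  }
  if (!is.finite(ms_r) || (ms_r == 0 && ms_e == 0 && ms_c == 0)) {
    stop("icc_a_k: reliability undefined (no variance)", call. = FALSE)
  }
  icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  list(icc = icc, ms_r = ms_r, ms_c = ms_c, ms_e = ms_e,
       n_raters = k, n_scenarios = n)
}

#' ICC(A,k) for every motivation question
#'
#' Builds the rater x scenario matrix per question from a clean rating table
#' and computes [icc_a_k()] on each.
#'
#' @param ratings clean rating table.
#' @param use passed to [icc_a_k()]; "pairwise" is the practical choice for
#'   survey designs where raters see scenario subsets.
#' @return data frame (question, icc, n_raters, n_scenarios).
#' @export
icc_by_question <- function(ratings, use = "pairwise") {
  qs <- grep("^q[0-9]{2}$", names(ratings), value = TRUE)
  out <- lapply(qs, function(q) {
    m <- tapply(ratings[[q]], list(ratings$rater_id, ratings$scenario_id),
                mean)
    res <- icc_a_k(m, use = use)
    data.frame(question = q, icc = res$icc, n_raters = res$n_raters,
               n_scenarios = res$n_scenarios, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
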