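#' Pipeline configuration
#'
#' Assembles the settings of an end-to-end run: either paths to existing
#' survey tables or the synthetic generator, stage toggles, fitting and
#' permutation settings, output directory and the mandatory global seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed (mandatory; every stochastic stage derives
#'   a sub-seed from it).
#' @param synthetic if TRUE (default) the input tables come from
#'   [simulate_study()] with `synth_config`.
#' @param synth_config a [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param inputs named list of CSV paths (`decisions`, `ratings`, `traits`,
#'   `scenarios`) when `synthetic = FALSE`.
#' @param stages character vector of stages to run, in dependency order, among
#'   "simulate", "qc", "factors", "fit", "spaces", "traits".
#' @param fit_models model ids fitted in the fit stage (default "1.0" and
#'   "2.0"; the full seven-model comparison is a deliberate opt-in because of
#'   its run time).
#' @param n_restarts restarts per maximum-likelihood fit.
#' @param n_perm permutations for RSA and trait correlations (default 500).
#' @param loo compute leave-one-out accuracy per fit (default FALSE; refitting
#'   per trial is by far the most expensive step).
#' @param log_level "info" (stage messages) or "quiet".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            synthetic = TRUE,
                            synth_config = synthetic_config(),
                            inputs = NULL,
                            stages = c("simulate", "qc", "factors", "fit",
                                       "spaces", "traits"),
                            fit_models = c("1.0", "2.0"),
                            n_restarts = 10,
                            n_perm = 500,
                            loo = FALSE,
                            log_level = c("info", "quiet")) {
  if (missing(seed)) stop("pipeline_config: `seed` is mandatory",
                          call. = FALSE)
  log_level <- match.arg(log_level)
  if (!synthetic) {
    need <- c("decisions", "ratings", "traits", "scenarios")
    if (is.null(inputs) || !all(need %in% names(inputs))) {
      stop(sprintf("pipeline_config: non-synthetic runs need input paths: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, synth_config = synth_config,
                 inputs = inputs, stages = stages, fit_models = fit_models,
                 n_restarts = n_restarts, n_perm = n_perm, loo = loo,
                 log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (config$log_level == "info") {
    message(sprintf("[helpcb %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_matrix_out <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(scenario_id = rownames(m) %||% seq_len(nrow(m)), df)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate (or load) the
#' survey tables; quality control and consensus with inter-rater
#' reliability; factor analysis and motivation scores; model fitting and
#' comparison; representational spaces with RSA and RDM regressions; trait
#' statistics. All intermediate products are written as CSV/JSON files into
#' the output directory, together with a run manifest (input hashes, seed,
#' outputs, package version). A rerun with the identical configuration
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly also written as manifest.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add <- function(p) outputs <<- c(outputs, p)
  st <- function(name) name %in% config$stages

  # ---- inputs ----
  if (config$synthetic) {
    if (st("simulate")) {
      pipe_log(config, "simulate: generating synthetic study")
      cfg <- config$synth_config
      cfg$seed <- config$seed
      study <- simulate_study(cfg)
      add(write_csv_out(study$decisions, file.path(config$out_dir,
                                                   "decisions.csv")))
      add(write_csv_out(study$ratings, file.path(config$out_dir,
                                                 "ratings.csv")))
      add(write_csv_out(study$traits, file.path(config$out_dir, "traits.csv")))
      add(write_csv_out(study$scenarios, file.path(config$out_dir,
                                                   "scenarios.csv")))
      truth <- list(agents = study$agents, exclusions = study$truth)
      jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                           dataframe = "columns", digits = NA)
      add(file.path(config$out_dir, "truth.json"))
    } else {
      stop("run_pipeline: synthetic runs need the 'simulate' stage",
           call. = FALSE)
    }
  } else {
    pipe_log(config, "loading input tables")
    study <- list(
      decisions = utils::read.csv(config$inputs$decisions,
                                  stringsAsFactors = FALSE),
      ratings = utils::read.csv(config$inputs$ratings,
                                stringsAsFactors = FALSE),
      traits = utils::read.csv(config$inputs$traits, stringsAsFactors = FALSE),
      scenarios = utils::read.csv(config$inputs$scenarios,
                                  stringsAsFactors = FALSE)
    )
  }
  need_cols <- c("participant_id", "scenario_id", "wth_level",
                 "attention_item", "repeat_tag", "cant_imagine")
  miss <- setdiff(need_cols, names(study$decisions))
  if (length(miss) > 0) {
    stop(sprintf("run_pipeline: decisions table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.character(study$decisions$repeat_tag) ||
      all(is.na(study$decisions$repeat_tag))) {
    study$decisions$repeat_tag[is.na(study$decisions$repeat_tag)] <- ""
  }

  clean_dec <- NULL; consensus <- NULL; scores <- NULL

  # ---- qc + consensus ----
  if (st("qc")) {
    pipe_log(config, "qc: decision and rating surveys")
    dqc <- apply_decision_qc(study$decisions)
    rqc <- apply_rating_qc(study$ratings)
    clean_dec <- dqc$decisions
    consensus <- suppressWarnings(
      compute_consensus(rqc$ratings, clean_dec, min_raters = 0)
    )
    icc <- icc_by_question(rqc$ratings, use = "pairwise")
    add(write_csv_out(clean_dec, file.path(config$out_dir,
                                           "decisions_clean.csv")))
    add(write_csv_out(consensus, file.path(config$out_dir, "consensus.csv")))
    add(write_csv_out(icc, file.path(config$out_dir, "icc.csv")))
    qc_report <- list(
      decision_excluded = dqc$report$excluded,
      decision_trials_dropped = dqc$report$n_trials_dropped,
      rating_excluded_raters = rqc$report$excluded_raters,
      rating_excluded_pairs = rqc$report$excluded_pairs
    )
    jsonlite::write_json(qc_report, file.path(config$out_dir,
                                              "qc_report.json"),
                         dataframe = "columns", digits = NA)
    add(file.path(config$out_dir, "qc_report.json"))
    pipe_log(config, "qc: excluded %d participants, %d rater-question pairs",
             nrow(dqc$report$excluded), nrow(rqc$report$excluded_pairs))
  }

  # ---- factor analysis ----
  if (st("factors")) {
    if (is.null(consensus)) stop("run_pipeline: 'factors' needs the 'qc' stage",
                                 call. = FALSE)
    pipe_log(config, "factors: parallel analysis + EFA")
    X <- as.matrix(consensus[, paste0("mean_", efa_questions())])
    colnames(X) <- efa_questions()
    pa <- parallel_analysis(X, n_sim = 500, seed = sub_seed(config$seed, 11))
    nf <- max(pa$n_factors, 2L)  # the motivation space needs two factors
    efa <- fit_efa(X, n_factors = nf)
    scores <- normalize_scores(efa, consensus$scenario_id,
                               consensus$mean_q02)
    add(write_csv_out(scores, file.path(config$out_dir,
                                        "motivation_scores.csv")))
    jsonlite::write_json(
      list(n_factors_suggested = pa$n_factors,
           n_factors_used = nf,
           eigenvalues = efa$eigenvalues,
           loadings = as.data.frame(efa$loadings),
           variance_explained_total = efa$variance_explained_total,
           item_assignment = as.list(efa$item_assignment)),
      file.path(config$out_dir, "factors.json"),
      dataframe = "columns", digits = NA)
    add(file.path(config$out_dir, "factors.json"))

    lmm <- do.call(rbind, lapply(efa_questions(), function(q) {
      mv <- stats::setNames(consensus[[paste0("mean_", q)]],
                            consensus$scenario_id)
      suppressWarnings(motivation_wth_lmm(clean_dec, mv, dimension = q))
    }))
    add(write_csv_out(lmm, file.path(config$out_dir, "lmm_results.csv")))
  }

  # ---- model fitting ----
  fits <- NULL
  if (st("fit")) {
    if (is.null(scores)) stop("run_pipeline: 'fit' needs the 'factors' stage",
                              call. = FALSE)
    pipe_log(config, "fit: %d participants x models {%s}",
             length(unique(clean_dec$participant_id)),
             paste(config$fit_models, collapse = ", "))
    d <- merge(clean_dec,
               data.frame(scenario_id = scores$scenario_id,
                          cost = scores$cost, benefit = scores$benefit,
                          urgency = scores$urgency_bin,
                          stringsAsFactors = FALSE),
               by = "scenario_id")
    fits <- fit_all(d, model_ids = config$fit_models,
                    n_restarts = config$n_restarts,
                    seed = sub_seed(config$seed, 21), loo = config$loo)
    comp <- compare_models(fits)
    add(write_csv_out(fits, file.path(config$out_dir, "fits.csv")))
    add(write_csv_out(comp, file.path(config$out_dir, "comparison.csv")))
  }

  # ---- representational spaces ----
  if (st("spaces")) {
    if (is.null(scores)) stop("run_pipeline: 'spaces' needs the 'factors'
                              stage", call. = FALSE)
    pipe_log(config, "spaces: RDMs, MDS, RSA (%d permutations)",
             config$n_perm)
    wmat <- tapply(clean_dec$wth_code,
                   list(clean_dec$participant_id, clean_dec$scenario_id),
                   mean)
    rdm_dec <- suppressWarnings(decision_rdm(wmat))
    mot <- motivation_rdms(scores)
    emb_cols <- grep("^e[0-9]+$", names(study$scenarios), value = TRUE)
    emb <- as.matrix(study$scenarios[, emb_cols])
    rownames(emb) <- study$scenarios$scenario_id
    sem <- semantic_space(emb, seed = sub_seed(config$seed, 31))
    ord <- match(colnames(rdm_dec), scores$scenario_id)
    rdm_mot <- mot$full[ord, ord]
    rdm_ben <- mot$benefit[ord, ord]
    rdm_cost <- mot$cost[ord, ord]
    sord <- match(colnames(rdm_dec), study$scenarios$scenario_id)
    rdm_sem <- sem$rdm[sord, sord]

    add(write_matrix_out(rdm_dec, file.path(config$out_dir,
                                            "rdm_decision.csv")))
    add(write_matrix_out(rdm_mot, file.path(config$out_dir,
                                            "rdm_motivation.csv")))
    add(write_matrix_out(rdm_ben, file.path(config$out_dir,
                                            "rdm_benefit.csv")))
    add(write_matrix_out(rdm_cost, file.path(config$out_dir, "rdm_cost.csv")))
    add(write_matrix_out(rdm_sem, file.path(config$out_dir,
                                            "rdm_semantic.csv")))
    coords <- mds_embed(rdm_dec, seed = sub_seed(config$seed, 32))
    coords$scenario_id <- colnames(rdm_dec)
    add(write_csv_out(coords, file.path(config$out_dir,
                                        "coords_decision.csv")))
    add(write_csv_out(sem$embedding, file.path(config$out_dir,
                                               "coords_semantic.csv")))

    pairs <- list(
      decision_vs_motivation = list(rdm_dec, rdm_mot),
      decision_vs_semantic = list(rdm_dec, rdm_sem),
      motivation_vs_semantic = list(rdm_mot, rdm_sem)
    )
    rsa_res <- lapply(names(pairs), function(nm) {
      res <- rsa(pairs[[nm]][[1]], pairs[[nm]][[2]],
                 n_perm = config$n_perm, seed = sub_seed(config$seed, 33))
      list(pair = nm, r = res$r, p = res$p,
           n_permutations = res$n_permutations)
    })
    jsonlite::write_json(rsa_res, file.path(config$out_dir,
                                            "rsa_results.json"),
                         auto_unbox = TRUE, digits = NA)
    add(file.path(config$out_dir, "rsa_results.json"))

    mean_wth <- tapply(clean_dec$wth_code, clean_dec$scenario_id, mean)
    mean_wth <- as.numeric(mean_wth[colnames(rdm_dec)])
    dec <- decompose_decision_rdm(rdm_dec, mean_wth)
    preds <- list(benefit = rdm_ben, cost = rdm_cost, semantic = rdm_sem)
    reg1 <- rdm_regression(dec$wth, preds)
    reg2 <- rdm_regression(dec$residual, preds)
    jsonlite::write_json(list(wth_rdm = reg1, residual_rdm = reg2),
                         file.path(config$out_dir, "rdm_regressions.json"),
                         dataframe = "columns", digits = NA)
    add(file.path(config$out_dir, "rdm_regressions.json"))

    qmean <- stats::setNames(scores$quadrant, scores$scenario_id)
    qa <- quadrant_anova(mean_wth, qmean[colnames(rdm_dec)])
    jsonlite::write_json(list(F = qa$F, df1 = qa$df1, df2 = qa$df2, p = qa$p,
                              eta_sq_partial = qa$eta_sq_partial,
                              posthoc = qa$posthoc),
                         file.path(config$out_dir, "quadrant_anova.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
    add(file.path(config$out_dir, "quadrant_anova.json"))
  }

  # ---- individual differences ----
  if (st("traits")) {
    if (is.null(fits)) stop("run_pipeline: 'traits' needs the 'fit' stage",
                            call. = FALSE)
    pipe_log(config, "traits: correlations and group tests")
    per_p <- stats::aggregate(wth_code ~ participant_id, data = clean_dec,
                              FUN = mean)
    names(per_p)[2] <- "mean_wth"
    tt <- merge(per_p, study$traits, by = "participant_id")
    best <- if ("2.0" %in% config$fit_models) "2.0" else config$fit_models[1]
    f2 <- fits[fits$model_id == best, c("participant_id", "w_cost", "b")]
    tt <- merge(tt, f2, by = "participant_id")
    trait_cols <- intersect(c("iri_ec", "svo", "rr", "bis",
                              "bfi_agreeableness"), names(tt))
    fam <- length(trait_cols)
    cors <- list()
    for (tr in trait_cols) {
      for (vv in c("mean_wth", "w_cost", "b")) {
        if (!vv %in% names(tt)) next
        res <- correlate(tt[[vv]], tt[[tr]], n_perm = config$n_perm,
                         n_boot = config$n_perm, family_size = fam,
                         seed = sub_seed(config$seed, 41))
        cors[[length(cors) + 1L]] <- data.frame(
          variable = vv, trait = tr, r = res$r, p = res$p, p_adj = res$p_adj,
          ci_lo = res$ci[1], ci_hi = res$ci[2], n = res$n,
          stringsAsFactors = FALSE)
      }
    }
    add(write_csv_out(do.call(rbind, cors),
                      file.path(config$out_dir, "correlations.csv")))
    gt <- list()
    for (dem in intersect(c("sex", "gender", "race", "education", "income",
                            "ethnicity"), names(tt))) {
      sizes <- table(tt[[dem]])
      usable <- names(sizes)[sizes >= 3]
      sel <- tt[[dem]] %in% usable
      if (length(usable) < 2) next
      res <- group_compare(tt$mean_wth[sel], tt[[dem]][sel])
      gt[[length(gt) + 1L]] <- data.frame(
        variable = dem, test = res$test, statistic = res$statistic,
        p = res$p, stringsAsFactors = FALSE)
    }
    if (length(gt) > 0) {
      add(write_csv_out(do.call(rbind, gt),
                        file.path(config$out_dir, "group_tests.csv")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("helpcb")),
    seed = config$seed,
    stages = config$stages,
    synthetic = config$synthetic,
    outputs = basename(outputs),
    md5 = as.list(tools::md5sum(outputs))
  )
  names(manifest$md5) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log(config, "done: %d outputs in %s", length(outputs), config$out_dir)
  invisible(manifest)
}
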