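#' Decision-space dissimilarity matrix
#'
#' Pairwise scenario dissimilarity from the participant x scenario WTH codes:
#' for scenarios x and y, over the n participants who rated both,
#' \deqn{F(S_x, S_y) = (1/n) [ 0.5 \sum_i |WTH_{i,x} - WTH_{i,y}|
#'   + 0.5 | \sum_i (WTH_{i,x} - WTH_{i,y}) | ].}
#' The unsigned term captures rater-level divergence, the signed term the
#' difference in average WTH; both are computed over the same joint rater
#' set.
#'
#' @param wth numeric matrix, participants x scenarios, NA where a
#'   participant did not rate a scenario.
#' @param min_overlap warn when some pair has fewer joint raters than this
#'   (default 5).
#' @return symmetric dissimilarity matrix (class matrix) with the scenario
#'   columns' names.
#' @export
decision_rdm <- function(wth, min_overlap = 5) {
  wth <- as.matrix(wth)
  ns <- ncol(wth)
  rdm <- matrix(0, ns, ns, dimnames = list(colnames(wth), colnames(wth)))
  min_n <- Inf
  for (x in seq_len(ns - 1)) {
    for (y in (x + 1):ns) {
      joint <- !is.na(wth[, x]) & !is.na(wth[, y])
      n <- sum(joint)
      if (n == 0) {
        stop(sprintf("decision_rdm: no joint raters for pair (%d, %d)", x, y),
             call. = FALSE)
      }
      min_n <- min(min_n, n)
      d <- wth[joint, x] - wth[joint, y]
      rdm[x, y] <- rdm[y, x] <- (0.5 * sum(abs(d)) + 0.5 * abs(sum(d))) / n
    }
  }
  if (ns > 1 && min_n < min_overlap) {
    warning(sprintf("decision_rdm: minimum pair overlap is %d raters", min_n))
  }
  check_rdm(rdm, "decision_rdm")
  rdm
}

#' Motivation-space dissimilarity matrices
#'
#' The full motivation RDM is the Euclidean distance between scenarios in the
#' (benefit, cost) plane; the benefit and cost RDMs are the absolute
#' differences along each axis.
#'
#' @param scores data frame with `scenario_id`, `benefit`, `cost`.
#' @return list of matrices `full`, `benefit`, `cost`.
#' @export
motivation_rdms <- function(scores) {
  ids <- scores$scenario_id
  full <- as.matrix(stats::dist(cbind(scores$benefit, scores$cost)))
  ben <- abs(outer(scores$benefit, scores$benefit, "-"))
  cost <- abs(outer(scores$cost, scores$cost, "-"))
  dimnames(full) <- dimnames(ben) <- dimnames(cost) <- list(ids, ids)
  lapply(list(full = full, benefit = ben, cost = cost), function(m) {
    check_rdm(m); m
  })
}

#' Semantic space from scenario embeddings
#'
#' Cosine distances between the high-dimensional scenario embeddings are
#' embedded in 2-D by metric multidimensional scaling; the semantic RDM is
#' the Euclidean distance between scenarios in that plane, and semantic
#' clusters come from Ward agglomerative clustering of the 2-D coordinates.
#'
#' @param embeddings numeric matrix, scenarios x d (d >= 2), no zero rows.
#' @param n_clusters number of agglomerative clusters (default 12).
#' @param seed accepted for interface stability; the embedding is
#'   deterministic.
#' @return list with `embedding` (data frame scenario_id, dim1, dim2,
#'   method, stress), `rdm`, `clusters` (integer labels).
#' @export
semantic_space <- function(embeddings, n_clusters = 12, seed = 1) {
  emb <- as.matrix(embeddings)
  if (ncol(emb) < 2) stop("semantic_space: embedding dim must be >= 2",
                          call. = FALSE)
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) {
    bad <- rownames(emb)[nrm == 0] %||% which(nrm == 0)
    stop(sprintf("semantic_space: zero-norm embedding for scenario(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cosd <- 1 - tcrossprod(emb / nrm)
  cosd <- pmax((cosd + t(cosd)) / 2, 0)
  diag(cosd) <- 0
  emb2 <- mds_embed(cosd, seed = seed)
  coords <- as.matrix(emb2[, c("dim1", "dim2")])
  rdm <- as.matrix(stats::dist(coords))
  dimnames(rdm) <- list(rownames(emb), rownames(emb))
  check_rdm(rdm, "semantic_rdm")
  cl <- stats::cutree(stats::hclust(stats::dist(coords), method = "ward.D2"),
                      k = n_clusters)
  emb2$scenario_id <- rownames(emb) %||% as.character(seq_len(nrow(emb)))
  list(embedding = emb2, rdm = rdm, clusters = unname(cl))
}

#' Metric MDS embedding of a dissimilarity matrix
#'
#' Classical (Torgerson) scaling of a precomputed dissimilarity matrix to
#' `k` dimensions, with the stress-1 of the configuration reported.
#'
#' @param rdm symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k embedding dimension (default 2).
#' @param seed accepted for interface stability; classical scaling is
#'   deterministic.
#' @return data frame with columns `dim1..dimk`, `method`, `stress`.
#' @export
mds_embed <- function(rdm, k = 2, seed = 1) {
  check_rdm(rdm, "mds_embed")
  coords <- stats::cmdscale(stats::as.dist(rdm), k = k)
  if (ncol(coords) < k) {  # degenerate (e.g. all-zero) input
    coords <- cbind(coords, matrix(0, nrow(rdm), k - ncol(coords)))
  }
  dhat <- as.matrix(stats::dist(coords))
  denom <- sum(rdm^2)
  stress <- if (denom == 0) 0 else sqrt(sum((rdm - dhat)^2) / denom)
  out <- as.data.frame(coords)
  names(out) <- paste0("dim", seq_len(k))
  out$method <- "mds"
  out$stress <- stress
  out
}

#' Representational similarity analysis between two RDMs
#'
#' Pearson correlation of the upper-triangle vectors, with significance from
#' a scenario-label permutation null: each permutation re-orders the rows and
#' columns of the second RDM jointly and recomputes the correlation; the
#' p-value is the proportion of null correlations strictly greater than the
#' observed one (one-sided, per the strict definition; `smoothed = TRUE`
#' applies the (s+1)/(N+1) correction to avoid exact zeros).
#'
#' @param rdm_a,rdm_b RDMs over the same scenario order (n >= 4).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param smoothed use the add-one p-value (default FALSE).
#' @return list with `r`, `p`, `n_permutations`, `null` (the null
#'   correlations).
#' @export
rsa <- function(rdm_a, rdm_b, n_perm = 5000, seed = 1, smoothed = FALSE) {
  check_rdm(rdm_a, "rsa rdm_a"); check_rdm(rdm_b, "rsa rdm_b")
  n <- nrow(rdm_a)
  if (n < 4) stop("rsa: need at least 4 scenarios", call. = FALSE)
  if (nrow(rdm_b) != n) stop("rsa: RDM sizes differ", call. = FALSE)
  va <- upper_vec(rdm_a)
  vb <- upper_vec(rdm_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("rsa: constant upper triangle, correlation undefined", call. = FALSE)
  }
  r_obs <- stats::cor(va, vb)
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    null[i] <- stats::cor(va, upper_vec(rdm_b[perm, perm]))
  }
  p <- if (smoothed) (sum(null > r_obs) + 1) / (n_perm + 1)
    else mean(null > r_obs)
  list(r = r_obs, p = p, n_permutations = n_perm, null = null)
}

#' Decompose the decision RDM into mean-WTH and residual components
#'
#' The WTH RDM holds the absolute differences of the per-scenario mean WTH;
#' the residual RDM holds the residuals of an OLS fit (with intercept) of the
#' decision-RDM upper triangle on the WTH-RDM upper triangle, reassembled as
#' a symmetric matrix with a zero diagonal.
#'
#' @param rdm_decision decision RDM.
#' @param mean_wth per-scenario mean WTH, in the RDM's scenario order.
#' @return list with `wth` and `residual` matrices plus the fitted `intercept`
#'   and `slope`.
#' @export
decompose_decision_rdm <- function(rdm_decision, mean_wth) {
  check_rdm(rdm_decision, "decompose_decision_rdm")
  n <- nrow(rdm_decision)
  if (length(mean_wth) != n) {
    stop("decompose_decision_rdm: mean_wth length mismatch", call. = FALSE)
  }
  wth <- abs(outer(mean_wth, mean_wth, "-"))
  dimnames(wth) <- dimnames(rdm_decision)
  y <- upper_vec(rdm_decision)
  x <- upper_vec(wth)
  fit <- stats::lm(y ~ x)
  resid_m <- matrix(0, n, n, dimnames = dimnames(rdm_decision))
  resid_m[upper.tri(resid_m)] <- stats::residuals(fit)
  resid_m <- resid_m + t(resid_m)
  list(wth = wth, residual = resid_m,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Multiple regression between RDMs
#'
#' OLS of the target RDM's upper triangle on the predictors' upper triangles,
#' all z-scored, so the coefficients are standardized betas; intercept
#' included (zero after standardization).
#'
#' @param target target RDM or an already-symmetric residual matrix.
#' @param predictors named list of predictor RDMs in the same scenario order.
#' @param conf_level confidence level of the reported intervals
#'   (default 0.95).
#' @return data frame (term, beta, se, ci_lo, ci_hi, p).
#' @export
rdm_regression <- function(target, predictors, conf_level = 0.95) {
  y <- scale(upper_vec(target))[, 1]
  Xl <- lapply(predictors, function(m) scale(upper_vec(m))[, 1])
  X <- do.call(cbind, Xl)
  colnames(X) <- names(predictors) %||% paste0("p", seq_along(Xl))
  kappa_x <- kappa(cbind(1, X))
  if (kappa_x > 1e8) {
    warning(sprintf("rdm_regression: predictors nearly collinear (condition
                    number %.2e)", kappa_x))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  data.frame(
    term = c("(intercept)", colnames(X)),
    beta = unname(sm[, 1]),
    se = unname(sm[, 2]),
    ci_lo = unname(ci[, 1]),
    ci_hi = unname(ci[, 2]),
    p = unname(sm[, 4]),
    stringsAsFactors = FALSE
  )
}

#' Welch ANOVA over motivation quadrants with Games-Howell post hoc
#'
#' Welch's heteroscedasticity-robust one-way ANOVA of the per-scenario mean
#' WTH across the four motivation-space quadrants, an approximate partial
#' eta-squared, and Games-Howell pairwise comparisons (studentized-range
#' based, Welch-Satterthwaite degrees of freedom).
#'
#' @param values numeric response (per-scenario mean WTH).
#' @param groups group labels (quadrants).
#' @return list with `F`, `df1`, `df2`, `p`, `eta_sq_partial` and `posthoc`
#'   data frame (group1, group2, diff, se, q, df, p_adj).
#' @export
quadrant_anova <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop(sprintf("quadrant_anova: group(s) with fewer than 2 members: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
         call. = FALSE)
  }
  w <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  f <- unname(w$statistic)
  df1 <- unname(w$parameter[1]); df2 <- unname(w$parameter[2])
  eta <- (f * df1) / (f * df1 + df2)
  lev <- levels(groups)
  k <- length(lev)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  ns <- as.numeric(sizes)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- vars[i] / ns[i] + vars[j] / ns[j]
      se <- sqrt(se2)
      df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                       (vars[j] / ns[j])^2 / (ns[j] - 1))
      diff <- means[j] - means[i]
      q <- abs(diff) / sqrt(se2 / 2)
      p_adj <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lev[i], group2 = lev[j], diff = unname(diff),
        se = unname(se), q = unname(q), df = unname(df),
        p_adj = unname(p_adj), stringsAsFactors = FALSE
      )
    }
  }
  list(F = f, df1 = df1, df2 = df2, p = unname(w$p.value),
       eta_sq_partial = eta, posthoc = do.call(rbind, rows))
}
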