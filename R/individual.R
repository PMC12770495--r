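#' Pearson correlation with permutation p and bootstrap CI
#'
#' Pearson's r with a two-sided permutation p-value (one vector shuffled,
#' compared on |r|), a percentile bootstrap confidence interval, and an
#' optional Bonferroni adjustment for the test's family size.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped,
#'   n >= 5 required).
#' @param n_perm permutations (default 5000).
#' @param n_boot bootstrap resamples (default 5000).
#' @param family_size number of tests in the Bonferroni family (default 1).
#' @param seed integer seed.
#' @param conf_level CI level (default 0.95).
#' @return list with `r`, `p`, `p_adj`, `ci`, `n`.
#' @export
correlate <- function(x, y, n_perm = 5000, n_boot = 5000, family_size = 1,
                      seed = 1, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("correlate: need at least 5 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate: zero variance, correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null[i] <- stats::cor(x, y[sample.int(n)])
  }
  p <- mean(abs(null) >= abs(r))
  boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    boot[i] <- if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0)
      NA_real_ else stats::cor(x[idx], y[idx])
  }
  alpha <- 1 - conf_level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(r = r, p = p, p_adj = min(1, p * family_size), ci = ci, n = n)
}

# D'Agostino-Pearson omnibus normality test: combines the skewness and
# kurtosis z-statistics into K2 ~ chi-squared(2).
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) return(list(K2 = NA_real_, p = NA_real_))
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / a + sqrt((Y / a)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- -6 / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  list(K2 = K2, p = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Group comparison with Welch tests and assumption diagnostics
#'
#' Two groups: Welch's two-sided t-test; more than two: Welch's one-way
#' ANOVA. Normality (D'Agostino-Pearson omnibus per group) and variance
#' homogeneity (Levene for two groups, Bartlett for more) diagnostics are
#' reported alongside.
#'
#' @param values numeric response.
#' @param groups group labels; every group needs n >= 3.
#' @return list with `test` ("welch_t" or "welch_anova"), `statistic`, `df`
#'   (or `df1`/`df2`), `p`, and `diagnostics` (normality p per group,
#'   variance-test p).
#' @export
group_compare <- function(values, groups) {
  groups <- droplevels(factor(groups))
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("group_compare: need >= 2 groups",
                                call. = FALSE)
  if (any(sizes < 3)) {
    stop(sprintf("group_compare: group(s) with n < 3: %s",
                 paste(names(sizes)[sizes < 3], collapse = ", ")),
         call. = FALSE)
  }
  norm_p <- vapply(levels(groups), function(g) {
    dagostino_pearson(values[groups == g])$p
  }, numeric(1))
  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = FALSE)
    var_test <- tryCatch(
      car::leveneTest(values ~ groups)[1, "Pr(>F)"],
      error = function(e) NA_real_
    )
    list(test = "welch_t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = unname(tt$p.value),
         diagnostics = list(normality_p = norm_p, variance_p = var_test,
                            variance_test = "levene"))
  } else {
    w <- stats::oneway.test(values ~ groups, var.equal = FALSE)
    var_test <- tryCatch(
      stats::bartlett.test(values ~ groups)$p.value,
      error = function(e) NA_real_
    )
    list(test = "welch_anova", statistic = unname(w$statistic),
         df1 = unname(w$parameter[1]), df2 = unname(w$parameter[2]),
         p = unname(w$p.value),
         diagnostics = list(normality_p = norm_p, variance_p = var_test,
                            variance_test = "bartlett"))
  }
}

#' Cohen's d between two groups
#'
#' Standardized mean difference with the pooled standard deviation.
#'
#' @param high,low numeric vectors.
#' @return scalar d (positive when `high` has the larger mean).
#' @export
cohens_d <- function(high, low) {
  n1 <- length(high); n2 <- length(low)
  sp <- sqrt(((n1 - 1) * stats::var(high) + (n2 - 1) * stats::var(low)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(high) - mean(low)) / sp
}

#' Trait-by-category effect-size grid
#'
#' For each trait, participants are median-split into high (strictly above
#' the median) and low groups; for each scenario category, the two groups'
#' per-participant mean WTH ratings are compared by Cohen's d (positive d:
#' the high-trait group is more willing to help). Optional bootstrap CIs.
#'
#' @param decisions clean decision table (`participant_id`, `scenario_id`,
#'   `wth_code`).
#' @param traits data frame with `participant_id` and one column per trait.
#' @param categories named vector: category label per scenario_id.
#' @param trait_names which trait columns to use (default: all numeric).
#' @param n_boot bootstrap resamples for the CI (0 to skip, default 0).
#' @param seed integer seed (bootstrap only).
#' @param conf_level CI level.
#' @return data frame (trait, category, d, ci_lo, ci_hi, n_high, n_low);
#'   cells with an empty group are NA.
#' @export
trait_effect_grid <- function(decisions, traits, categories,
                              trait_names = NULL, n_boot = 0, seed = 1,
                              conf_level = 0.95) {
  if (is.null(trait_names)) {
    trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
    trait_names <- setdiff(trait_names, "participant_id")
  }
  decisions$category <- categories[decisions$scenario_id]
  cats <- sort(unique(stats::na.omit(decisions$category)))
  # per participant x category mean WTH
  agg <- stats::aggregate(wth_code ~ participant_id + category,
                          data = decisions, FUN = mean)
  set.seed(seed)
  rows <- list()
  for (tr in trait_names) {
    tv <- traits[[tr]]
    names(tv) <- traits$participant_id
    med <- stats::median(tv, na.rm = TRUE)
    hi_ids <- traits$participant_id[!is.na(tv) & tv > med]
    lo_ids <- traits$participant_id[!is.na(tv) & tv <= med]
    for (ct in cats) {
      a <- agg[agg$category == ct, ]
      high <- a$wth_code[a$participant_id %in% hi_ids]
      low <- a$wth_code[a$participant_id %in% lo_ids]
      if (length(high) == 0 || length(low) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, category = ct, d = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, n_high = length(high), n_low = length(low),
          stringsAsFactors = FALSE)
        next
      }
      d <- cohens_d(high, low)
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0) {
        bd <- numeric(n_boot)
        for (i in seq_len(n_boot)) {
          bd[i] <- cohens_d(sample(high, replace = TRUE),
                            sample(low, replace = TRUE))
        }
        alpha <- 1 - conf_level
        ci <- stats::quantile(bd, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, category = ct, d = d, ci_lo = ci[1], ci_hi = ci[2],
        n_high = length(high), n_low = length(low), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
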