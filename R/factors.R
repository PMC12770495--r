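#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix against the
#' rank-wise mean (or another quantile) of eigenvalues from simulated
#' standard-normal datasets of identical shape. Factors are retained from the
#' first rank down, as long as the observed eigenvalue exceeds the simulated
#' reference at the same rank.
#'
#' @param X numeric matrix/data frame, observations x variables.
#' @param n_sim number of simulated datasets (default 500, minimum 100).
#' @param seed integer seed for the simulations.
#' @param quantile NULL for the mean criterion (default), or a probability
#'   (e.g. 0.95) to compare against that simulated quantile.
#' @return list with `n_factors`, `observed` and `reference` eigenvalues.
#' @export
parallel_analysis <- function(X, n_sim = 500, seed = 1, quantile = NULL) {
  X <- as.matrix(X)
  if (n_sim < 100) stop("parallel_analysis: n_sim must be >= 100",
                        call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop(sprintf("parallel_analysis: constant column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sims <- matrix(NA_real_, n_sim, p)
  for (s in seq_len(n_sim)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    sims[s, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  ref <- if (is.null(quantile)) colMeans(sims)
    else apply(sims, 2, stats::quantile, probs = quantile)
  above <- obs > ref
  n_factors <- which(c(!above, TRUE))[1] - 1L
  list(n_factors = as.integer(n_factors), observed = obs, reference = ref)
}

# Minimum-residual (minres) factor extraction: choose uniquenesses u to
# minimize the sum of squared off-diagonal residuals of R - L L', where L is
# built from the leading eigenpairs of R with communalities 1 - u on the
# diagonal.
minres_extract <- function(R, n_factors) {
  p <- ncol(R)
  load_from_psi <- function(psi) {
    Rr <- R
    diag(Rr) <- 1 - psi
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(vals), n_factors)
    L
  }
  obj <- function(psi) {
    L <- load_from_psi(psi)
    resid <- R - tcrossprod(L)
    sum(resid[upper.tri(resid)]^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = rep(0.005, p), upper = rep(0.995, p),
                      control = list(maxit = 1000))
  if (opt$convergence != 0) {
    stop(sprintf("minres_extract: no convergence (optim code %d)",
                 opt$convergence), call. = FALSE)
  }
  list(loadings = load_from_psi(opt$par), uniquenesses = opt$par,
       converged = TRUE)
}

#' Exploratory factor analysis of the motivation consensus matrix
#'
#' Minimum-residual extraction (maximum likelihood via [stats::factanal()]
#' available as an option) followed by varimax (orthogonal, default) or
#' promax (oblique) rotation. Factor signs are fixed so each factor's largest
#' |loading| item loads positively. Factor scores use the Thurstone
#' regression estimator; items are assigned to the factor on which their
#' loading is maximal, provided |loading| > 0.3.
#'
#' @param X numeric matrix/data frame, scenarios x items (standardized
#'   internally).
#' @param n_factors number of factors (>= 1).
#' @param rotation "varimax" (default) or "promax".
#' @param method "minres" (default) or "ml".
#' @return object of class `factor_solution`: loadings, eigenvalues,
#'   factor correlation `Phi`, Thurstone `scores`, `variance_explained_total`
#'   (rotated sums of squared loadings over the number of items),
#'   `item_assignment`, `uniquenesses`.
#' @export
fit_efa <- function(X, n_factors, rotation = c("varimax", "promax"),
                    method = c("minres", "ml")) {
  rotation <- match.arg(rotation)
  method <- match.arg(method)
  X <- as.matrix(X)
  if (n_factors < 1) stop("fit_efa: n_factors must be >= 1", call. = FALSE)
  Z <- scale(X)
  R <- stats::cor(X)
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  L0 <- if (method == "minres") {
    minres_extract(R, n_factors)$loadings
  } else {
    fa <- stats::factanal(covmat = R, factors = n_factors, rotation = "none")
    matrix(fa$loadings, ncol = n_factors)
  }
  rownames(L0) <- colnames(X)
  Phi <- diag(n_factors)
  if (n_factors == 1) {
    L <- L0
  } else if (rotation == "varimax") {
    rot <- stats::varimax(L0)
    L <- L0 %*% rot$rotmat
  } else {
    rot <- stats::promax(L0)
    L <- matrix(rot$loadings, ncol = n_factors,
                dimnames = dimnames(L0))
    U <- rot$rotmat
    Phi <- solve(crossprod(U))
    Phi <- stats::cov2cor(Phi)
  }
  # sign convention: dominant item of each factor loads positively
  for (f in seq_len(n_factors)) {
    dom <- which.max(abs(L[, f]))
    if (L[dom, f] < 0) {
      L[, f] <- -L[, f]
      Phi[f, ] <- -Phi[f, ]
      Phi[, f] <- -Phi[, f]
    }
  }
  colnames(L) <- paste0("F", seq_len(n_factors))
  # Thurstone (regression) scores; structure = L %*% Phi (equals L when
  # orthogonal)
  St <- L %*% Phi
  W <- solve(R, St)
  scores <- Z %*% W
  colnames(scores) <- colnames(L)
  assign_f <- apply(L, 1, function(row) {
    f <- which.max(abs(row))
    if (abs(row[f]) > 0.3) colnames(L)[f] else NA_character_
  })
  out <- list(
    loadings = L,
    eigenvalues = eigenvalues,
    n_factors = as.integer(n_factors),
    rotation = rotation,
    method = method,
    Phi = Phi,
    scores = scores,
    variance_explained_total = sum(colSums(L^2)) / ncol(X),
    item_assignment = assign_f,
    uniquenesses = 1 - rowSums(L^2)
  )
  class(out) <- "factor_solution"
  out
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d factor(s), %s rotation (%s extraction)\n",
              x$n_factors, x$rotation, x$method))
  cat(sprintf("  total variance explained: %.1f%%\n",
              100 * x$variance_explained_total))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tucker congruence coefficient
#'
#' Similarity of two loading vectors, invariant to scaling;
#' |congruence| near 1 indicates factor recovery.
#'
#' @param a,b numeric vectors (loadings on one factor).
#' @return scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Normalized motivation scores, urgency split and quadrants
#'
#' Min-max normalizes the benefit and cost factor scores to \[0, 1\],
#' dichotomizes the consensus urgency by a median split (strictly above the
#' median = 1), and partitions scenarios into four quadrants by the per-factor
#' medians: LL (low benefit, low cost), LH (low benefit, high cost), HL, HH,
#' "high" meaning strictly above the median.
#'
#' @param solution a `factor_solution` whose scores include the benefit and
#'   cost factors.
#' @param scenario_id character vector of scenario ids, parallel to the score
#'   rows.
#' @param urgency consensus urgency rating per scenario.
#' @param cost_item name of the self-cost item used to identify which factor
#'   is the cost factor (default "q05"); the other factor is benefit.
#' @return data frame (scenario_id, benefit, cost, urgency_bin, quadrant).
#' @export
normalize_scores <- function(solution, scenario_id, urgency,
                             cost_item = "q05") {
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$n_factors != 2) {
    stop("normalize_scores: expects a 2-factor solution", call. = FALSE)
  }
  L <- solution$loadings
  if (!cost_item %in% rownames(L)) {
    stop(sprintf("normalize_scores: cost item '%s' not among loadings",
                 cost_item), call. = FALSE)
  }
  cost_f <- which.max(abs(L[cost_item, ]))
  ben_f <- setdiff(1:2, cost_f)
  benefit <- min_max(solution$scores[, ben_f])
  cost <- min_max(solution$scores[, cost_f])
  mb <- stats::median(benefit)
  mc <- stats::median(cost)
  quadrant <- paste0(ifelse(benefit > mb, "H", "L"),
                     ifelse(cost > mc, "H", "L"))
  # label order: benefit then cost
  data.frame(
    scenario_id = scenario_id,
    benefit = benefit,
    cost = cost,
    urgency_bin = as.integer(urgency > stats::median(urgency)),
    quadrant = quadrant,
    stringsAsFactors = FALSE
  )
}

#' Mixed-model association of one motivation with WTH
#'
#' Fits `WTH ~ 1 + motivation + (1 + motivation | participant)` by REML with
#' lme4 and reports the fixed slope plus the Nakagawa marginal and
#' conditional R2 (random-slope variance handled by averaging the
#' per-observation random-effect variance over the design).
#'
#' @param decisions clean decision table with `participant_id`, `scenario_id`
#'   and `wth_code`.
#' @param motivation named numeric vector: consensus value per scenario_id.
#' @param dimension label stored in the result.
#' @return data frame row: dimension, slope, marginal_R2, conditional_R2,
#'   singular flag.
#' @export
motivation_wth_lmm <- function(decisions, motivation, dimension = "motivation") {
  d <- decisions
  d$m <- as.numeric(motivation[d$scenario_id])
  if (any(is.na(d$m))) {
    stop("motivation_wth_lmm: motivation missing for some scenarios",
         call. = FALSE)
  }
  if (stats::sd(d$m) == 0) {
    return(data.frame(dimension = dimension, slope = 0,
                      marginal_R2 = 0, conditional_R2 = NA_real_,
                      singular = TRUE, stringsAsFactors = FALSE))
  }
  fit <- suppressMessages(
    lme4::lmer(wth_code ~ 1 + m + (1 + m | participant_id), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4)))
  )
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning(sprintf("motivation_wth_lmm: singular fit for %s", dimension))
  }
  beta <- lme4::fixef(fit)
  Xf <- stats::model.matrix(fit)
  var_f <- stats::var(as.vector(Xf %*% beta))
  vc <- lme4::VarCorr(fit)$participant_id
  Sigma <- matrix(as.numeric(vc), 2, 2)
  Zr <- cbind(1, d$m)
  var_r <- mean(rowSums((Zr %*% Sigma) * Zr))
  var_e <- attr(lme4::VarCorr(fit), "sc")^2
  tot <- var_f + var_r + var_e
  data.frame(
    dimension = dimension,
    slope = unname(beta["m"]),
    marginal_R2 = var_f / tot,
    conditional_R2 = (var_f + var_r) / tot,
    singular = singular,
    stringsAsFactors = FALSE
  )
}
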