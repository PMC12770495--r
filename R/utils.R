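#' Min-max normalization to [0, 1]
#'
#' Linearly rescales a numeric vector so its minimum maps to 0 and its maximum
#' to 1. Used to put factor scores (benefit, cost) on the common scale the
#' utility models expect.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector in \[0, 1\].
#' @export
min_max <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("min_max: `x` must be finite numeric", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("min_max: zero range, normalization undefined", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Upper-triangle (diagonal excluded) of a square matrix as a vector,
# column-major order; the fixed vectorization used for all RDM comparisons.
upper_vec <- function(m) {
  m[upper.tri(m, diag = FALSE)]
}

# Validate an RDM: square, symmetric, zero diagonal, non-negative, finite.
check_rdm <- function(m, label = "rdm") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s: must be a square matrix", label), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(sprintf("%s: non-finite entries", label), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop(sprintf("%s: not symmetric", label), call. = FALSE)
  }
  if (max(abs(diag(m))) > 1e-8) {
    stop(sprintf("%s: non-zero diagonal", label), call. = FALSE)
  }
  if (min(m) < -1e-8) {
    stop(sprintf("%s: negative dissimilarities", label), call. = FALSE)
  }
  invisible(TRUE)
}

# Derived sub-stream seeds: one global seed, fixed offsets per stage so each
# table can be regenerated independently of the others.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
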