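## Small shared helpers.

#' Derive a reproducible substream seed from a master seed
#'
#' Stage-level reruns must be reproducible on their own, so every stochastic
#' stage draws its seed deterministically from the master seed and a stage
#' label rather than consuming a shared RNG stream.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(label) == 1)
  h <- sum(as.integer(charToRaw(as.character(label))) *
             (seq_along(charToRaw(as.character(label))) %% 97 + 1))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == floor(x) && x >= 0

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cronbach's alpha of a set of items/variables
#' @param x numeric matrix or data.frame (rows = participants).
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  stopifnot(k >= 2)
  v <- stats::var(x)
  k / (k - 1) * (1 - sum(diag(v)) / sum(v))
}

#' Symmetric inverse square root of a positive-definite matrix
#' @keywords internal
inv_sqrt_sym <- function(m, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(e$values < tol * max(e$values))) {
    stop("matrix is numerically singular; cannot form inverse square root")
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}
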