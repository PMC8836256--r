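# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Fisher-transform confidence interval for a correlation coefficient
#'
#' @param r correlation estimate in (-1, 1).
#' @param n number of paired observations (must exceed 3).
#' @param conf confidence level.
#' @return length-2 numeric vector (lower, upper); `NA` when undefined.
#' @keywords internal
fisher_ci <- function(r, n, conf = 0.95) {
  if (is.na(r) || n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

# Deterministic per-stage seed derived from a single global seed, so that
# pipeline stages are independently reproducible.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483646 + 1)
}

# Spearman rank correlation; returns NA (not zero) when either vector is
# constant, because the coefficient is undefined there.
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("spearman_rho: length mismatch (%d vs %d)", length(x), length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}
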