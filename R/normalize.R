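# Trimmed mean of M-values, implemented from the published algorithm:
# pairwise M (log2 ratio of library-scaled proportions) and A (average
# log2 abundance) against a reference sample, double trimming, and a
# precision-weighted mean with inverse approximate binomial variances.

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (!length(log_r)) {
    warnf("no miRNAs usable for TMM; factor set to 1")
    return(1)
  }
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * trim_m) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  if (!any(keep)) {
    warnf("no miRNAs survive TMM trimming; factor set to 1")
    return(1)
  }
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  f <- 2^f
  if (!is.finite(f)) f <- 1
  f
}

#' TMM scaling factors
#'
#' Computes trimmed-mean-of-M-values normalization factors correcting
#' RNA-composition bias between libraries.  Unless given, the reference
#' sample is the one whose library-scaled 75th count percentile is
#' closest to the mean of those percentiles.  Per sample, M and A values
#' against the reference are doubly trimmed (`trim_m` of M from each
#' tail, `trim_a` of A) and averaged with inverse-variance weights; the
#' returned factors are rescaled to geometric mean 1.
#'
#' @param counts an [ev_counts] object or a numeric count matrix.
#' @param trim_m two-sided trim fraction on M values (default 0.30).
#' @param trim_a two-sided trim fraction on A values (default 0.05).
#' @param ref optional reference sample ID.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  m <- if (inherits(counts, "ev_counts")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) stopf("every sample needs library size > 0")
  if (is.null(ref)) {
    f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
    ref_i <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_i <- match(ref, colnames(m))
    if (is.na(ref_i)) stopf("unknown reference sample '%s'", ref)
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_i) return(1)
    .tmm_pair(m[, j], m[, ref_i], lib[j], lib[ref_i], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' TMM-normalized counts per million
#'
#' CPM on effective library sizes (library size times TMM factor), with a
#' library-size-scaled prior count so downstream log operations are
#' defined at zero counts: with scaled prior p_j the value is
#' `(y + p_j) / (L_j + 2 p_j) * 1e6` where `p_j = prior_count * L_j /
#' mean(L)`.  `prior_count = 0` gives plain CPM (columns sum to 1e6 when
#' all factors are 1).
#'
#' @param counts an [ev_counts] object or numeric count matrix.
#' @param factors per-sample TMM factors (computed if `NULL`).
#' @param prior_count prior count (default 0.5).
#' @return object of class `ev_norm`: list with `values` (CPM matrix),
#'   `tmm_factors`, `library_sizes`, `prior_count`, and `meta` when the
#'   input carried metadata.
#' @export
cpm_matrix <- function(counts, factors = NULL, prior_count = 0.5) {
  m <- if (inherits(counts, "ev_counts")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  if (is.null(factors)) factors <- tmm_factors(m)
  if (length(factors) != ncol(m))
    stopf("factors must align with samples (%d vs %d)",
          length(factors), ncol(m))
  if (any(factors <= 0)) stopf("factors must be positive")
  if (prior_count < 0) stopf("prior_count must be >= 0")
  eff <- lib * factors
  if (any(eff <= 0)) stopf("zero effective library size")
  prior <- prior_count * eff / mean(eff)
  vals <- t((t(m) + prior) / (eff + 2 * prior)) * 1e6
  structure(list(values = vals, tmm_factors = factors,
                 library_sizes = lib, prior_count = prior_count,
                 meta = if (inherits(counts, "ev_counts")) counts$meta else NULL),
            class = "ev_norm")
}

#' @export
print.ev_norm <- function(x, ...) {
  cat(sprintf("ev_norm: %d miRNAs x %d samples (TMM-CPM, prior %.2g)\n",
              nrow(x$values), ncol(x$values), x$prior_count))
  invisible(x)
}
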