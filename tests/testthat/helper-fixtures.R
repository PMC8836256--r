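# Shared fixture builders; everything is generated in code at test time.

# Tiny count container with explicit values.
toy_counts <- function(values, groups) {
  m <- as.matrix(values)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    rownames(m) <- sprintf("miR-%d", seq_len(nrow(m)))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  ev_counts(m, data.frame(sample_id = colnames(m), group = groups,
                          stringsAsFactors = FALSE))
}

# Random NB count fixture for two groups.
nb_fixture <- function(n_mirnas = 200, n_a = 6, n_b = 6, phi = 0.2,
                       depth = 1e5, seed = 1) {
  set.seed(seed)
  w <- 10^runif(n_mirnas, -5, -2)
  w <- w / sum(w)
  n <- n_a + n_b
  mu <- outer(w, rep(depth, n))
  m <- matrix(rnbinom(length(mu), size = 1 / phi, mu = mu),
              n_mirnas, n,
              dimnames = list(sprintf("miR-%04d", seq_len(n_mirnas)),
                              sprintf("S%02d", seq_len(n))))
  toy_counts(m, rep(c("A", "B"), c(n_a, n_b)))
}

# Balanced 2+2+2 outlier injection into the three largest groups,
# mirroring the observed exclusions; returns corrupted counts + truth.
inject_balanced <- function(counts, seed,
                            groups = c("HealthCtl", "HospCtl", "CIS"),
                            per_group = 2, severity = 1) {
  truth <- character(0)
  for (i in seq_along(groups)) {
    inj <- inject_outlier_subjects(counts, per_group, severity,
                                   groups = groups[i], seed = seed * 13 + i)
    counts <- inj$counts
    truth <- c(truth, inj$truth$outlier_subject_ids)
  }
  list(counts = counts, outlier_subject_ids = sort(truth))
}

# Brute-force trapezoidal ROC area by threshold sweep (independent of
# the rank-based implementation).
trapezoid_auc <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
enum_hyper_p <- function(N, K, n, k_obs) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(hits >= k_obs)
}
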