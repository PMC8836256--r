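#' z-score normalized expression across a subject set
#'
#' Per miRNA, `z = (value - mean) / sd` computed across exactly the given
#' subjects (the union of the two compared groups), with the sample
#' (n - 1) standard deviation.  This removes absolute expression-level
#' differences between miRNAs before ROC analysis and panel averaging.
#'
#' @param norm an `ev_norm` object from [cpm_matrix()] or a numeric
#'   matrix of normalized values (rows = miRNAs).
#' @param mirna_ids markers to z-score.
#' @param subjects sample IDs defining the scoring population.
#' @return markers x subjects matrix of z-scores.
#' @export
zscore_markers <- function(norm, mirna_ids, subjects) {
  vals <- if (inherits(norm, "ev_norm")) norm$values else as.matrix(norm)
  bad <- setdiff(mirna_ids, rownames(vals))
  if (length(bad)) stopf("unknown miRNAs: %s", paste(bad, collapse = ", "))
  bad_s <- setdiff(subjects, colnames(vals))
  if (length(bad_s)) stopf("unknown subjects: %s", paste(bad_s, collapse = ", "))
  x <- vals[mirna_ids, subjects, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0))
    stopf("zero standard deviation for: %s",
          paste(mirna_ids[sdv == 0], collapse = ", "))
  (x - mu) / sdv
}

#' ROC area under the curve with Mann-Whitney p-value
#'
#' AUC is the Mann-Whitney concordance probability `U / (n_pos * n_neg)`
#' with ties counted one half.  The two-sided p-value uses the normal
#' approximation to the Mann-Whitney U statistic with tie correction and
#' continuity correction.
#'
#' @param scores per-subject numeric scores.
#' @param labels logical or two-level vector; `positive` names the class
#'   scored as positive.
#' @param positive value of `labels` treated as the positive class
#'   (default: `TRUE` for logicals, else the second sorted unique value).
#' @return list of class `ev_roc`: `auc`, `p`, `n_pos`, `n_neg`,
#'   `orientation` (+1; -1 after a flip by [rank_markers()]).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (is.null(positive))
    positive <- if (is.logical(labels)) TRUE else sort(unique(labels))[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be non-empty")
  r <- rank(scores)
  U <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  n <- n_pos + n_neg
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_pos * n_neg / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (U - n_pos * n_neg / 2)
    z <- (abs(z) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  structure(list(auc = auc, p = p, n_pos = n_pos, n_neg = n_neg,
                 orientation = 1), class = "ev_roc")
}

#' Rank candidate markers by predictive power
#'
#' Each marker is oriented so its AUC is at least 0.5 (the flip recorded
#' in `orientation`), then markers are sorted by AUC descending, ties
#' broken by smaller Mann-Whitney p, then lexicographic ID.
#'
#' @param z markers x subjects z-score matrix from [zscore_markers()].
#' @param labels per-subject class labels aligned to the columns of `z`.
#' @param positive positive class (see [roc_auc()]).
#' @param expected_direction optional named vector of +1/-1 forcing each
#'   marker's orientation (+1: higher score in the positive class).
#' @return data.frame ranked by predictive power: `mirna_id`, `auc`, `p`,
#'   `orientation`.
#' @export
rank_markers <- function(z, labels, positive = NULL,
                         expected_direction = NULL) {
  res <- lapply(rownames(z), function(id) {
    r <- roc_auc(z[id, ], labels, positive = positive)
    flip <- if (!is.null(expected_direction) && id %in% names(expected_direction))
      expected_direction[[id]] < 0 else r$auc < 0.5
    if (flip) {
      r <- roc_auc(-z[id, ], labels, positive = positive)
      r$orientation <- -1
    }
    data.frame(mirna_id = id, auc = r$auc, p = r$p,
               orientation = r$orientation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$auc, out$p, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy biomarker panel construction
#'
#' Builds panels from the ranked marker list: the size-k panel score per
#' subject is the mean of the oriented z-scores of the top k markers.
#' Panels grow while each additional marker strictly increases the AUC;
#' growth stops at the first k whose AUC does not exceed the running
#' maximum, and the selected panel is the prefix achieving the maximum.
#' By construction the selected panel's AUC is at least that of the best
#' single marker.
#'
#' @param z markers x subjects z-score matrix.
#' @param labels per-subject class labels.
#' @param ranked data.frame from [rank_markers()] (its order defines the
#'   prefixes).
#' @param positive positive class (see [roc_auc()]).
#' @return object of class `ev_panel`: list with `ranked_markers`,
#'   `trajectory` (data.frame panel_size, auc, p), `selected_panel`,
#'   `panel_auc`, `panel_p`, `subject_scores` (mean oriented z per
#'   subject for the selected panel).
#' @export
build_panel <- function(z, labels, ranked = NULL, positive = NULL) {
  if (is.null(ranked)) ranked <- rank_markers(z, labels, positive = positive)
  if (!nrow(ranked)) stopf("ranked marker list is empty")
  zo <- z[ranked$mirna_id, , drop = FALSE] * ranked$orientation
  traj <- data.frame(panel_size = integer(0), auc = numeric(0),
                     p = numeric(0))
  best_auc <- -Inf
  for (k in seq_len(nrow(ranked))) {
    score <- colMeans(zo[seq_len(k), , drop = FALSE])
    r <- roc_auc(score, labels, positive = positive)
    traj <- rbind(traj, data.frame(panel_size = k, auc = r$auc, p = r$p))
    if (r$auc <= best_auc) break
    best_auc <- r$auc
  }
  k_best <- traj$panel_size[which.max(traj$auc)]
  sel <- ranked$mirna_id[seq_len(k_best)]
  score <- colMeans(zo[seq_len(k_best), , drop = FALSE])
  structure(list(ranked_markers = ranked,
                 trajectory = traj,
                 selected_panel = sel,
                 panel_auc = max(traj$auc),
                 panel_p = traj$p[which.max(traj$auc)],
                 subject_scores = score),
            class = "ev_panel")
}

#' @export
print.ev_panel <- function(x, ...) {
  cat(sprintf("ev_panel: %d markers selected (AUC %.3f, p %.2g)\n",
              length(x$selected_panel), x$panel_auc, x$panel_p))
  invisible(x)
}

#' Unpaired two-tailed pooled-variance t-test on panel scores
#'
#' Classical Student's t with pooled variance and
#' `df = n1 + n2 - 2`, applied to per-subject mean z-scores of a panel.
#'
#' @param scores per-subject numeric values (e.g. `subject_scores` of an
#'   `ev_panel`).
#' @param labels two-level class vector aligned to `scores`.
#' @return list with `t`, `df`, `p`, `mean_diff` (first level minus
#'   second in sorted label order).
#' @export
panel_group_test <- function(scores, labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stopf("labels must have exactly 2 levels")
  x <- scores[labels == lv[1]]
  y <- scores[labels == lv[2]]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stopf("both groups need >= 2 subjects")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stopf("zero pooled variance")
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df),
       mean_diff = mean(x) - mean(y))
}

#' D'Agostino-Pearson K-squared omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into `K2 = Z_skew^2 + Z_kurt^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom.  Requires n >= 8.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `k2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stopf("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stopf("constant vector: normality test undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  term <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  z_kurt <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Normality-gated correlation of panel scores with a clinical covariate
#'
#' Runs the D'Agostino-Pearson normality test on both marginals (scores
#' and covariate); if both pass at `alpha`, Pearson's product-moment
#' correlation with a Fisher-z 95% CI is used, otherwise Spearman's rank
#' correlation.  The chosen method is recorded in the output.
#'
#' @param scores per-subject panel scores (n >= 8).
#' @param covariate per-subject covariate, e.g. a disability score.
#' @param alpha normality-test significance level gating the method.
#' @return list with `method` (`"pearson"`/`"spearman"`), `r`, `ci`
#'   (95%), `p`, `normality_p` (both marginals).
#' @export
correlate_panel_covariate <- function(scores, covariate, alpha = 0.05) {
  ok <- !is.na(scores) & !is.na(covariate)
  scores <- scores[ok]; covariate <- covariate[ok]
  n <- length(scores)
  if (n < 8) stopf("need n >= 8 for the normality gate")
  p1 <- dagostino_k2(scores)$p
  p2 <- dagostino_k2(covariate)$p
  method <- if (p1 > alpha && p2 > alpha) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(scores, covariate, method = method,
                                         exact = FALSE))
  r <- unname(ct$estimate)
  list(method = method, r = r, ci = fisher_ci(r, n), p = ct$p.value,
       normality_p = c(scores = p1, covariate = p2))
}
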