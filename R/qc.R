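#' Discard background-noise miRNAs
#'
#' A miRNA is considered background and discarded when the fraction of
#' samples in which its count falls below `min_count` is at least
#' `min_fraction`.  Kept miRNAs preserve their original order; the
#' operation is idempotent.
#'
#' @param counts an [ev_counts] object.
#' @param min_count count below which a sample does not support the
#'   miRNA (default 10).
#' @param min_fraction fraction of unsupporting samples at or above which
#'   the miRNA is discarded, in (0, 1] (default 0.5).
#' @return list with `counts` (filtered [ev_counts]) and `report` (list
#'   with `n_mirnas_in`, `n_mirnas_kept`, `discarded` IDs).
#' @export
filter_background <- function(counts, min_count = 10, min_fraction = 0.5) {
  stopifnot(inherits(counts, "ev_counts"))
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must be in (0, 1]")
  if (!ncol(counts$counts)) stopf("counts has no samples")
  frac_low <- rowMeans(counts$counts < min_count)
  keep <- frac_low < min_fraction
  list(counts = ev_counts(counts$counts[keep, , drop = FALSE], counts$meta),
       report = list(n_mirnas_in = nrow(counts$counts),
                     n_mirnas_kept = sum(keep),
                     discarded = rownames(counts$counts)[!keep]))
}

#' Within-group subject homogeneity (Spearman rho vs group mean profile)
#'
#' For each subject, the Spearman rank correlation between the subject's
#' miRNA count vector and the arithmetic mean count vector of the
#' subject's group.  By default the subject is included in the group mean
#' (the literal reading of the procedure this reproduces); set
#' `leave_one_out = TRUE` for the more sensitive variant.  Ties receive
#' average ranks.  A constant count vector yields `NA` (the coefficient
#' is undefined), never a silent zero.
#'
#' @param counts an [ev_counts] object; every group needs >= 2 subjects.
#' @param leave_one_out exclude the subject from its group mean.
#' @return named numeric vector of rho per sample ID.
#' @export
subject_homogeneity <- function(counts, leave_one_out = FALSE) {
  stopifnot(inherits(counts, "ev_counts"))
  tab <- table(counts$meta$group)
  if (any(tab < 2)) stopf("every group needs >= 2 subjects")
  rho <- setNames(rep(NA_real_, ncol(counts$counts)),
                  colnames(counts$counts))
  for (g in names(tab)) {
    ids <- counts$meta$sample_id[counts$meta$group == g]
    sub <- counts$counts[, ids, drop = FALSE]
    gm <- rowMeans(sub)
    for (s in ids) {
      ref <- if (leave_one_out)
        rowMeans(sub[, setdiff(ids, s), drop = FALSE]) else gm
      rho[s] <- spearman_rho(sub[, s], ref)
    }
  }
  if (anyNA(rho))
    warnf("rho undefined (constant vector) for: %s",
          paste(names(rho)[is.na(rho)], collapse = ", "))
  rho
}

#' Flag outlier subjects from homogeneity correlations
#'
#' Two rules over the pooled rho distribution: `"quartile"` flags
#' subjects strictly below the 25th percentile (the literal published
#' rule, which by construction removes about a quarter of subjects), and
#' `"tukey"` (default) flags rho below Q1 - 1.5 IQR, which only removes
#' genuinely discordant subjects.  With `by_group = TRUE` the chosen rule
#' is applied within each group's rho distribution separately.
#'
#' @param rho named numeric vector from [subject_homogeneity()].
#' @param rule `"tukey"` or `"quartile"`.
#' @param groups optional named group vector (names = sample IDs),
#'   required for `by_group = TRUE`.
#' @param by_group apply the rule per group instead of pooled.
#' @return character vector of flagged sample IDs, with the threshold(s)
#'   used attached as attribute `"threshold"`.
#' @export
flag_outliers <- function(rho, rule = c("tukey", "quartile"),
                          groups = NULL, by_group = FALSE) {
  rule <- match.arg(rule)
  if (!length(rho)) stopf("rho is empty")
  rho_ok <- rho[!is.na(rho)]
  if (length(rho_ok) < 4) stopf("need >= 4 subjects with defined rho")
  apply_rule <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    thr <- if (rule == "quartile") q[1] else q[1] - 1.5 * (q[2] - q[1])
    list(flagged = names(v)[v < thr], threshold = thr)
  }
  if (by_group) {
    if (is.null(groups)) stopf("by_group = TRUE requires groups")
    out <- lapply(split(rho_ok, groups[names(rho_ok)]), apply_rule)
    flagged <- sort(unlist(lapply(out, `[[`, "flagged"), use.names = FALSE))
    thr <- vapply(out, `[[`, numeric(1), "threshold")
  } else {
    res <- apply_rule(rho_ok)
    flagged <- sort(res$flagged)
    thr <- res$threshold
  }
  structure(flagged, threshold = thr)
}

#' Amplification-bias check: total reads versus total UMIs
#'
#' Spearman rank correlation between per-sample total read counts and
#' total unique-molecule counts.  A rank correlation near 1 indicates
#' that PCR amplification introduced no systematic bias; a warning is
#' emitted below 0.99.
#'
#' @param total_reads,total_umis equal-length numeric vectors in the same
#'   sample order.
#' @param warn_below warning threshold on rho.
#' @return Spearman rho (scalar).
#' @export
umi_bias_check <- function(total_reads, total_umis, warn_below = 0.99) {
  if (length(total_reads) != length(total_umis))
    stopf("length mismatch: %d reads vs %d umis",
          length(total_reads), length(total_umis))
  rho <- spearman_rho(total_reads, total_umis)
  if (!is.na(rho) && rho < warn_below)
    warnf("reads-vs-UMIs rank correlation %.3f is below %.2f: possible amplification bias",
          rho, warn_below)
  rho
}

#' One-call QC: filter, homogeneity, outlier exclusion
#'
#' Convenience wrapper running [filter_background()],
#' [subject_homogeneity()] and [flag_outliers()], returning the filtered
#' matrix with outlier subjects removed plus a QC report.
#'
#' @inheritParams filter_background
#' @inheritParams flag_outliers
#' @param leave_one_out passed to [subject_homogeneity()].
#' @return list with `counts` (filtered, outliers excluded) and `report`
#'   (fields `n_mirnas_in`, `n_mirnas_kept`, `rho`, `excluded_subjects`,
#'   `threshold`, and `umi_bias_rho` when metadata carries `total_reads`).
#' @export
run_qc <- function(counts, min_count = 10, min_fraction = 0.5,
                   rule = "tukey", by_group = FALSE,
                   leave_one_out = FALSE) {
  fb <- filter_background(counts, min_count, min_fraction)
  rho <- subject_homogeneity(fb$counts, leave_one_out = leave_one_out)
  groups <- setNames(fb$counts$meta$group, fb$counts$meta$sample_id)
  flagged <- flag_outliers(rho, rule = rule, groups = groups,
                           by_group = by_group)
  keep <- setdiff(colnames(fb$counts$counts), flagged)
  umi_rho <- if ("total_reads" %in% names(counts$meta) &&
                 !anyNA(counts$meta$total_reads))
    umi_bias_check(counts$meta$total_reads, library_sizes(counts))
  else NA_real_
  list(counts = subset_samples(fb$counts, keep),
       report = list(n_mirnas_in = fb$report$n_mirnas_in,
                     n_mirnas_kept = fb$report$n_mirnas_kept,
                     rho = rho,
                     excluded_subjects = as.character(flagged),
                     threshold = attr(flagged, "threshold"),
                     umi_bias_rho = umi_rho))
}
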