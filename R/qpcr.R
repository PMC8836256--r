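#' Flag outlier technical replicates on a qPCR plate
#'
#' A replicate is flagged when its Cq deviates from the median of its
#' well (sample, assay) by more than `max_dev` cycles.  Per assay, the
#' replicate columns (samples x replicate index) are additionally
#' quantile-normalized across samples and the deviation on that scale is
#' returned as a diagnostic (`qn_dev`): it exposes column-level
#' distribution shifts, but flagging uses the raw scale because the
#' rank-based normalization both dilutes genuine displacements and,
#' when a displaced replicate elsewhere on the plate inflates the shared
#' quantile distribution, manufactures deviations in wells that agree to
#' within a fraction of a cycle.  Flagged replicates are excluded from
#' downstream means; a well whose replicates are all flagged is marked
#' missing.
#'
#' @param plate data.frame with columns `sample`, `assay`, `replicate`,
#'   `cq` (cycles in (0, 45)).
#' @param max_dev flagging threshold in cycles (default 0.5).
#' @return the plate with a logical `flagged` column and a numeric
#'   `qn_dev` diagnostic column; fully-flagged wells listed in attribute
#'   `"missing_wells"`.
#' @export
replicate_qc <- function(plate, max_dev = 0.5) {
  req <- c("sample", "assay", "replicate", "cq")
  if (!all(req %in% names(plate))) stopf("plate needs columns: %s",
                                         paste(req, collapse = ", "))
  if (any(plate$cq <= 0 | plate$cq >= 45)) stopf("Cq must lie in (0, 45)")
  n_rep <- stats::aggregate(replicate ~ sample + assay, plate, length)
  if (any(n_rep$replicate < 2))
    stopf("every (sample, assay) well needs >= 2 replicates")
  plate$flagged <- FALSE
  plate$qn_dev <- NA_real_
  for (a in unique(plate$assay)) {
    idx <- which(plate$assay == a)
    sub <- plate[idx, ]
    wide <- stats::reshape(sub[, c("sample", "replicate", "cq")],
                           idvar = "sample", timevar = "replicate",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$sample
    qn <- limma::normalizeQuantiles(m)
    dev_qn <- abs(qn - apply(qn, 1, stats::median, na.rm = TRUE))
    dev_raw <- abs(m - apply(m, 1, stats::median, na.rm = TRUE))
    for (r in seq_len(ncol(m))) {
      rep_i <- as.integer(sub("cq\\.", "", colnames(m)[r]))
      sel <- sub$replicate == rep_i
      plate$qn_dev[idx][sel] <-
        dev_qn[match(sub$sample[sel], rownames(m)), r]
      bad <- rownames(m)[!is.na(dev_raw[, r]) & dev_raw[, r] > max_dev]
      plate$flagged[idx][sub$sample %in% bad & sel] <- TRUE
    }
  }
  wells <- unique(plate[, c("sample", "assay")])
  missing <- wells[vapply(seq_len(nrow(wells)), function(i) {
    sel <- plate$sample == wells$sample[i] & plate$assay == wells$assay[i]
    all(plate$flagged[sel])
  }, logical(1)), , drop = FALSE]
  if (nrow(missing))
    warnf("%d wells have all replicates flagged and are marked missing",
          nrow(missing))
  attr(plate, "missing_wells") <- missing
  plate
}

#' Delta Cq per sample and target
#'
#' `Delta Cq = mean(unflagged target Cq) - mean(unflagged UniSp6 Cq)` for
#' each sample; the spike-in duplicates are averaged before subtraction.
#' Lower Delta Cq means higher expression.
#'
#' @param plate data.frame from [replicate_qc()] (a missing `flagged`
#'   column is treated as all unflagged).
#' @param reference spike-in assay name (default `"UniSp6"`).
#' @return data.frame `sample`, `target`, `delta_cq`,
#'   `n_replicates_used`.
#' @export
delta_cq <- function(plate, reference = "UniSp6") {
  if (!"flagged" %in% names(plate)) plate$flagged <- FALSE
  if (!reference %in% plate$assay)
    stopf("missing reference assay '%s'", reference)
  ok <- plate[!plate$flagged, , drop = FALSE]
  targets <- setdiff(unique(plate$assay), reference)
  rows <- list()
  for (s in unique(plate$sample)) {
    ref_cq <- ok$cq[ok$sample == s & ok$assay == reference]
    if (!length(ref_cq)) stopf("sample %s has no usable %s replicates",
                               s, reference)
    for (a in targets) {
      tcq <- ok$cq[ok$sample == s & ok$assay == a]
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, target = a,
        delta_cq = if (length(tcq)) mean(tcq) - mean(ref_cq) else NA_real_,
        n_replicates_used = length(tcq), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of Delta Cq values
#'
#' Classical unpaired two-tailed pooled-variance Student's t-test per
#' target (df = n1 + n2 - 2).  Note that lower Delta Cq means higher
#' expression, so a negative mean difference (first group minus second)
#' indicates higher expression in the first group.
#'
#' @param dcq data.frame from [delta_cq()].
#' @param labels named group vector (names = sample IDs) with two levels
#'   among the plate's samples.
#' @return data.frame `target`, `t`, `df`, `p`, `mean_a`, `mean_b`
#'   (group means in sorted label order).
#' @export
compare_groups_dcq <- function(dcq, labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stopf("labels must have exactly 2 levels")
  rows <- lapply(unique(dcq$target), function(a) {
    sub <- dcq[dcq$target == a & !is.na(dcq$delta_cq), ]
    g <- labels[sub$sample]
    res <- panel_group_test(sub$delta_cq, g)
    data.frame(target = a, t = res$t, df = res$df, p = res$p,
               mean_a = mean(sub$delta_cq[g == lv[1]]),
               mean_b = mean(sub$delta_cq[g == lv[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}

#' Cross-platform correlation: Delta Cq versus sequencing counts
#'
#' Per target, the Spearman rank correlation between per-subject Delta Cq
#' and normalized sequencing counts, optionally restricted to one subject
#' group.  True signals are expected to correlate negatively (lower
#' Delta Cq at higher counts).
#'
#' @param dcq data.frame from [delta_cq()].
#' @param norm an `ev_norm` object or matrix of normalized counts with
#'   the plate's targets among its rows.
#' @param group optional group label; requires `labels`.
#' @param labels named group vector (names = sample IDs).
#' @return data.frame `target`, `rho`, `p`, `n`.
#' @export
crossplatform_correlation <- function(dcq, norm, group = NULL,
                                      labels = NULL) {
  vals <- if (inherits(norm, "ev_norm")) norm$values else as.matrix(norm)
  rows <- lapply(unique(dcq$target), function(a) {
    sub <- dcq[dcq$target == a & !is.na(dcq$delta_cq), ]
    if (!is.null(group)) {
      if (is.null(labels)) stopf("group filtering requires labels")
      sub <- sub[labels[sub$sample] == group, , drop = FALSE]
    }
    ids <- intersect(sub$sample, colnames(vals))
    if (length(ids) < 5 || !(a %in% rownames(vals)))
      stopf("target %s: need >= 5 subjects with both measurements", a)
    x <- vals[a, ids]
    y <- sub$delta_cq[match(ids, sub$sample)]
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(target = a, rho = unname(ct$estimate), p = ct$p.value,
               n = length(ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
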