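#' Pair serum and CSF expression by matched subjects
#'
#' Restricts both compartments to the miRNAs detected (post-filter) in
#' both, checks that `subject_map` is a bijection between serum and CSF
#' sample IDs, and computes per-miRNA mean normalized expression in each
#' compartment together with log10 transforms.
#'
#' @param serum,csf `ev_norm` objects or numeric matrices of normalized
#'   expression.
#' @param subject_map data.frame with columns `serum_id`, `csf_id`.
#' @return object of class `ev_pairs`: data.frame `mirna_id`,
#'   `serum_mean`, `csf_mean`, `log10_serum`, `log10_csf`, with the
#'   counts of compartment-exclusive miRNAs in attribute `"excluded"`.
#' @export
pair_compartments <- function(serum, csf, subject_map) {
  sv <- if (inherits(serum, "ev_norm")) serum$values else as.matrix(serum)
  cv <- if (inherits(csf, "ev_norm")) csf$values else as.matrix(csf)
  if (!all(c("serum_id", "csf_id") %in% names(subject_map)))
    stopf("subject_map needs columns serum_id and csf_id")
  if (anyDuplicated(subject_map$serum_id) ||
      anyDuplicated(subject_map$csf_id) ||
      nrow(subject_map) == 0)
    stopf("subject_map must be a bijection")
  bad <- c(setdiff(subject_map$serum_id, colnames(sv)),
           setdiff(subject_map$csf_id, colnames(cv)))
  if (length(bad)) stopf("unknown samples in subject_map: %s",
                         paste(bad, collapse = ", "))
  shared <- intersect(rownames(sv), rownames(cv))
  excluded <- c(serum_only = length(setdiff(rownames(sv), shared)),
                csf_only = length(setdiff(rownames(cv), shared)))
  s <- sv[shared, subject_map$serum_id, drop = FALSE]
  c_ <- cv[shared, subject_map$csf_id, drop = FALSE]
  out <- data.frame(mirna_id = shared,
                    serum_mean = rowMeans(s),
                    csf_mean = rowMeans(c_),
                    stringsAsFactors = FALSE)
  pos <- out$serum_mean > 0 & out$csf_mean > 0
  if (!all(pos)) {
    excluded["zero_mean"] <- sum(!pos)
    out <- out[pos, , drop = FALSE]
  }
  out$log10_serum <- log10(out$serum_mean)
  out$log10_csf <- log10(out$csf_mean)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "subject_map") <- subject_map
  class(out) <- c("ev_pairs", "data.frame")
  out
}

#' Split paired miRNAs into "similar" and "high-serum" populations
#'
#' Deterministic one-dimensional 2-means on the per-miRNA difference
#' `d = log10(serum_mean) - log10(csf_mean)`, initialized at the 10th and
#' 90th percentiles of d.  The cluster with the higher centre is labelled
#' `high_serum`; the separating threshold (midpoint of the final centres)
#' is reported.  A degenerate difference distribution (all equal) yields
#' a single `similar` population with a warning.
#'
#' @param pairs an `ev_pairs` data.frame from [pair_compartments()].
#' @param max_iter Lloyd iteration cap.
#' @return the input with a `population` column added; cluster sizes and
#'   the threshold in attributes `"sizes"` and `"threshold"`.
#' @export
split_populations <- function(pairs, max_iter = 100L) {
  if (nrow(pairs) < 10) stopf("need >= 10 paired miRNAs")
  d <- pairs$log10_serum - pairs$log10_csf
  if (max(d) - min(d) < 1e-12) {
    warnf("degenerate log-difference distribution: single population")
    pairs$population <- "similar"
    attr(pairs, "sizes") <- c(similar = nrow(pairs), high_serum = 0L)
    attr(pairs, "threshold") <- NA_real_
    return(pairs)
  }
  centers <- stats::quantile(d, c(0.1, 0.9), names = FALSE)
  if (diff(centers) < 1e-12) centers <- range(d)
  for (i in seq_len(max_iter)) {
    assign_high <- abs(d - centers[2]) < abs(d - centers[1])
    new_centers <- c(mean(d[!assign_high]), mean(d[assign_high]))
    if (anyNA(new_centers)) break
    if (max(abs(new_centers - centers)) < 1e-12) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  pairs$population <- ifelse(assign_high, "high_serum", "similar")
  attr(pairs, "sizes") <- c(similar = sum(!assign_high),
                            high_serum = sum(assign_high))
  attr(pairs, "threshold") <- mean(centers)
  attr(pairs, "centers") <- centers
  pairs
}

#' Between-compartment correlation within a miRNA population
#'
#' Correlation of the per-miRNA mean linear expression in serum versus
#' CSF within one population.  Spearman rank correlation is the primary
#' method (the distributions fail normality); Pearson is also available.
#' The 95% CI uses the Fisher transform of the coefficient.
#'
#' @param pairs an `ev_pairs` data.frame with a `population` column.
#' @param population `"similar"` or `"high_serum"`.
#' @param method `"spearman"` (primary) or `"pearson"`.
#' @return list with `r`, `ci`, `p`, `n`, `method`, and `r_pearson` as a
#'   secondary descriptor when method is spearman.
#' @export
correlate_population <- function(pairs, population,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!"population" %in% names(pairs))
    stopf("run split_populations() first")
  sel <- pairs$population == population
  if (sum(sel) < 5) stopf("population '%s' has < 5 miRNAs", population)
  x <- pairs$serum_mean[sel]
  y <- pairs$csf_mean[sel]
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  r <- unname(ct$estimate)
  out <- list(r = r, ci = fisher_ci(r, sum(sel)), p = ct$p.value,
              n = sum(sel), method = method)
  if (method == "spearman") out$r_pearson <- stats::cor(x, y)
  out
}

#' Per-miRNA serum-CSF correlation across matched subjects
#'
#' For each listed miRNA, the correlation of per-subject serum versus CSF
#' normalized expression, with the method gated by the
#' D'Agostino-Pearson normality test on both marginals (Pearson if both
#' pass, else Spearman), as in [correlate_panel_covariate()].  Missing
#' miRNAs are reported with NA rows, not fatal.
#'
#' @param serum,csf `ev_norm` objects or matrices.
#' @param mirna_ids miRNAs to correlate.
#' @param subject_map data.frame `serum_id`, `csf_id` (>= 5 subjects).
#' @param alpha normality-gate level.
#' @return data.frame `mirna_id`, `method`, `r`, `ci_lo`, `ci_hi`, `p`.
#' @export
per_mirna_correlation <- function(serum, csf, mirna_ids, subject_map,
                                  alpha = 0.05) {
  sv <- if (inherits(serum, "ev_norm")) serum$values else as.matrix(serum)
  cv <- if (inherits(csf, "ev_norm")) csf$values else as.matrix(csf)
  if (nrow(subject_map) < 5) stopf("need >= 5 matched subjects")
  rows <- lapply(mirna_ids, function(id) {
    if (!(id %in% rownames(sv)) || !(id %in% rownames(cv)))
      return(data.frame(mirna_id = id, method = NA_character_,
                        r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    x <- sv[id, subject_map$serum_id]
    y <- cv[id, subject_map$csf_id]
    method <- if (length(x) >= 8 &&
                  dagostino_k2(x)$p > alpha && dagostino_k2(y)$p > alpha)
      "pearson" else "spearman"
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    ci <- fisher_ci(unname(ct$estimate), length(x))
    data.frame(mirna_id = id, method = method, r = unname(ct$estimate),
               ci_lo = ci[1], ci_hi = ci[2], p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$r))
    warnf("miRNAs missing from one compartment: %s",
          paste(out$mirna_id[is.na(out$r)], collapse = ", "))
  out
}
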