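#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1, after validating that all inputs lie in (0, 1].
#'
#' @param raw_p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(raw_p) {
  if (!length(raw_p)) return(numeric(0))
  if (anyNA(raw_p) || any(raw_p <= 0 | raw_p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(raw_p, method = "BH")
}

#' Pairwise differential expression for one contrast
#'
#' Negative-binomial test of `group_a` versus `group_b`; positive log2
#' fold change means higher in `group_a`.  Two engines:
#'
#' * `"ql"` (default): per-miRNA NB log-link model with a group effect
#'   fitted by Newton iterations at the shrunk per-miRNA dispersion;
#'   quasi-dispersion estimated from the residual deviance and squeezed
#'   across miRNAs by empirical Bayes; F-statistic on the group effect
#'   (deviance difference over squeezed quasi-dispersion) with squeezed
#'   denominator degrees of freedom.
#' * `"exact"`: conditional NB exact test on library-equalized counts at
#'   the common dispersion, two-sided by the double-tail rule.
#'
#' Normalization enters via effective library sizes (library size times
#' TMM factor).  The reported log2 fold change is the ratio of
#' prior-augmented group-mean TMM-CPM.  miRNAs with zero counts in both
#' groups are skipped (p = 1, log2fc = 0).
#'
#' @param counts an [ev_counts] object (raw counts).
#' @param group_a,group_b group labels present in the metadata.
#' @param engine `"ql"` or `"exact"`.
#' @param factors optional TMM factors for these samples (computed from
#'   the contrast's samples when `NULL`).
#' @param dispersion optional result of [estimate_dispersion()] on these
#'   samples.
#' @param p_threshold,lfc_threshold DE calling thresholds (raw p < 0.01,
#'   |log2FC| >= 1).
#' @param prior_count prior for the fold-change CPM.
#' @return data.frame of class `ev_de`: `mirna_id`, `log2fc`, `raw_p`,
#'   `adj_p`, `dispersion`, `call` (`"up"`, `"down"`, `"none"`), with the
#'   contrast stored in attribute `"contrast"`.
#' @export
de_test <- function(counts, group_a, group_b, engine = c("ql", "exact"),
                    factors = NULL, dispersion = NULL,
                    p_threshold = 0.01, lfc_threshold = 1,
                    prior_count = 0.5) {
  engine <- match.arg(engine)
  stopifnot(inherits(counts, "ev_counts"))
  if (identical(group_a, group_b)) stopf("contrast groups must differ")
  for (g in c(group_a, group_b))
    if (!g %in% counts$meta$group) stopf("unknown group '%s'", g)
  ids_a <- counts$meta$sample_id[counts$meta$group == group_a]
  ids_b <- counts$meta$sample_id[counts$meta$group == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stopf("both groups need >= 2 samples")
  sub <- subset_samples(counts, c(ids_a, ids_b))
  Y <- sub$counts
  lib <- colSums(Y)
  if (is.null(factors)) factors <- tmm_factors(Y)
  eff <- lib * factors
  grp <- c(rep("A", length(ids_a)), rep("B", length(ids_b)))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(Y, groups = grp, eff_lib = eff)
  phi_tag <- dispersion$tagwise
  phi_common <- dispersion$common

  nz <- rowSums(Y) > 0
  G <- nrow(Y)
  raw_p <- rep(1, G)

  if (engine == "ql") {
    idx_a <- which(grp == "A"); idx_b <- which(grp == "B")
    Yn <- Y[nz, , drop = FALSE]
    phi_n <- phi_tag[nz]
    b_a <- .nb_fit_block(Yn[, idx_a, drop = FALSE], eff[idx_a], phi_n)
    b_b <- .nb_fit_block(Yn[, idx_b, drop = FALSE], eff[idx_b], phi_n)
    b_0 <- .nb_fit_block(Yn, eff, phi_n)
    dev_full <- .nb_dev_rows(Yn[, idx_a, drop = FALSE], b_a, eff[idx_a], phi_n) +
      .nb_dev_rows(Yn[, idx_b, drop = FALSE], b_b, eff[idx_b], phi_n)
    dev_null <- .nb_dev_rows(Yn, b_0, eff, phi_n)
    df_resid <- ncol(Y) - 2
    s2 <- dev_full / df_resid
    sq <- limma::squeezeVar(s2, df = df_resid)
    df_total <- df_resid + sq$df.prior
    Fstat <- pmax(dev_null - dev_full, 0) / pmax(sq$var.post, 1e-12)
    raw_p[nz] <- stats::pf(Fstat, 1, df_total, lower.tail = FALSE)
  } else {
    # equalize libraries, then conditional test on group sums
    n_bar <- exp(mean(log(eff)))
    pseudo <- round(t(t(Y) / eff) * n_bar)
    sA <- rowSums(pseudo[, grp == "A", drop = FALSE])
    sB <- rowSums(pseudo[, grp == "B", drop = FALSE])
    raw_p[nz] <- .exact_nb_p(sA[nz], sB[nz], sum(grp == "A"),
                             sum(grp == "B"), rep(phi_common, sum(nz)))
  }
  raw_p <- pmin(pmax(raw_p, 1e-300), 1)

  cpm <- cpm_matrix(Y, factors = factors, prior_count = prior_count)$values
  mean_a <- rowMeans(cpm[, grp == "A", drop = FALSE])
  mean_b <- rowMeans(cpm[, grp == "B", drop = FALSE])
  log2fc <- ifelse(nz, log2(mean_a / mean_b), 0)

  det <- data.frame(mirna_id = rownames(Y), log2fc = log2fc,
                    raw_p = raw_p, adj_p = adjust_bh(raw_p),
                    dispersion = unname(phi_tag),
                    stringsAsFactors = FALSE)
  rownames(det) <- NULL
  det$call <- .de_call(det$raw_p, det$log2fc, p_threshold, lfc_threshold)
  attr(det, "contrast") <- c(group_a = group_a, group_b = group_b)
  attr(det, "engine") <- engine
  class(det) <- c("ev_de", "data.frame")
  det
}

.de_call <- function(p, lfc, p_threshold, lfc_threshold) {
  ifelse(p < p_threshold & lfc >= lfc_threshold, "up",
         ifelse(p < p_threshold & lfc <= -lfc_threshold, "down", "none"))
}

#' Call differentially expressed miRNAs from a DE table
#'
#' Calls use the raw p-value (the thresholds the downstream set logic is
#' defined at); the sets surviving BH adjustment at the same thresholds
#' are reported alongside.
#'
#' @param det an `ev_de` data.frame from [de_test()].
#' @param p_threshold raw p-value threshold (default 0.01).
#' @param lfc_threshold absolute log2 fold-change threshold, boundary
#'   inclusive (default 1).
#' @return list with `up`, `down` (IDs at the raw threshold) and
#'   `up_adj`, `down_adj` (IDs also significant after BH adjustment).
#' @export
call_de <- function(det, p_threshold = 0.01, lfc_threshold = 1) {
  calls <- .de_call(det$raw_p, det$log2fc, p_threshold, lfc_threshold)
  calls_adj <- .de_call(det$adj_p, det$log2fc, p_threshold, lfc_threshold)
  list(up = det$mirna_id[calls == "up"],
       down = det$mirna_id[calls == "down"],
       up_adj = det$mirna_id[calls_adj == "up"],
       down_adj = det$mirna_id[calls_adj == "down"])
}

# Extract up/down sets for a directed contrast "A_vs_B" from a named DE
# list, flipping direction when only "B_vs_A" is available.
.contrast_sets <- function(de, a, b, p_threshold, lfc_threshold) {
  fwd <- paste0(a, "_vs_", b)
  rev <- paste0(b, "_vs_", a)
  if (fwd %in% names(de)) {
    call_de(de[[fwd]], p_threshold, lfc_threshold)[c("up", "down")]
  } else if (rev %in% names(de)) {
    s <- call_de(de[[rev]], p_threshold, lfc_threshold)
    list(up = s$down, down = s$up)
  } else {
    stopf("missing contrast %s (or %s)", fwd, rev)
  }
}

#' Stage-specific miRNA sets by double dissociation
#'
#' CIS-specific down-regulated miRNAs are those down in CIS versus
#' healthy controls and down in CIS versus RRMS; RRMS-specific
#' up-regulated miRNAs are up in RRMS versus healthy controls and up in
#' RRMS versus CIS.  Also returns the direction-resolved Venn partition
#' of the three patient-versus-HealthCtl contrasts, and flags which
#' specific miRNAs are additionally dysregulated (same direction) versus
#' hospitalized controls when those contrasts are supplied.
#'
#' @param de named list of `ev_de` tables; names like `"CIS_vs_HealthCtl"`
#'   (either orientation of each contrast is accepted).
#' @param p_threshold,lfc_threshold calling thresholds.
#' @return object of class `ev_specific_sets`: list with
#'   `cis_specific_down`, `rrms_specific_up`, `venn_partition` (list of
#'   miRNA ID sets keyed by region and direction, e.g. `"CIS+RRMS:up"`),
#'   and `hospctl_support` when available.
#' @export
stage_specific_sets <- function(de, p_threshold = 0.01, lfc_threshold = 1) {
  cis_h <- .contrast_sets(de, "CIS", "HealthCtl", p_threshold, lfc_threshold)
  rrms_h <- .contrast_sets(de, "RRMS", "HealthCtl", p_threshold, lfc_threshold)
  cis_r <- .contrast_sets(de, "CIS", "RRMS", p_threshold, lfc_threshold)

  cis_specific_down <- sort(intersect(cis_h$down, cis_r$down))
  # "up in RRMS vs CIS" is "down in CIS vs RRMS"
  rrms_specific_up <- sort(intersect(rrms_h$up, cis_r$down))

  venn <- list()
  vs_h <- list(CIS = cis_h, RRMS = rrms_h)
  has_vi <- any(c("VI_vs_HealthCtl", "HealthCtl_vs_VI") %in% names(de))
  if (has_vi)
    vs_h$VI <- .contrast_sets(de, "VI", "HealthCtl", p_threshold, lfc_threshold)
  for (dir in c("up", "down")) {
    sets <- lapply(vs_h, `[[`, dir)
    ids <- sort(unique(unlist(sets)))
    if (!length(ids)) next
    member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    if (length(ids) == 1L) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
    region <- apply(member, 1, function(r)
      paste(colnames(member)[r], collapse = "+"))
    for (reg in unique(region))
      venn[[paste0(reg, ":", dir)]] <- ids[region == reg]
  }

  hosp <- NULL
  if (any(grepl("HospCtl", names(de)))) {
    cis_hosp <- tryCatch(.contrast_sets(de, "CIS", "HospCtl",
                                        p_threshold, lfc_threshold),
                         error = function(e) NULL)
    rrms_hosp <- tryCatch(.contrast_sets(de, "RRMS", "HospCtl",
                                         p_threshold, lfc_threshold),
                          error = function(e) NULL)
    hosp <- list(
      cis_specific_down = if (!is.null(cis_hosp))
        intersect(cis_specific_down, cis_hosp$down) else character(0),
      rrms_specific_up = if (!is.null(rrms_hosp))
        intersect(rrms_specific_up, rrms_hosp$up) else character(0))
  }

  structure(list(cis_specific_down = cis_specific_down,
                 rrms_specific_up = rrms_specific_up,
                 venn_partition = venn,
                 hospctl_support = hosp),
            class = "ev_specific_sets")
}

#' @export
print.ev_specific_sets <- function(x, ...) {
  cat("CIS-specific down:", length(x$cis_specific_down), "miRNAs\n")
  cat("RRMS-specific up: ", length(x$rrms_specific_up), "miRNAs\n")
  invisible(x)
}
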