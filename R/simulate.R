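#' Simulation parameters for the synthetic EV miRNome generator
#'
#' The defaults emulate the study design the package targets: five subject
#' groups (healthy controls, hospitalized controls, CIS-remission,
#' RRMS-relapse, viral inflammatory CNS disorder) of sizes 18/22/18/16/11,
#' a sequencing depth of about five million molecules per sample, and a
#' per-sample detected-miRNA count in the low thousands.  A small number
#' of miRNAs carry planted effects: `n_cis_down` down-regulated only in
#' CIS, `n_rrms_up` up-regulated only in RRMS (the stage-specific ground
#' truth), a "pan-disease" set dysregulated in CIS, RRMS and VI alike
#' (populating the overlap regions of the three-way comparison against
#' healthy controls), and a VI-private set.
#'
#' @param n_mirnas number of mature miRNAs in the matrix.
#' @param group_sizes named integer vector of subjects per group.
#' @param library_size_mean expected per-sample depth (UMIs).
#' @param library_size_cv coefficient of variation of depth across samples.
#' @param dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), constant across miRNAs.
#' @param baseline_logmean_range log10 range of the baseline relative
#'   abundance draw (log-uniform), pilot-calibrated so the per-sample
#'   detected-miRNA count lands in the observed band.
#' @param n_cis_down,n_rrms_up numbers of stage-specific planted miRNAs.
#' @param planted_log2fc absolute log2 fold change of planted effects
#'   (>= 1 so planted effects exceed the calling threshold in expectation).
#' @param n_shared_up,n_shared_down pan-disease planted effects shared by
#'   CIS, RRMS and VI.
#' @param n_vi_up,n_vi_down VI-private planted effects.
#' @param seed integer seed.
#' @return an object of class `ev_sim_params` (validated list).
#' @export
sim_params <- function(n_mirnas = 2000,
                       group_sizes = c(HealthCtl = 18, HospCtl = 22,
                                       CIS = 18, RRMS = 16, VI = 11),
                       library_size_mean = 5e6,
                       library_size_cv = 0.25,
                       dispersion = 0.2,
                       baseline_logmean_range = c(-8, -2.5),
                       n_cis_down = 6,
                       n_rrms_up = 9,
                       planted_log2fc = 2,
                       n_shared_up = 18,
                       n_shared_down = 11,
                       n_vi_up = 17,
                       n_vi_down = 8,
                       seed = 1L) {
  p <- list(n_mirnas = n_mirnas, group_sizes = group_sizes,
            library_size_mean = library_size_mean,
            library_size_cv = library_size_cv,
            dispersion = dispersion,
            baseline_logmean_range = baseline_logmean_range,
            n_cis_down = n_cis_down, n_rrms_up = n_rrms_up,
            planted_log2fc = planted_log2fc,
            n_shared_up = n_shared_up, n_shared_down = n_shared_down,
            n_vi_up = n_vi_up, n_vi_down = n_vi_down,
            seed = as.integer(seed))
  if (n_mirnas < 10) stopf("n_mirnas must be >= 10")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stopf("group_sizes must be a named vector")
  if (any(group_sizes <= 1)) stopf("every group needs > 1 subject")
  if (library_size_mean <= 0) stopf("library_size_mean must be positive")
  if (library_size_cv < 0) stopf("library_size_cv must be >= 0")
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (length(baseline_logmean_range) != 2 ||
      diff(baseline_logmean_range) <= 0)
    stopf("baseline_logmean_range must be an increasing pair")
  if (planted_log2fc < 0) stopf("planted_log2fc must be >= 0")
  n_planted <- n_cis_down + n_rrms_up + n_shared_up + n_shared_down +
    n_vi_up + n_vi_down
  if (n_planted > n_mirnas / 4)
    stopf("too many planted miRNAs (%d) for n_mirnas = %d",
          n_planted, n_mirnas)
  structure(p, class = "ev_sim_params")
}

# Draws library sizes from a gamma with the requested mean and CV.
.draw_lib_sizes <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Simulate a five-group serum EV miRNA count matrix with planted truth
#'
#' Counts are negative-binomial: baseline relative abundances are drawn
#' log-uniformly over `baseline_logmean_range` (log10), multiplied by the
#' group's planted fold changes, renormalized within each group (so the
#' planted effects induce a realistic, mild composition bias that TMM must
#' correct), scaled by each sample's library size, and then sampled with
#' constant dispersion.  Planted miRNAs are drawn from the upper abundance
#' range (expected baseline count >= 100) so their effects are estimable.
#'
#' Metadata includes EDSS scores for CIS and RRMS subjects (uniform over
#' the clinical ranges 0-3.5 and 1.0-7.5) and `total_reads`, which are
#' UMIs inflated by a per-sample PCR amplification factor, for the
#' reads-versus-UMIs bias check.
#'
#' @param params an `ev_sim_params` object.
#' @return list with elements `counts` (an [ev_counts] object) and
#'   `truth` (class `ev_sim_truth`: planted ID sets, per-group true log2
#'   fold changes, empty `outlier_subject_ids`).
#' @export
simulate_counts <- function(params = sim_params()) {
  if (!inherits(params, "ev_sim_params")) params <- do.call(sim_params, params)
  set.seed(params$seed)
  G <- params$n_mirnas
  groups <- rep(names(params$group_sizes), params$group_sizes)
  n <- length(groups)
  sample_ids <- sprintf("%s_%02d", groups, unlist(lapply(
    params$group_sizes, seq_len)))
  mirna_ids <- sprintf("sim-miR-%04d", seq_len(G))

  lr <- params$baseline_logmean_range
  w <- 10^stats::runif(G, lr[1], lr[2])      # baseline relative abundance
  names(w) <- mirna_ids

  # eligible hosts for planted effects: abundant enough to be estimable
  eligible <- which(w / sum(w) * params$library_size_mean >= 100)
  n_need <- params$n_cis_down + params$n_rrms_up + params$n_shared_up +
    params$n_shared_down + params$n_vi_up + params$n_vi_down
  if (length(eligible) < n_need)
    stopf("baseline draw yielded too few abundant miRNAs for planting")
  picks <- sample(eligible, n_need)
  take <- function(k) {
    out <- picks[seq_len(k)]
    picks <<- picks[-seq_len(k)]
    out
  }
  cis_down <- take(params$n_cis_down)
  rrms_up <- take(params$n_rrms_up)
  shared_up <- take(params$n_shared_up)
  shared_down <- take(params$n_shared_down)
  vi_up <- take(params$n_vi_up)
  vi_down <- take(params$n_vi_down)

  group_names <- names(params$group_sizes)
  lfc <- matrix(0, G, length(group_names),
                dimnames = list(mirna_ids, group_names))
  d <- params$planted_log2fc
  if ("CIS" %in% group_names) lfc[cis_down, "CIS"] <- -d
  if ("RRMS" %in% group_names) lfc[rrms_up, "RRMS"] <- d
  for (g in intersect(c("CIS", "RRMS", "VI"), group_names)) {
    lfc[shared_up, g] <- d
    lfc[shared_down, g] <- -d
  }
  if ("VI" %in% group_names) {
    lfc[vi_up, "VI"] <- d
    lfc[vi_down, "VI"] <- -d
  }

  lib <- .draw_lib_sizes(n, params$library_size_mean, params$library_size_cv)
  counts <- matrix(0L, G, n, dimnames = list(mirna_ids, sample_ids))
  for (g in colnames(lfc)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    wg <- w * 2^lfc[, g]
    wg <- wg / sum(wg)
    mu <- outer(wg, lib[idx])
    counts[, idx] <- stats::rnbinom(length(mu), size = 1 / params$dispersion,
                                    mu = mu)
  }

  edss <- rep(NA_real_, n)
  edss[groups == "CIS"] <- round(stats::runif(sum(groups == "CIS"), 0, 3.5) * 2) / 2
  edss[groups == "RRMS"] <- round(stats::runif(sum(groups == "RRMS"), 1, 7.5) * 2) / 2
  umis <- colSums(counts)
  amp <- stats::rnorm(n, mean = 1.75, sd = 0.02)  # per-sample PCR amplification
  meta <- data.frame(sample_id = sample_ids, group = groups,
                     compartment = "serum", edss = edss,
                     total_reads = round(umis * amp),
                     stringsAsFactors = FALSE)

  truth <- structure(list(
    cis_down_ids = mirna_ids[cis_down],
    rrms_up_ids = mirna_ids[rrms_up],
    shared_up_ids = mirna_ids[shared_up],
    shared_down_ids = mirna_ids[shared_down],
    vi_up_ids = mirna_ids[vi_up],
    vi_down_ids = mirna_ids[vi_down],
    log2fc = lfc,
    outlier_subject_ids = character(0)
  ), class = "ev_sim_truth")

  list(counts = ev_counts(counts, meta), truth = truth)
}

#' Corrupt a subset of subjects to exercise the outlier-exclusion rule
#'
#' For each chosen subject, a fraction `severity` of miRNAs have their
#' expected counts replaced by a rank-shuffled copy of the subject's
#' fitted mean profile and are re-drawn from the negative binomial.  At
#' severity 1 the subject's profile is uncorrelated with its group mean;
#' as severity tends to 0 the subject is unchanged.
#'
#' @param counts an [ev_counts] object.
#' @param n_outliers number of subjects to corrupt (must be smaller than
#'   the smallest group).
#' @param severity fraction of miRNAs shuffled, in (0, 1].
#' @param dispersion NB dispersion used for the re-draw.
#' @param groups optional group labels to sample victims from.  Because
#'   the group mean profile includes every subject, corrupting several
#'   subjects of a small group contaminates the reference that the
#'   homogeneity check compares against; restricting injection to large
#'   groups (the observed exclusions came from the three largest) keeps
#'   at least ~12 intact subjects per affected group.
#' @param seed integer seed.
#' @return list with `counts` (corrupted copy; untouched columns are
#'   bit-identical) and `truth` (list with `outlier_subject_ids`).
#' @export
inject_outlier_subjects <- function(counts, n_outliers, severity = 1,
                                    dispersion = 0.2, groups = NULL,
                                    seed = 1L) {
  stopifnot(inherits(counts, "ev_counts"))
  if (severity <= 0 || severity > 1) stopf("severity must be in (0, 1]")
  if (n_outliers < 0) stopf("n_outliers must be >= 0")
  if (n_outliers >= min(table(counts$meta$group)))
    stopf("n_outliers must be smaller than the smallest group")
  if (n_outliers == 0)
    return(list(counts = counts,
                truth = list(outlier_subject_ids = character(0))))
  set.seed(seed)
  pool <- counts$meta$sample_id
  if (!is.null(groups)) {
    bad <- setdiff(groups, counts$meta$group)
    if (length(bad)) stopf("unknown groups: %s", paste(bad, collapse = ", "))
    pool <- counts$meta$sample_id[counts$meta$group %in% groups]
  }
  victims <- sample(pool, n_outliers)
  G <- nrow(counts$counts)
  k <- max(1L, round(severity * G))
  m <- counts$counts
  for (s in victims) {
    y <- m[, s]
    idx <- sample.int(G, k)
    mu <- pmax(y, 0.25)          # subject's own profile as the mean
    shuffled <- if (k > 1) sample(idx) else idx
    mu[idx] <- mu[shuffled]      # rank-shuffle the chosen fraction
    m[idx, s] <- stats::rnbinom(k, size = 1 / dispersion, mu = mu[idx])
  }
  list(counts = ev_counts(m, counts$meta),
       truth = list(outlier_subject_ids = sort(victims)))
}

#' Simulate a matched CSF expression matrix from serum samples
#'
#' Emulates the two qualitative miRNA populations seen when comparing
#' compartments: a "similar" population whose CSF expression tracks serum,
#' and a "high-serum" population whose CSF expression sits a fixed number
#' of decades below the identity line.  Per subject, CSF values are the
#' serum values multiplied by a per-miRNA ratio, so per-miRNA mean
#' identities hold exactly when noise is off.  Values are real-valued
#' normalized expression (not integer counts).
#'
#' @param serum an [ev_counts] object or numeric matrix restricted to the
#'   matched subjects of a single group (typically RRMS).
#' @param high_serum_fraction fraction of miRNAs in the high-serum
#'   population (default 128/2151, the observed split).
#' @param offset_log10 decades by which high-serum miRNAs are lower in
#'   CSF.
#' @param noise_sd per-miRNA lognormal noise sd (log10 units) on the CSF
#'   mean.
#' @param subject_noise_sd optional extra per-subject lognormal noise
#'   (log10 units) decoupling individual subjects' serum and CSF values.
#' @param seed integer seed.
#' @return list with `csf` (numeric matrix, same dimnames as serum),
#'   `truth` (data.frame: mirna_id, population, ratio) and `subject_map`
#'   (data.frame serum_id, csf_id).
#' @export
simulate_matched_csf <- function(serum, high_serum_fraction = 128 / 2151,
                                 offset_log10 = 2, noise_sd = 0.2,
                                 subject_noise_sd = 0, seed = 1L) {
  m <- if (inherits(serum, "ev_counts")) serum$counts else as.matrix(serum)
  if (inherits(serum, "ev_counts") &&
      length(unique(serum$meta$group)) != 1)
    stopf("serum must be restricted to a single group")
  if (high_serum_fraction <= 0 || high_serum_fraction >= 1)
    stopf("high_serum_fraction must be in (0, 1)")
  set.seed(seed)
  G <- nrow(m)
  n_high <- max(1L, round(high_serum_fraction * G))
  high <- sample.int(G, n_high)
  pop <- rep("similar", G)
  pop[high] <- "high_serum"
  eps <- if (noise_sd > 0) stats::rnorm(G, 0, noise_sd) else numeric(G)
  ratio <- 10^(eps - offset_log10 * (pop == "high_serum"))
  csf <- m * ratio
  if (subject_noise_sd > 0)
    csf <- csf * 10^stats::rnorm(length(csf), 0, subject_noise_sd)
  csf_ids <- paste0(colnames(m), "_CSF")
  colnames(csf) <- csf_ids
  list(csf = csf,
       truth = data.frame(mirna_id = rownames(m), population = pop,
                          ratio = ratio, stringsAsFactors = FALSE),
       subject_map = data.frame(serum_id = colnames(m), csf_id = csf_ids,
                                stringsAsFactors = FALSE))
}

#' Simulate an RT-qPCR plate from sequencing counts
#'
#' Per sample and assayed miRNA, triplicate quantification cycles are
#' generated as `intercept - efficiency_slope * log2(CPM + 1)` plus
#' replicate noise; the UniSp6 spike-in is run in duplicate around a fixed
#' cycle.  With probability `outlier_rate` a target replicate is displaced
#' by at least two cycles (recorded in the truth ledger), exercising the
#' technical-replicate QC.
#'
#' @param counts an [ev_counts] object.
#' @param mirna_ids assayed miRNA IDs (must exist in `counts`).
#' @param efficiency_slope cycles per log2 expression unit.
#' @param replicate_sd technical replicate noise sd (cycles).
#' @param outlier_rate per-replicate probability of displacement.
#' @param intercept baseline cycle at zero expression.
#' @param unisp6_cq spike-in centre cycle.
#' @param seed integer seed.
#' @return list with `plate` (data.frame sample, assay, replicate, cq) and
#'   `truth` (data.frame of displaced replicates; the generating log2
#'   expression per sample/assay as attribute `"expr"`).
#' @export
simulate_qpcr <- function(counts, mirna_ids, efficiency_slope = 1,
                          replicate_sd = 0.2, outlier_rate = 0,
                          intercept = 36, unisp6_cq = 19, seed = 1L) {
  stopifnot(inherits(counts, "ev_counts"))
  if (!length(mirna_ids)) stopf("mirna_ids must be non-empty")
  bad <- setdiff(mirna_ids, rownames(counts$counts))
  if (length(bad)) stopf("unknown miRNAs: %s", paste(bad, collapse = ", "))
  if (outlier_rate < 0 || outlier_rate >= 1)
    stopf("outlier_rate must be in [0, 1)")
  set.seed(seed)
  lib <- library_sizes(counts)
  cpm0 <- t(t(counts$counts[mirna_ids, , drop = FALSE]) / lib) * 1e6
  samples <- colnames(counts$counts)
  rows <- vector("list", length(samples) * (length(mirna_ids) + 1))
  flagged <- list()
  k <- 0
  for (s in samples) {
    for (a in mirna_ids) {
      base <- intercept - efficiency_slope * log2(cpm0[a, s] + 1)
      cq <- base + stats::rnorm(3, 0, replicate_sd)
      out <- stats::runif(3) < outlier_rate
      if (any(out)) {
        shift <- (2 + stats::rexp(sum(out), 1)) * sample(c(-1, 1), sum(out),
                                                         replace = TRUE)
        cq[out] <- cq[out] + shift
        flagged[[length(flagged) + 1]] <-
          data.frame(sample = s, assay = a, replicate = which(out),
                     stringsAsFactors = FALSE)
      }
      k <- k + 1
      rows[[k]] <- data.frame(sample = s, assay = a, replicate = 1:3,
                              cq = cq, stringsAsFactors = FALSE)
    }
    k <- k + 1
    rows[[k]] <- data.frame(sample = s, assay = "UniSp6", replicate = 1:2,
                            cq = unisp6_cq + stats::rnorm(2, 0, replicate_sd / 2),
                            stringsAsFactors = FALSE)
  }
  plate <- do.call(rbind, rows)
  plate$cq <- pmin(pmax(plate$cq, 1), 44.9)
  truth <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(sample = character(0), assay = character(0),
               replicate = integer(0))
  attr(truth, "expr") <- log2(cpm0 + 1)
  list(plate = plate, truth = truth)
}
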