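# Pipeline orchestration: a single declarative config drives
# simulate -> qc -> normalize -> de -> specific -> panel -> enrichment
# -> csf -> qpcr, with per-stage derived seeds and a hashed run manifest.

.default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_outliers = 6L, outlier_severity = 1.0,
                    outlier_groups = c("HealthCtl", "HospCtl", "CIS")),
    inputs = list(),
    qc = list(min_count = 10, min_fraction = 0.5, outlier_rule = "tukey"),
    normalize = list(prior_count = 0.5),
    de = list(engine = "ql", p_threshold = 0.01, lfc_threshold = 1.0,
              contrasts = c("CIS:HealthCtl", "CIS:HospCtl",
                            "RRMS:HealthCtl", "RRMS:HospCtl",
                            "VI:HealthCtl", "VI:HospCtl", "RRMS:CIS")),
    enrichment = list(alpha = 0.01, min_mirnas = 3),
    csf = list(high_serum_fraction = 128 / 2151, offset_log10 = 2,
               noise_sd = 0.2),
    qpcr = list(replicate_sd = 0.2, outlier_rate = 0.05)
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills defaults, performs
#' all range and path checks, and aggregates every error found rather
#' than stopping at the first.
#'
#' @param config YAML path or list (see the shipped
#'   `extdata/demo_config.yaml` for the schema).
#' @return list with `config` (defaults merged) and `errors` (character
#'   vector; empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(list(config = NULL,
                                          errors = paste("no such config file:", config)))
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.default_config(), config %||% list())
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    add("seed must be an integer")
  if (!in01(cfg$qc$min_fraction)) add("qc.min_fraction must be in (0, 1]")
  if (!is.numeric(cfg$qc$min_count) || cfg$qc$min_count < 0)
    add("qc.min_count must be >= 0")
  if (!cfg$qc$outlier_rule %in% c("tukey", "quartile"))
    add("qc.outlier_rule must be 'tukey' or 'quartile'")
  if (!is.numeric(cfg$normalize$prior_count) || cfg$normalize$prior_count < 0)
    add("normalize.prior_count must be >= 0")
  if (!cfg$de$engine %in% c("ql", "exact"))
    add("de.engine must be 'ql' or 'exact'")
  if (!in01(cfg$de$p_threshold)) add("de.p_threshold must be in (0, 1]")
  if (!is.numeric(cfg$de$lfc_threshold) || cfg$de$lfc_threshold < 0)
    add("de.lfc_threshold must be >= 0")
  if (!all(grepl("^[^:]+:[^:]+$", cfg$de$contrasts)))
    add("de.contrasts entries must look like 'GroupA:GroupB'")
  if (!in01(cfg$enrichment$alpha)) add("enrichment.alpha must be in (0, 1]")
  if (!is.numeric(cfg$enrichment$min_mirnas) || cfg$enrichment$min_mirnas < 1)
    add("enrichment.min_mirnas must be >= 1")
  if (!is.numeric(cfg$csf$high_serum_fraction) ||
      cfg$csf$high_serum_fraction <= 0 || cfg$csf$high_serum_fraction >= 1)
    add("csf.high_serum_fraction must be in (0, 1)")
  if (!is.numeric(cfg$qpcr$outlier_rate) || cfg$qpcr$outlier_rate < 0 ||
      cfg$qpcr$outlier_rate >= 1)
    add("qpcr.outlier_rate must be in [0, 1)")
  for (f in c("counts", "meta", "target_map", "gmt")) {
    p <- cfg$inputs[[f]] %||% cfg$enrichment[[f]]
    if (!is.null(p) && !file.exists(p))
      add(sprintf("path for '%s' does not resolve: %s", f, p))
  }
  list(config = cfg, errors = errs)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in dependency order, writing each stage's
#' artifacts (TSV tables, JSON summaries) under `out_dir` plus a run
#' manifest listing every output file with its content hash, the merged
#' parameters and the seed.  A single global seed fans out to
#' deterministic per-stage seeds, so identical config and seed produce
#' byte-identical outputs.  A stage failure aborts with the failing
#' stage named; artifacts already written are retained and the manifest
#' carries a `failed` marker.
#'
#' @param config YAML path or list (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  v <- validate_config(config)
  if (length(v$errors))
    stopf("invalid config:\n- %s", paste(v$errors, collapse = "\n- "))
  cfg <- v$config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(out_dir, name)
    files <<- c(files, p)
    p
  }
  stage <- "init"
  manifest <- list(seed = cfg$seed, parameters = cfg, stages = list())
  log_stage <- function(name, ...) {
    info <- list(...)
    manifest$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
  }

  result <- tryCatch({
    # --- simulate / load -------------------------------------------------
    stage <- "simulate"
    if (!is.null(cfg$inputs$counts)) {
      raw <- read_counts(cfg$inputs$counts, cfg$inputs$meta)
      truth <- NULL
    } else {
      sim_args <- cfg$simulate
      n_out <- sim_args$n_outliers %||% 0L
      sev <- sim_args$outlier_severity %||% 1.0
      out_groups <- sim_args$outlier_groups
      sim_args$n_outliers <- NULL
      sim_args$outlier_severity <- NULL
      sim_args$outlier_groups <- NULL
      sim_args$seed <- derive_seed(cfg$seed, "simulate")
      sim <- simulate_counts(do.call(sim_params, sim_args))
      raw <- sim$counts
      truth <- sim$truth
      if (n_out > 0) {
        if (!is.null(out_groups))
          out_groups <- intersect(out_groups, raw$meta$group)
        if (!length(out_groups)) out_groups <- list(NULL)
        # spread victims evenly across the designated groups so no group
        # loses more than its share of intact subjects
        quota <- rep(n_out %/% length(out_groups), length(out_groups))
        if (n_out %% length(out_groups))
          quota[seq_len(n_out %% length(out_groups))] <-
            quota[seq_len(n_out %% length(out_groups))] + 1
        victims <- character(0)
        for (i in seq_along(out_groups)) {
          if (quota[i] == 0) next
          inj <- inject_outlier_subjects(raw, quota[i], sev,
                                         groups = out_groups[[i]],
                                         seed = derive_seed(cfg$seed,
                                                            paste0("outliers", i)))
          raw <- inj$counts
          victims <- c(victims, inj$truth$outlier_subject_ids)
        }
        truth$outlier_subject_ids <- sort(victims)
      }
      .write_json(list(cis_down_ids = truth$cis_down_ids,
                       rrms_up_ids = truth$rrms_up_ids,
                       outlier_subject_ids = truth$outlier_subject_ids),
                  out("truth.json"))
    }
    write_counts(raw, out("counts.tsv"), out("meta.tsv"))
    log_stage("simulate", mirnas = nrow(raw$counts),
              samples = ncol(raw$counts))

    # --- qc --------------------------------------------------------------
    stage <- "qc"
    qc <- run_qc(raw, min_count = cfg$qc$min_count,
                 min_fraction = cfg$qc$min_fraction,
                 rule = cfg$qc$outlier_rule)
    .write_json(list(n_mirnas_in = qc$report$n_mirnas_in,
                     n_mirnas_kept = qc$report$n_mirnas_kept,
                     rho = as.list(round(qc$report$rho, 6)),
                     excluded_subjects = qc$report$excluded_subjects,
                     umi_bias_rho = qc$report$umi_bias_rho),
                out("qc.json"))
    clean <- qc$counts
    log_stage("qc", mirnas_kept = qc$report$n_mirnas_kept,
              excluded = length(qc$report$excluded_subjects))

    # --- normalize -------------------------------------------------------
    stage <- "normalize"
    factors <- tmm_factors(clean)
    norm <- cpm_matrix(clean, factors,
                       prior_count = cfg$normalize$prior_count)
    utils::write.table(data.frame(sample_id = names(factors),
                                  tmm_factor = factors,
                                  library_size = library_sizes(clean)),
                       out("factors.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(mirna_id = rownames(norm$values),
                                  round(norm$values, 6),
                                  check.names = FALSE),
                       out("cpm.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_stage("normalize", samples = length(factors))

    # --- differential expression ----------------------------------------
    stage <- "de"
    de <- list()
    for (ct in cfg$de$contrasts) {
      ab <- strsplit(ct, ":", fixed = TRUE)[[1]]
      nm <- paste0(ab[1], "_vs_", ab[2])
      det <- de_test(clean, ab[1], ab[2], engine = cfg$de$engine,
                     p_threshold = cfg$de$p_threshold,
                     lfc_threshold = cfg$de$lfc_threshold)
      de[[nm]] <- det
      utils::write.table(det, out(paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_stage("de", contrasts = length(de))

    # --- stage-specific sets --------------------------------------------
    stage <- "specific"
    sets <- stage_specific_sets(de, p_threshold = cfg$de$p_threshold,
                                lfc_threshold = cfg$de$lfc_threshold)
    .write_json(list(cis_specific_down = sets$cis_specific_down,
                     rrms_specific_up = sets$rrms_specific_up,
                     venn_partition = sets$venn_partition,
                     hospctl_support = sets$hospctl_support),
                out("specific_sets.json"))
    log_stage("specific", cis_down = length(sets$cis_specific_down),
              rrms_up = length(sets$rrms_specific_up))

    # --- biomarker panels -------------------------------------------------
    stage <- "panel"
    meta <- clean$meta
    panel_one <- function(markers, ga, gb) {
      if (length(markers) < 1) return(NULL)
      subj <- meta$sample_id[meta$group %in% c(ga, gb)]
      labels <- setNames(meta$group[match(subj, meta$sample_id)], subj)
      z <- zscore_markers(norm, markers, subj)
      pan <- build_panel(z, labels[colnames(z)], positive = ga)
      gt <- panel_group_test(pan$subject_scores, labels[colnames(z)])
      list(comparison = paste0(ga, "_vs_", gb),
           ranked = pan$ranked_markers,
           trajectory = pan$trajectory,
           selected_panel = pan$selected_panel,
           panel_auc = pan$panel_auc, panel_p = pan$panel_p,
           t = gt$t, t_df = gt$df, t_p = gt$p)
    }
    panels <- Filter(Negate(is.null), list(
      panel_one(sets$cis_specific_down, "CIS", "HealthCtl"),
      panel_one(sets$rrms_specific_up, "RRMS", "HealthCtl"),
      panel_one(union(sets$cis_specific_down, sets$rrms_specific_up),
                "RRMS", "CIS")))
    # EDSS correlation for the CIS-RRMS panel, per group
    edss_cor <- NULL
    mixed <- union(sets$cis_specific_down, sets$rrms_specific_up)
    if (length(mixed) >= 1 && "edss" %in% names(meta)) {
      subj <- meta$sample_id[meta$group %in% c("CIS", "RRMS")]
      z <- zscore_markers(norm, mixed, subj)
      labels <- setNames(meta$group[match(subj, meta$sample_id)], subj)
      ranked <- rank_markers(z, labels[colnames(z)], positive = "RRMS")
      pan <- build_panel(z, labels[colnames(z)], ranked, positive = "RRMS")
      edss_cor <- lapply(c("CIS", "RRMS"), function(g) {
        ids <- meta$sample_id[meta$group == g & !is.na(meta$edss)]
        ids <- intersect(ids, names(pan$subject_scores))
        if (length(ids) < 8) return(NULL)
        cc <- correlate_panel_covariate(pan$subject_scores[ids],
                                        meta$edss[match(ids, meta$sample_id)])
        c(list(group = g), cc[c("method", "r", "p")])
      })
      edss_cor <- Filter(Negate(is.null), edss_cor)
    }
    .write_json(list(panels = panels, edss_correlation = edss_cor),
                out("panel.json"))
    log_stage("panel", n_panels = length(panels))

    # --- enrichment -------------------------------------------------------
    stage <- "enrichment"
    tm_path <- cfg$enrichment$target_map %||%
      system.file("extdata", "synthetic_target_map.tsv", package = "evmir")
    gmt_path <- cfg$enrichment$gmt %||%
      system.file("extdata", "synthetic_pathways.gmt", package = "evmir")
    enr_written <- FALSE
    if (nzchar(tm_path) && nzchar(gmt_path) &&
        length(sets$rrms_specific_up)) {
      tm <- load_target_map(tm_path)
      db <- load_gmt(gmt_path)
      # map simulated marker IDs onto the target map's miRNAs by rank so
      # the synthetic fixtures remain usable with simulated IDs
      query_mirnas <- sets$rrms_specific_up
      if (!any(query_mirnas %in% names(tm)))
        query_mirnas <- names(tm)[seq_len(min(length(query_mirnas),
                                              length(tm)))]
      targets <- collect_targets(query_mirnas, tm)
      enr <- suppressWarnings(ora(targets, db))
      sig <- filter_pathways(enr, alpha = cfg$enrichment$alpha,
                             min_mirnas = cfg$enrichment$min_mirnas)
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(sig, out("enrichment_significant.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      enr_written <- TRUE
      log_stage("enrichment", pathways = nrow(enr), significant = nrow(sig))
    } else log_stage("enrichment", skipped = TRUE)

    # --- serum-CSF comparison --------------------------------------------
    stage <- "csf"
    rrms_ids <- meta$sample_id[meta$group == "RRMS"]
    serum_vals <- norm$values[, rrms_ids, drop = FALSE]
    csf_sim <- simulate_matched_csf(serum_vals,
                                    high_serum_fraction = cfg$csf$high_serum_fraction,
                                    offset_log10 = cfg$csf$offset_log10,
                                    noise_sd = cfg$csf$noise_sd,
                                    seed = derive_seed(cfg$seed, "csf"))
    pairs <- pair_compartments(serum_vals, csf_sim$csf, csf_sim$subject_map)
    pairs <- split_populations(pairs)
    cor_sim <- correlate_population(pairs, "similar")
    cor_high <- correlate_population(pairs, "high_serum")
    per_mirna <- if (length(sets$rrms_specific_up))
      per_mirna_correlation(serum_vals, csf_sim$csf, sets$rrms_specific_up,
                            csf_sim$subject_map) else NULL
    .write_json(list(sizes = as.list(attr(pairs, "sizes")),
                     threshold = attr(pairs, "threshold"),
                     similar = cor_sim[c("r", "p", "n", "method")],
                     high_serum = cor_high[c("r", "p", "n", "method")],
                     per_mirna = per_mirna),
                out("compartment.json"))
    log_stage("csf", paired = nrow(pairs))

    # --- qPCR validation --------------------------------------------------
    stage <- "qpcr"
    qp_targets <- utils::head(sets$rrms_specific_up, 2)
    if (length(qp_targets) >= 1) {
      qp_subj <- meta$sample_id[meta$group %in% c("CIS", "RRMS")]
      qp_counts <- subset_samples(clean, qp_subj)
      qp <- simulate_qpcr(qp_counts, qp_targets,
                          replicate_sd = cfg$qpcr$replicate_sd,
                          outlier_rate = cfg$qpcr$outlier_rate,
                          seed = derive_seed(cfg$seed, "qpcr"))
      plate <- replicate_qc(qp$plate)
      dcq <- delta_cq(plate)
      labels <- setNames(meta$group[match(qp_subj, meta$sample_id)], qp_subj)
      cmp <- compare_groups_dcq(dcq, labels)
      xc <- do.call(rbind, lapply(c("CIS", "RRMS"), function(g)
        cbind(group = g,
              crossplatform_correlation(dcq, norm, group = g,
                                        labels = labels))))
      utils::write.table(dcq, out("qpcr_delta_cq.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      .write_json(list(group_comparison = cmp, crossplatform = xc),
                  out("qpcr.json"))
      log_stage("qpcr", targets = length(qp_targets))
    } else log_stage("qpcr", skipped = TRUE)

    TRUE
  }, error = function(e) {
    manifest$failed <<- list(stage = stage, message = conditionMessage(e))
    FALSE
  })

  manifest$files <- lapply(setNames(basename(files), basename(files)),
                           function(b) unname(tools::md5sum(file.path(out_dir, b))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  if (!result)
    stopf("pipeline failed at stage '%s': %s", stage,
          manifest$failed$message)
  invisible(manifest)
}
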