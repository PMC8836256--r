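#' Load a miRNA-to-target map from TSV
#'
#' Expects a header-less or headered two-column TSV (`mirna_id`, `gene`);
#' duplicate pairs are collapsed.
#'
#' @param path TSV file path.
#' @param provenance free-text provenance tag stored on the result
#'   (e.g. `"validated, 3'UTR"`).
#' @return named list mapping miRNA ID to a character vector of target
#'   gene symbols, with attribute `"provenance"`.
#' @export
load_target_map <- function(path, provenance = "validated, 3'UTR") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stopf("target map needs 2 columns (mirna_id, gene)")
    names(df)[1:2] <- c("mirna_id", "gene")
  }
  if (!nrow(df)) stopf("empty target map: %s", path)
  if (any(!nzchar(df$gene)) || anyNA(df$gene))
    stopf("empty gene symbols in target map")
  tm <- lapply(split(df$gene, df$mirna_id), function(g) sort(unique(g)))
  attr(tm, "provenance") <- provenance
  tm
}

#' Load pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, `name<TAB>description<TAB>gene...`.
#' The gene universe is the union of all sets.
#'
#' @param path GMT file path.
#' @return object of class `ev_pathway_db`: list with `pathways` (named
#'   list of gene vectors) and `universe`.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  pw <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("malformed GMT line %d: fewer than 3 fields", i)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("malformed GMT line %d: no genes", i)
    if (parts[1] %in% names(pw)) stopf("duplicate pathway '%s' (line %d)",
                                       parts[1], i)
    pw[[parts[1]]] <- sort(genes)
  }
  structure(list(pathways = pw, universe = sort(unique(unlist(pw)))),
            class = "ev_pathway_db")
}

#' Collect validated targets of a miRNA set
#'
#' Union of the target sets of the query miRNAs; miRNAs absent from the
#' map are reported under `unmapped`, never silently dropped.
#'
#' @param mirnas character vector of miRNA IDs.
#' @param target_map named list from [load_target_map()].
#' @return list with `genes` (union), `per_mirna` (named list of target
#'   sets for the mapped query miRNAs) and `unmapped`.
#' @export
collect_targets <- function(mirnas, target_map) {
  mapped <- intersect(mirnas, names(target_map))
  per <- target_map[mapped]
  list(genes = sort(unique(unlist(per))),
       per_mirna = per,
       unmapped = setdiff(mirnas, mapped))
}

#' Hypergeometric pathway over-representation analysis
#'
#' Per pathway, the raw p-value is the upper-tail hypergeometric
#' probability of drawing at least the observed overlap `k` when `n`
#' query genes are drawn from a universe of `N` genes of which `K` are in
#' the pathway.  The universe is the union of all pathway genes; query
#' genes outside it are dropped with a warning.  BH adjustment is across
#' all pathways tested.  When per-miRNA target contributions are
#' supplied, each pathway records which query miRNAs contribute at least
#' one overlapping target.
#'
#' @param query gene symbol vector, or the result of [collect_targets()]
#'   (which also supplies the per-miRNA contributions).
#' @param db an `ev_pathway_db` from [load_gmt()].
#' @param per_mirna optional named list of per-miRNA target gene sets.
#' @return data.frame of class `ev_enrichment`: `pathway`, `k`, `K`, `n`,
#'   `N`, `raw_p`, `adj_p`, `n_mirnas`, `mirnas` (comma-separated),
#'   `targets` (comma-separated overlap genes), sorted by raw p.
#' @export
ora <- function(query, db, per_mirna = NULL) {
  stopifnot(inherits(db, "ev_pathway_db"))
  if (is.list(query) && !is.null(query$genes)) {
    per_mirna <- per_mirna %||% query$per_mirna
    query <- query$genes
  }
  if (!length(db$universe)) stopf("empty gene universe")
  outside <- setdiff(query, db$universe)
  if (length(outside))
    warnf("%d query genes outside the universe dropped", length(outside))
  q <- intersect(unique(query), db$universe)
  n <- length(q)
  N <- length(db$universe)
  rows <- lapply(names(db$pathways), function(pw) {
    genes <- db$pathways[[pw]]
    hit <- intersect(q, genes)
    k <- length(hit)
    K <- length(genes)
    raw_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    contrib <- character(0)
    if (!is.null(per_mirna))
      contrib <- names(per_mirna)[vapply(per_mirna, function(g)
        length(intersect(g, hit)) > 0, logical(1))]
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, raw_p = raw_p,
               n_mirnas = length(contrib),
               mirnas = paste(contrib, collapse = ","),
               targets = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$raw_p)
  out <- out[order(out$raw_p, out$pathway),
             c("pathway", "k", "K", "n", "N", "raw_p", "adj_p",
               "n_mirnas", "mirnas", "targets")]
  rownames(out) <- NULL
  class(out) <- c("ev_enrichment", "data.frame")
  out
}

#' Filter enriched pathways by the study's inclusion rule
#'
#' Keeps pathways with BH-adjusted p below `alpha` and at least
#' `min_mirnas` contributing miRNAs, sorted by ascending adjusted p.
#'
#' @param res an `ev_enrichment` data.frame from [ora()].
#' @param alpha adjusted-p threshold (default 0.01).
#' @param min_mirnas minimum contributing miRNAs (default 3).
#' @return filtered, re-sorted data.frame.
#' @export
filter_pathways <- function(res, alpha = 0.01, min_mirnas = 3) {
  keep <- res$adj_p < alpha & res$n_mirnas >= min_mirnas
  out <- res[keep, , drop = FALSE]
  out <- out[order(out$adj_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
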