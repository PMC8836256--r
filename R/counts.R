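#' miRNA x sample UMI count matrix with sample metadata
#'
#' Container coupling a non-negative integer count matrix (rows = mature
#' miRNA IDs, columns = sample IDs) with a per-sample metadata table.
#' Metadata rows are matched to columns by `sample_id` and reordered to
#' the column order of the matrix.
#'
#' @param counts numeric matrix of non-negative counts with unique
#'   rownames (miRNA IDs) and colnames (sample IDs).
#' @param meta data.frame with at least columns `sample_id` and `group`;
#'   optional columns `compartment`, `edss`, `total_reads`.
#' @return an object of class `ev_counts`: a list with elements
#'   `counts` (matrix) and `meta` (data.frame).
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("miR-", 1:3), paste0("S", 1:4)))
#' meta <- data.frame(sample_id = paste0("S", 1:4),
#'                    group = c("A", "A", "B", "B"))
#' ev_counts(m, meta)
#' @export
ev_counts <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stopf("counts must be numeric")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      anyDuplicated(rownames(counts)))
    stopf("counts must have unique rownames (miRNA IDs)")
  if ((ncol(counts) > 0 && is.null(colnames(counts))) ||
      anyDuplicated(colnames(counts)))
    stopf("counts must have unique colnames (sample IDs)")
  if (!is.data.frame(meta)) stopf("meta must be a data.frame")
  if (!all(c("sample_id", "group") %in% names(meta)))
    stopf("meta must contain columns 'sample_id' and 'group'")
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in meta")
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing))
    stopf("meta is missing samples: %s", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (anyNA(meta$group)) stopf("every sample needs a group label")
  structure(list(counts = counts, meta = meta), class = "ev_counts")
}

#' @export
print.ev_counts <- function(x, ...) {
  cat(sprintf("ev_counts: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ev_counts <- function(x) dim(x$counts)

#' Per-sample library sizes (total UMI counts)
#' @param x an `ev_counts` object.
#' @return named numeric vector of column sums.
#' @export
library_sizes <- function(x) colSums(x$counts)

#' Per-sample number of detected miRNAs (count >= `min_count`)
#' @param x an `ev_counts` object.
#' @param min_count detection threshold, default 1.
#' @return named integer vector.
#' @export
detected_per_sample <- function(x, min_count = 1) {
  colSums(x$counts >= min_count)
}

#' Subset samples of an `ev_counts` object
#' @param x an `ev_counts` object.
#' @param sample_ids character vector of sample IDs to keep (order kept).
#' @return an `ev_counts` object restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  bad <- setdiff(sample_ids, colnames(x$counts))
  if (length(bad)) stopf("unknown samples: %s", paste(bad, collapse = ", "))
  ev_counts(x$counts[, sample_ids, drop = FALSE],
            x$meta[match(sample_ids, x$meta$sample_id), , drop = FALSE])
}

#' Write / read a count matrix and its metadata as TSV
#'
#' The count TSV has a first column `mirna_id` followed by one column per
#' sample; the metadata TSV mirrors the `meta` data.frame.
#'
#' @param x an `ev_counts` object.
#' @param counts_path,meta_path file paths.
#' @return `write_counts` returns the paths invisibly; `read_counts`
#'   returns an `ev_counts` object.
#' @export
write_counts <- function(x, counts_path, meta_path) {
  df <- data.frame(mirna_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "mirna_id") stopf("first column must be 'mirna_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mirna_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  ev_counts(m, meta)
}
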