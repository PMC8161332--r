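#' Construct an OTU table
#'
#' Light container pairing an OTUs x samples count matrix with a per-sample
#' metadata tibble. Counts must be non-negative integers with unique row
#' (OTU) and column (sample) names and positive column sums; `meta` must
#' cover every sample via its `sample_id` column.
#'
#' @param counts Integer matrix, OTUs as rows, samples as columns.
#' @param meta Tibble with at least `sample_id`; typically also `station`,
#'   `layer` (`"surface"`/`"DCM"`), `lat`, `lon`.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs OTU rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate OTU ids.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample ids.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (any(colSums(counts) == 0)) {
    abort(paste0("Samples with zero total counts: ",
                 paste(colnames(counts)[colSums(counts) == 0], collapse = ", ")))
  }
  meta <- as_tibble(meta)
  if (is.null(meta$sample_id)) abort("`meta` must have a `sample_id` column.")
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing)) {
    abort(paste0("`meta` does not cover samples: ", paste(missing, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, meta = meta), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  depths <- colSums(x$counts)
  cat(sprintf("  per-sample depth: %d - %d (median %d)\n",
              min(depths), max(depths), as.integer(median(depths))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

# Counts matrix from an otu_table or a bare matrix.
get_counts <- function(x) {
  if (inherits(x, "otu_table")) x$counts else as.matrix(x)
}

# Per-sample relative abundances (columns sum to 1).
relative_abundance <- function(x) {
  m <- get_counts(x)
  sweep(m, 2, colSums(m), "/")
}

#' Read an OTU table and sample metadata from disk
#'
#' The OTU table is a TSV with OTUs as rows, an `otu_id` first column, and
#' one column per sample; the metadata a CSV keyed by `sample_id`.
#'
#' @param counts_path Path to the TSV count table.
#' @param meta_path Path to the metadata CSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, meta_path) {
  tab <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(tab)[1] != "otu_id") abort("First column of the OTU TSV must be `otu_id`.")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$otu_id
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  otu_table(counts, meta)
}

#' Write an OTU table (and its metadata) to disk
#'
#' @param x An [otu_table()].
#' @param counts_path,meta_path Output paths (TSV counts, CSV metadata).
#' @return `counts_path`, invisibly.
#' @export
write_otu_table <- function(x, counts_path, meta_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  tab <- bind_cols(tibble(otu_id = rownames(x$counts)), as_tibble(x$counts))
  readr::write_tsv(tab, counts_path)
  if (!is.null(meta_path)) readr::write_csv(x$meta, meta_path)
  invisible(counts_path)
}
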