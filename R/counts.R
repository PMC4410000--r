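#' Construct a count matrix with sample metadata
#'
#' The container for all expression statistics in the package: an integer
#' gene-by-sample matrix plus a sample metadata table with `sample_id`,
#' `sex` (`"male"`, `"female"` or `"unknown"`) and `stage` columns.
#' Metadata rows must match matrix columns exactly and in order.
#'
#' @param counts Integer matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids). All values must be
#'   non-negative integers.
#' @param metadata `data.frame` with columns `sample_id`, `sex`, `stage`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `metadata`.
#' @export
count_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop("counts must be non-negative integers; first offending cell: gene '",
         rownames(counts)[bad[1]], "', sample '", colnames(counts)[bad[2]], "'")
  }
  storage.mode(counts) <- "double"
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "stage")
  miss <- setdiff(req, colnames(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$sex <- as.character(metadata$sex)
  if (!all(metadata$sex %in% c("male", "female", "unknown"))) {
    stop("metadata sex must be 'male', 'female' or 'unknown'")
  }
  only_meta <- setdiff(metadata$sample_id, colnames(counts))
  only_counts <- setdiff(colnames(counts), metadata$sample_id)
  if (length(only_meta) || length(only_counts)) {
    stop("metadata/counts sample mismatch; only in metadata: [",
         paste(only_meta, collapse = ", "), "]; only in counts: [",
         paste(only_counts, collapse = ", "), "]")
  }
  counts <- counts[, metadata$sample_id, drop = FALSE]
  structure(list(counts = counts, metadata = metadata),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  sex: ", paste(names(table(x$metadata$sex)),
                       table(x$metadata$sex), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its sample metadata from TSV
#'
#' The counts file is a TSV with a `gene_id` first column and one column
#' per sample; the metadata file is a TSV with `sample_id`, `sex` and
#' `stage` columns. Non-integer cells and metadata/column mismatches are
#' rejected with the offending cell or sample named. Samples are
#' reordered to follow the metadata.
#'
#' @param counts_path,metadata_path Paths to the two TSV files.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path) {
  for (p in c(counts_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "gene_id") {
    stop("counts TSV must have 'gene_id' as its first column")
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  if (!is.numeric(mat) || any(is.na(mat)) || any(mat != round(mat))) {
    bad <- which(is.na(suppressWarnings(as.numeric(mat))) |
                   suppressWarnings(as.numeric(mat)) !=
                   round(suppressWarnings(as.numeric(mat))))
    idx <- arrayInd(bad[1], dim(mat))
    stop("non-integer count at gene '", rownames(mat)[idx[1]],
         "', sample '", colnames(mat)[idx[2]], "'")
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' Write a count matrix and metadata to TSV
#'
#' Inverse of [read_counts()]; a write-then-read round trip reproduces
#' the object exactly.
#'
#' @param x A [count_matrix()].
#' @param counts_path,metadata_path Output paths.
#' @return Invisibly, `counts_path`.
#' @export
write_counts <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Subset a count matrix by sample
#'
#' @param x A [count_matrix()].
#' @param sample_ids Character vector of sample ids to keep.
#' @return A [count_matrix()] restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "count_matrix"))
  miss <- setdiff(sample_ids, x$metadata$sample_id)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  count_matrix(x$counts[, sample_ids, drop = FALSE],
               x$metadata[match(sample_ids, x$metadata$sample_id), ,
                          drop = FALSE])
}
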