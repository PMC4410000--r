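#' Chromosome class from chromosome name
#'
#' Maps a chromosome name to the class used throughout the package:
#' `"X"` for chrX, `"Y"` for chrY, `"autosome"` for anything else.
#' The class is a pure function of the name; no annotation lookup is
#' involved.
#'
#' @param chromosome Character vector of chromosome names (e.g. `"chrX"`,
#'   `"chr1"`, `"X"`).
#' @return Character vector in `{"X","Y","autosome"}`.
#' @export
chromosome_class <- function(chromosome) {
  cls <- rep("autosome", length(chromosome))
  cls[chromosome %in% c("chrX", "X")] <- "X"
  cls[chromosome %in% c("chrY", "Y")] <- "Y"
  cls
}

#' Construct a gene annotation table
#'
#' Coordinates are stored 0-based half-open (BED convention) in the
#' columns `start` and `end`. The `class` column is derived from the
#' chromosome name via [chromosome_class()].
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chromosome Character vector of chromosome names.
#' @param start,end Integer-like vectors, 0-based half-open; `start < end`.
#' @param strand Character vector of `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation` with columns
#'   `gene_id`, `chromosome`, `start`, `end`, `strand`, `class`.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, strand) {
  gene_id <- as.character(gene_id)
  chromosome <- as.character(chromosome)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  stopifnot(length(chromosome) == n, length(start) == n,
            length(end) == n, length(strand) == n)
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0)) {
    stop("annotation coordinates must be non-negative numbers")
  }
  if (any(start >= end)) {
    bad <- gene_id[start >= end]
    stop("start must be < end; offending gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  ann <- data.frame(
    gene_id = gene_id, chromosome = chromosome,
    start = start, end = end, strand = strand,
    class = chromosome_class(chromosome),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotation from BED6 or a GTF subset
#'
#' BED coordinates are used as-is (0-based half-open). GTF coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention on read. For GTF, the `gene_id` attribute is required and
#' one record per gene is expected.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gtf"`.
#' @return A [gene_annotation()] table.
#' @export
read_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("annotation file is empty: ", path)
  if (format == "bed") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L)) {
      stop("malformed BED line (need 6 columns) at line ",
           which(nf < 6L)[1])
    }
    m <- do.call(rbind, fields)
    gene_annotation(
      gene_id = m[, 4], chromosome = m[, 1],
      start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
      strand = m[, 6]
    )
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L)) {
      stop("malformed GTF line (need 9 columns) at line ",
           which(nf < 9L)[1])
    }
    m <- do.call(rbind, fields)
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", m[, 9])
    no_id <- !grepl("gene_id", m[, 9], fixed = TRUE)
    if (any(no_id)) {
      stop("GTF line without gene_id attribute at line ", which(no_id)[1])
    }
    gene_annotation(
      gene_id = ids, chromosome = m[, 1],
      start = as.numeric(m[, 4]) - 1, end = as.numeric(m[, 5]),
      strand = m[, 7]
    )
  }
}

#' Write gene annotation as BED6
#'
#' @param annotation A [gene_annotation()] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  bed <- data.frame(
    annotation$chromosome,
    format(annotation$start, scientific = FALSE, trim = TRUE),
    format(annotation$end, scientific = FALSE, trim = TRUE),
    annotation$gene_id, 0L, annotation$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcriptional start sites of annotated genes
#'
#' The TSS of a `+` strand gene is its annotated start; for a `-` strand
#' gene it is the annotated end. Positions are 0-based.
#'
#' @param annotation A [gene_annotation()] table.
#' @return Numeric vector of TSS positions, named by gene id.
#' @export
tss_positions <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end)
  names(tss) <- annotation$gene_id
  tss
}
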