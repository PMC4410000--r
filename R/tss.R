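#' Construct a TSS-window signal table
#'
#' Per-gene read signal in a window of `2 * halfwidth` bp centred on the
#' TSS, for one sex's ChIP-seq track (replicate-averaged or single).
#' `kind` records whether values are window totals or per-base means;
#' the two differ by a constant factor that cancels in all downstream
#' fold-enrichment statistics.
#'
#' @param values Named numeric vector, one non-negative value per gene.
#' @param annotation A [gene_annotation()] covering the same genes.
#' @param sex `"male"` or `"female"`.
#' @param halfwidth Window half-width in bp.
#' @param kind `"total"` or `"mean"`.
#' @return A `data.frame` of class `tss_window_counts` with columns
#'   `gene_id`, `value`, `chromosome`, `class`, and attributes
#'   `halfwidth`, `sex`, `kind`.
#' @export
tss_window_counts <- function(values, annotation, sex = c("male", "female"),
                              halfwidth = 1500, kind = c("total", "mean")) {
  sex <- match.arg(sex)
  kind <- match.arg(kind)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (is.null(names(values))) stop("values must be named by gene id")
  miss <- setdiff(annotation$gene_id, names(values))
  if (length(miss)) {
    stop("missing window values for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  v <- values[annotation$gene_id]
  if (any(is.na(v)) || any(v < 0)) stop("window values must be >= 0")
  out <- data.frame(gene_id = annotation$gene_id, value = as.numeric(v),
                    chromosome = annotation$chromosome,
                    class = annotation$class, stringsAsFactors = FALSE)
  attr(out, "halfwidth") <- halfwidth
  attr(out, "sex") <- sex
  attr(out, "kind") <- kind
  class(out) <- c("tss_window_counts", "data.frame")
  out
}

#' Total TSS-window signal excluding chrY
#'
#' The library total used by the dosage model: the summed window signal
#' over all genes not on chrY.
#'
#' @param x A [tss_window_counts()] table.
#' @return A single non-negative number.
#' @export
total_excluding_y <- function(x) {
  stopifnot(inherits(x, "tss_window_counts"))
  sum(x$value[x$class != "Y"])
}

#' Average coverage over TSS windows from a bedGraph track
#'
#' Computes, for every annotated gene, the mean coverage over the window
#' `[TSS - halfwidth, TSS + halfwidth)` by interval-overlap weighting.
#' The TSS is the annotated start for `+` strand genes and the annotated
#' end for `-` strand genes. Windows are truncated at position 0 and the
#' mean is then taken over the covered width. Genes on chromosomes absent
#' from the coverage track get 0 with a warning. The result is invariant
#' to splitting any bedGraph interval into adjacent pieces.
#'
#' @param coverage_path Path to a 4-column bedGraph file.
#' @param annotation A [gene_annotation()] table.
#' @param halfwidth Window half-width in bp (default 1500, i.e. a 3 kb
#'   window).
#' @param sex Sex label to attach to the resulting track.
#' @return A [tss_window_counts()] with `kind = "mean"`.
#' @export
average_over_tss <- function(coverage_path, annotation, halfwidth = 1500,
                             sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(annotation, "gene_annotation"), halfwidth > 0)
  if (nrow(annotation) == 0L) stop("annotation is empty")
  cov <- rtracklayer::import(coverage_path, format = "bedGraph")
  if (length(cov)) {
    # overlapping intervals make per-base coverage ambiguous
    ov <- GenomicRanges::findOverlaps(cov, cov, ignore.strand = TRUE)
    if (any(S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov))) {
      stop("bedGraph has overlapping intervals; coverage is ambiguous")
    }
  }
  tss0 <- tss_positions(annotation)   # 0-based
  win_start0 <- pmax(tss0 - halfwidth, 0)
  win_end0 <- tss0 + halfwidth
  win <- GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(start = win_start0 + 1, end = win_end0)
  )
  absent <- setdiff(unique(annotation$chromosome),
                    as.character(GenomicRanges::seqnames(cov)))
  if (length(absent)) {
    warning("chromosome(s) absent from coverage, genes set to 0: ",
            paste(absent, collapse = ", "))
  }
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(win, cov, ignore.strand = TRUE)
  })
  vals <- numeric(nrow(annotation))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    inter <- GenomicRanges::pintersect(win[qh], cov[sh])
    contrib <- GenomicRanges::width(inter) * cov$score[sh]
    agg <- tapply(contrib, qh, sum)
    vals[as.integer(names(agg))] <- as.numeric(agg)
  }
  width_covered <- win_end0 - win_start0
  vals <- vals / width_covered
  names(vals) <- annotation$gene_id
  tss_window_counts(vals, annotation, sex = sex, halfwidth = halfwidth,
                    kind = "mean")
}
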