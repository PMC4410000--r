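#' Bundled eight-cell embryo dimorphism signature
#'
#' The published 69-gene sexually dimorphic signature defined from
#' RNA-seq of 6 male and 6 female mouse eight-cell embryos (adjusted
#' p < 0.1, |log2FC male/female| > 0.5), with genomic coordinates,
#' baseMean and log2 fold change as printed. Chromosome class is derived
#' from the chromosome column.
#'
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, `baseMean`, `log2fc`, `class`.
#' @export
eightcell_signature <- function() {
  path <- system.file("extdata", "eightcell_signature.tsv",
                      package = "dimorphseq")
  sig <- utils::read.delim(path, stringsAsFactors = FALSE)
  sig$class <- chromosome_class(sig$chromosome)
  sig
}

#' Bundled fetal-to-adult liver conservation counts
#'
#' Per-chromosome-class counts of genes called sexually dimorphic in
#' fetal liver and the subset also dimorphic in adult liver, as reported
#' for the 394-gene fetal and 1488-gene adult liver signatures.
#'
#' @return A `data.frame` with columns `class`, `fetal_dimorphic`,
#'   `also_adult`.
#' @export
liver_conservation_counts <- function() {
  path <- system.file("extdata", "liver_conservation_counts.tsv",
                      package = "dimorphseq")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled liver signature sizes
#'
#' Numbers of sexually dimorphic genes called in fetal (17.5 dpc) and
#' adult mouse liver under the same thresholds (adjusted p < 0.1,
#' |log2FC| > 0.5).
#'
#' @return A `data.frame` with columns `stage`, `n_dimorphic`.
#' @export
liver_signature_sizes <- function() {
  path <- system.file("extdata", "liver_signature_sizes.tsv",
                      package = "dimorphseq")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Summarise a signature's chromosome-class composition
#'
#' Counts signature members per chromosome class and the fraction on the
#' sex chromosomes.
#'
#' @param signature A data.frame with a `class` column (e.g.
#'   [eightcell_signature()] or [define_signature()] output).
#' @return A list: `n`, `n_x`, `n_y`, `n_autosome`,
#'   `sex_chromosome_fraction`.
#' @export
signature_class_summary <- function(signature) {
  stopifnot(is.data.frame(signature), "class" %in% colnames(signature))
  cls <- signature$class
  n <- length(cls)
  n_x <- sum(cls == "X"); n_y <- sum(cls == "Y")
  list(n = n, n_x = n_x, n_y = n_y, n_autosome = n - n_x - n_y,
       sex_chromosome_fraction = (n_x + n_y) / n)
}

#' Conservation fractions from paired dimorphism counts
#'
#' Given per-class counts of genes dimorphic at one stage and the subset
#' also dimorphic at another, returns the conserved fraction per class
#' and overall.
#'
#' @param counts A `data.frame` with columns `class`, `fetal_dimorphic`,
#'   `also_adult` (as from [liver_conservation_counts()]).
#' @return A `data.frame` with columns `class`, `n`, `conserved`,
#'   `fraction`; the final row is the overall total.
#' @export
conservation_fractions <- function(counts = liver_conservation_counts()) {
  stopifnot(all(c("class", "fetal_dimorphic", "also_adult") %in%
                  colnames(counts)))
  if (any(counts$also_adult > counts$fetal_dimorphic)) {
    stop("conserved counts exceed stage totals")
  }
  out <- data.frame(class = c(counts$class, "total"),
                    n = c(counts$fetal_dimorphic, sum(counts$fetal_dimorphic)),
                    conserved = c(counts$also_adult, sum(counts$also_adult)),
                    stringsAsFactors = FALSE)
  out$fraction <- out$conserved / out$n
  out
}
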