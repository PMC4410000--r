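#' Project a signature's sex-biased expression onto another dataset
#'
#' For each signature gene present in the target, computes
#' `log2fc = mean(VST, males) - mean(VST, females)` where VST is
#' `log2(normalised count + 1)` ([vst_counts()]). Group-mean differences
#' are used rather than refitting the NB model because comparison
#' datasets are often tiny (2-5 samples per sex). Genes absent from the
#' target are listed in attribute `"absent"`, never silently dropped. A
#' per-gene conservation flag marks `|log2fc| > 0.5`, and per-class
#' median/IQR summaries are attached for box-plot style reporting.
#'
#' @param signature A `dimorph_signature` (or any data.frame with
#'   `gene_id`, `log2fc` and optionally `class` columns).
#' @param target A [count_matrix()] containing both sexes.
#' @param sex Optional sample sex labels overriding target metadata.
#' @param dataset Label recorded on the result.
#' @param conserved_lfc Absolute log2FC above which a gene is flagged
#'   conserved (default 0.5).
#' @return A `data.frame` of class `projection_result` with columns
#'   `gene_id`, `class`, `signature_log2fc`, `log2fc`, `conserved`;
#'   attributes `dataset`, `absent`, `class_summary`.
#' @export
project_logfc <- function(signature, target, sex = NULL,
                          dataset = "target", conserved_lfc = 0.5) {
  stopifnot(is.data.frame(signature), inherits(target, "count_matrix"))
  if (is.null(sex)) sex <- target$metadata$sex
  male <- sex == "male"; female <- sex == "female"
  if (!any(male) || !any(female)) stop("target must contain both sexes")
  present <- signature$gene_id %in% rownames(target$counts)
  if (!any(present)) stop("no signature gene present in target")
  v <- vst_counts(target)
  ids <- signature$gene_id[present]
  lfc <- rowMeans(v[ids, male, drop = FALSE]) -
    rowMeans(v[ids, female, drop = FALSE])
  cls <- if ("class" %in% colnames(signature)) {
    signature$class[present]
  } else NA_character_
  out <- data.frame(gene_id = ids, class = cls,
                    signature_log2fc = signature$log2fc[present],
                    log2fc = unname(lfc),
                    conserved = abs(lfc) > conserved_lfc,
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(out$log2fc, out$class), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(x), q25 = q[1], median = q[2], q75 = q[3])
  }))
  attr(out, "dataset") <- dataset
  attr(out, "absent") <- signature$gene_id[!present]
  attr(out, "class_summary") <- summ
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Directional consistency of sex bias between two datasets
#'
#' Counts, over genes shared between two per-gene log2FC tables, how many
#' have the same versus opposite sign, and tests the split against a
#' 50:50 null with a one-sample chi-square goodness-of-fit test (1 df, no
#' continuity correction). Genes with `|log2fc|` below `floor` in either
#' table (or exactly zero, which carries no direction) are excluded; the
#' floor is recorded.
#'
#' @param lfc_a,lfc_b Data frames with `gene_id` and `log2fc` columns, or
#'   named numeric vectors of log2FC.
#' @param floor Dimorphism floor; default 0 counts every shared signed
#'   gene.
#' @return A list of class `consistency_result`: `n_same`, `n_opposite`,
#'   `fraction_consistent`, `statistic`, `p_value`, `floor`.
#' @export
directional_consistency <- function(lfc_a, lfc_b, floor = 0) {
  a <- as_lfc_vector(lfc_a); b <- as_lfc_vector(lfc_b)
  shared <- intersect(names(a), names(b))
  a <- a[shared]; b <- b[shared]
  keep <- abs(a) >= floor & abs(b) >= floor & a != 0 & b != 0
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) stop("no shared genes after applying the floor")
  n_same <- sum(sign(a) == sign(b))
  n_opp <- length(a) - n_same
  n <- n_same + n_opp
  expected <- n / 2
  stat <- (n_same - expected)^2 / expected + (n_opp - expected)^2 / expected
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(n_same = n_same, n_opposite = n_opp,
                 fraction_consistent = n_same / n,
                 statistic = stat, p_value = p, floor = floor),
            class = "consistency_result")
}

as_lfc_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "log2fc") %in% colnames(x))) {
      stop("log2FC table needs gene_id and log2fc columns")
    }
    stats::setNames(x$log2fc, x$gene_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a (gene_id, log2fc) data.frame or a named numeric vector")
  }
}

#' Correlate per-gene log2FC between two datasets
#'
#' @param lfc_a,lfc_b As in [directional_consistency()].
#' @param method `"spearman"` or `"pearson"`.
#' @return A list with `estimate`, `p_value`, `n` and `method`.
#' @export
correlate_logfc <- function(lfc_a, lfc_b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- as_lfc_vector(lfc_a); b <- as_lfc_vector(lfc_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  a <- a[shared]; b <- b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant log2FC vector")
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(shared), method = method)
}

#' X:autosome expression ratio
#'
#' Mean normalised expression of expressed X-linked genes divided by that
#' of expressed autosomal genes, restricted to samples of one sex.
#' Y-linked genes are excluded from both terms. The expression filter is
#' [detect_expressed()]'s default rule, applied to the sex-restricted
#' matrix. Used to compare X dosage between the sexes (Ohno-style
#' ratios).
#'
#' @param counts A [count_matrix()].
#' @param annotation A [gene_annotation()] covering the genes.
#' @param sex `"male"` or `"female"`.
#' @return A single positive number.
#' @export
x_autosome_ratio <- function(counts, annotation, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(counts, "count_matrix"),
            inherits(annotation, "gene_annotation"))
  ids <- counts$metadata$sample_id[counts$metadata$sex == sex]
  if (length(ids) == 0L) stop("no samples of sex: ", sex)
  sub <- subset_samples(counts, ids)
  expressed <- detect_expressed(sub)
  cls <- annotation$class[match(expressed, annotation$gene_id)]
  x_ids <- expressed[!is.na(cls) & cls == "X"]
  a_ids <- expressed[!is.na(cls) & cls == "autosome"]
  if (length(x_ids) == 0L || length(a_ids) == 0L) {
    stop("empty X or autosome class after expression filtering")
  }
  nm <- normalized_counts(sub)
  mean(nm[x_ids, , drop = FALSE]) / mean(nm[a_ids, , drop = FALSE])
}
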