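#' Median-of-ratios size factors
#'
#' The standard RNA-seq depth estimator: per sample, the median over
#' genes with non-zero counts in every sample of the ratio of the count
#' to the gene's geometric mean across samples. Factors are rescaled to
#' geometric mean 1, so a matrix whose second column is exactly twice the
#' first gets factors `(1/sqrt(2), sqrt(2))`.
#'
#' @param counts A [count_matrix()] or a bare numeric matrix.
#' @return Positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    stop("no gene has non-zero counts in all samples; ",
         "consider library-size (column total) scaling instead")
  }
  lg <- log(m[keep, , drop = FALSE])
  loggeo <- rowMeans(lg)
  logsf <- apply(lg - loggeo, 2, stats::median)
  sf <- exp(logsf - mean(logsf))
  names(sf) <- colnames(m)
  sf
}

#' Normalised counts
#'
#' Counts divided per sample by [size_factors()]; falls back to
#' column-total (library-size) scaling when the median-of-ratios
#' estimator is degenerate (no gene non-zero in all samples).
#'
#' @param counts A [count_matrix()].
#' @return Numeric matrix of normalised counts.
#' @export
normalized_counts <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  sf <- tryCatch(size_factors(m), error = function(e) {
    tot <- colSums(m)
    if (any(tot == 0)) stop("sample(s) with zero total counts: ",
                            paste(colnames(m)[tot == 0], collapse = ", "))
    tot / exp(mean(log(tot)))
  })
  sweep(m, 2, sf, `/`)
}

#' Variance-stabilising transform
#'
#' The transform used for plotting and signature projection:
#' `log2(normalised count + 1)`.
#'
#' @param counts A [count_matrix()].
#' @return Matrix of transformed values.
#' @export
vst_counts <- function(counts) {
  log2(normalized_counts(counts) + 1)
}

#' Detect expressed genes
#'
#' Default rule `"all_samples_nonzero"` takes a gene as expressed when it
#' has a non-zero count in every sample (the literal "expressed across
#' all samples" criterion). Alternative rules `"mean_ge:<t>"` keep genes
#' whose mean normalised count is `>= t` (inclusive).
#'
#' @param counts A [count_matrix()].
#' @param rule `"all_samples_nonzero"` or `"mean_ge:<threshold>"`.
#' @return Character vector of expressed gene ids, with the rule recorded
#'   in attribute `"rule"`.
#' @export
detect_expressed <- function(counts, rule = "all_samples_nonzero") {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (identical(rule, "all_samples_nonzero")) {
    ids <- rownames(m)[rowSums(m > 0) == ncol(m)]
  } else if (grepl("^mean_ge:", rule)) {
    thr <- suppressWarnings(as.numeric(sub("^mean_ge:", "", rule)))
    if (is.na(thr)) stop("unknown rule: ", rule)
    nm <- normalized_counts(counts)
    ids <- rownames(m)[rowMeans(nm) >= thr]
  } else {
    stop("unknown rule: ", rule)
  }
  attr(ids, "rule") <- rule
  ids
}

# Profile the NB log-mean of one group by Fisher scoring, vectorised over
# genes. y: genes x samples counts; sf: size factors; alpha: per-gene
# dispersion. Returns list(eta, info): eta = log group mean (common-scale),
# info = Fisher information for eta at the optimum.
nb_group_fit <- function(y, sf, alpha, max_iter = 50L, tol = 1e-8) {
  ybar <- rowSums(y) / sum(sf)
  eta <- log(pmax(ybar, 1e-8))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf                      # genes x samples
    w <- mu / (1 + alpha * mu)
    score <- rowSums((y - mu) / (1 + alpha * mu))
    info <- rowSums(w)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  list(eta = eta, info = rowSums(mu / (1 + alpha * mu)))
}

# Method-of-moments gene-wise NB dispersion on normalised counts with
# group-specific means, moderated 50:50 toward a fitted 1/mean trend.
estimate_dispersions <- function(norm, male, female) {
  n <- ncol(norm)
  mm <- rowMeans(norm[, male, drop = FALSE])
  mf <- rowMeans(norm[, female, drop = FALSE])
  ss <- rowSums((norm[, male, drop = FALSE] - mm)^2) +
    rowSums((norm[, female, drop = FALSE] - mf)^2)
  s2 <- ss / (n - 2)
  mu <- rowMeans(norm)
  # Var(y/s) ~ mu * mean(1/s) + alpha * mu^2 under the NB model
  xim <- mean(1 / attr(norm, "sf"))
  raw <- (s2 - mu * xim) / mu^2
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, 1e-8)
  # parametric trend alpha(mu) = a0 + a1/mu on genes with real signal
  use <- mu > 0 & is.finite(raw)
  trend <- rep(stats::median(raw[use]), length(raw))
  if (sum(use) >= 10) {
    fit <- tryCatch(stats::lm(raw[use] ~ I(1 / mu[use])),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      a0 <- max(stats::coef(fit)[1], 1e-8)
      a1 <- max(stats::coef(fit)[2], 0)
      trend <- a0 + a1 / pmax(mu, 1e-8)
    }
  }
  pmax(0.5 * raw + 0.5 * trend, 1e-8)
}

#' Negative-binomial two-group dimorphism test
#'
#' For every tested gene, fits a log-link negative-binomial GLM with sex
#' as the single covariate (size factors as offsets), estimates the
#' gene-wise dispersion by method of moments on normalised counts
#' (floored at 1e-8) moderated half-and-half toward a fitted
#' mean-dispersion trend, and performs a Wald test on the sex
#' coefficient. The log2 fold change is reported male-over-female, so a
#' female-specific gene such as Xist carries a strongly negative value.
#' Benjamini-Hochberg adjustment is applied across tested (i.e.
#' expression-filtered) genes only; genes failing the filter still get
#' estimates and a raw p-value when they have any counts, but are
#' flagged untested and carry no adjusted p.
#'
#' Genes with all-zero counts in one sex have a divergent NB group-mean
#' estimate; these are fitted with a 0.5 pseudocount added to every
#' sample of that gene, yielding a finite, strongly-signed estimate.
#'
#' @param counts A [count_matrix()] with at least 2 samples per sex.
#' @param sex Optional character vector of sample sexes overriding the
#'   metadata (e.g. from [call_sex()]).
#' @param filter_rule Expression-filter rule passed to
#'   [detect_expressed()].
#' @return A `data.frame` of class `dimorphism_table` with columns
#'   `gene_id`, `baseMean`, `log2fc`, `se`, `pvalue`, `padj`, `tested`.
#' @export
test_dimorphism <- function(counts, sex = NULL,
                            filter_rule = "all_samples_nonzero") {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(sex)) sex <- counts$metadata$sex
  if (length(sex) != ncol(counts$counts)) {
    stop("sex labels must match the number of samples")
  }
  male <- which(sex == "male"); female <- which(sex == "female")
  if (length(male) < 2 || length(female) < 2) {
    stop("need at least 2 samples per sex (got ", length(male), " male, ",
         length(female), " female)")
  }
  m <- counts$counts
  sf <- tryCatch(size_factors(m), error = function(e) {
    tot <- colSums(m); tot / exp(mean(log(tot)))
  })
  norm <- sweep(m, 2, sf, `/`)
  attr(norm, "sf") <- sf
  base_mean <- rowMeans(norm)

  expressed <- detect_expressed(counts, rule = filter_rule)
  nonzero <- rowSums(m) > 0
  tested <- rownames(m) %in% expressed & nonzero
  res <- data.frame(gene_id = rownames(m), baseMean = base_mean,
                    log2fc = NA_real_, se = NA_real_, pvalue = NA_real_,
                    padj = NA_real_, tested = tested,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(nonzero)) {
    y <- m[nonzero, , drop = FALSE]
    # genes with one sex all zero: pseudocount 0.5 on every sample
    zero_grp <- rowSums(y[, male, drop = FALSE]) == 0 |
      rowSums(y[, female, drop = FALSE]) == 0
    y[zero_grp, ] <- y[zero_grp, , drop = FALSE] + 0.5
    nt <- sweep(y, 2, sf, `/`)
    attr(nt, "sf") <- sf
    alpha <- estimate_dispersions(nt, male, female)
    fm <- nb_group_fit(y[, male, drop = FALSE], sf[male], alpha)
    ff <- nb_group_fit(y[, female, drop = FALSE], sf[female], alpha)
    b1 <- fm$eta - ff$eta                     # natural-log scale
    se <- sqrt(1 / pmax(fm$info, 1e-12) + 1 / pmax(ff$info, 1e-12))
    z <- b1 / se
    p <- 2 * stats::pnorm(-abs(z))
    res$log2fc[nonzero] <- b1 / log(2)
    res$se[nonzero] <- se / log(2)
    res$pvalue[nonzero] <- p
    res$padj[tested] <- stats::p.adjust(res$pvalue[tested], method = "BH")
  }
  attr(res, "filter_rule") <- filter_rule
  attr(res, "n_tested") <- sum(tested)
  class(res) <- c("dimorphism_table", "data.frame")
  res
}

#' Threshold a dimorphism table into a signature
#'
#' Keeps tested genes with `padj < padj_threshold` and
#' `|log2fc| > lfc_threshold`, both strictly (a gene at `padj = 0.1` or
#' `|log2fc| = 0.5` exactly is excluded). Members are annotated with
#' their chromosome class when an annotation is supplied, and per-class
#' counts are attached.
#'
#' @param table A `dimorphism_table` from [test_dimorphism()].
#' @param padj_threshold,lfc_threshold Strictly positive thresholds
#'   (defaults 0.1 and 0.5).
#' @param annotation Optional [gene_annotation()] for chromosome classes.
#' @return A `data.frame` of class `dimorph_signature`; attributes
#'   `padj_threshold`, `lfc_threshold`, `class_counts`.
#' @export
define_signature <- function(table, padj_threshold = 0.1,
                             lfc_threshold = 0.5, annotation = NULL) {
  stopifnot(inherits(table, "dimorphism_table") || is.data.frame(table))
  if (padj_threshold <= 0 || lfc_threshold <= 0) {
    stop("thresholds must be > 0")
  }
  if (!all(c("padj", "log2fc") %in% colnames(table))) {
    stop("table must have padj and log2fc columns")
  }
  keep <- !is.na(table$padj) & table$padj < padj_threshold &
    abs(table$log2fc) > lfc_threshold
  sig <- as.data.frame(table[keep, , drop = FALSE])
  rownames(sig) <- NULL
  if (!is.null(annotation)) {
    sig$class <- annotation$class[match(sig$gene_id, annotation$gene_id)]
  } else if (!"class" %in% colnames(sig)) {
    sig$class <- NA_character_
  }
  attr(sig, "padj_threshold") <- padj_threshold
  attr(sig, "lfc_threshold") <- lfc_threshold
  attr(sig, "class_counts") <- table(factor(sig$class,
                                            levels = c("X", "Y", "autosome")))
  class(sig) <- c("dimorph_signature", "data.frame")
  sig
}
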