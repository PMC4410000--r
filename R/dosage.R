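#' Fit the X-chromosome dosage model
#'
#' Compares female ChIP-seq TSS-window signal on chrX against the
#' expectation under pure 2x X dosage, built from the male track(s).
#' With `N_i` the (replicate-averaged) male window signal of X gene `i`,
#' `N_total` the male total over all genes excluding chrY (chrX
#' included), and `N_x` the male total over chrX genes, the scaled male
#' density is
#' \deqn{S_i = 2 N_i / (N_{total} + N_x)}
#' i.e. the density expected for a female sample carrying two male-like X
#' chromosomes. The observed female density is
#' \deqn{A_i = N_i^{female} / N_{ftotal}}
#' with `N_ftotal` the female total excluding chrY. Both are invariant to
#' rescaling either track, and `A_i = S_i` for every gene when female X
#' signal is exactly twice the male with matched totals.
#'
#' @param male A [tss_window_counts()] track or a list of replicate
#'   tracks (averaged per gene before totals are formed).
#' @param female A female track or list of replicates over the same
#'   annotation.
#' @param annotation A [gene_annotation()]; the fit covers its X genes.
#' @return A `data.frame` of class `dosage_model_fit` with one row per X
#'   gene: `gene_id`, `n_male`, `n_female`, `S`, `A`, `zero` (flag for
#'   genes with no signal in either sex); attributes `N_total`, `N_x`,
#'   `N_ftotal`, `halfwidth`.
#' @export
fit_dosage_model <- function(male, female, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  male <- average_replicates(male)
  female <- average_replicates(female)
  for (trk in list(male, female)) {
    if (!identical(trk$gene_id, annotation$gene_id)) {
      stop("tracks must cover the annotation genes in order")
    }
  }
  x_idx <- which(annotation$class == "X")
  if (length(x_idx) == 0L) stop("annotation has no X genes")
  n_total <- total_excluding_y(male)
  n_x <- sum(male$value[x_idx])
  n_ftotal <- total_excluding_y(female)
  if (n_total + n_x == 0) stop("degenerate input: male track has no signal")
  if (n_ftotal == 0) stop("degenerate input: female track has no signal")
  n_m <- male$value[x_idx]
  n_f <- female$value[x_idx]
  fit <- data.frame(gene_id = annotation$gene_id[x_idx],
                    n_male = n_m, n_female = n_f,
                    S = 2 * n_m / (n_total + n_x),
                    A = n_f / n_ftotal,
                    zero = n_m == 0 & n_f == 0,
                    stringsAsFactors = FALSE)
  attr(fit, "N_total") <- n_total
  attr(fit, "N_x") <- n_x
  attr(fit, "N_ftotal") <- n_ftotal
  attr(fit, "halfwidth") <- attr(male, "halfwidth")
  attr(fit, "kind") <- attr(male, "kind")
  class(fit) <- c("dosage_model_fit", "data.frame")
  fit
}

average_replicates <- function(x) {
  if (inherits(x, "tss_window_counts")) return(x)
  if (!is.list(x) || !length(x) ||
      !all(vapply(x, inherits, logical(1), "tss_window_counts"))) {
    stop("expected a tss_window_counts track or a list of them")
  }
  out <- x[[1]]
  if (length(x) > 1) {
    for (r in x[-1]) {
      if (!identical(r$gene_id, out$gene_id)) {
        stop("replicate tracks cover different genes")
      }
      out$value <- out$value + r$value
    }
    out$value <- out$value / length(x)
  }
  out
}

#' Female fold enrichment of a gene set beyond dosage
#'
#' `FE_female = sum(A_i) / sum(S_i)` over the set: the ratio of observed
#' female density to the pure-2x-dosage expectation, read-weighted across
#' the set. Values above 1 mean female signal in excess of dosage; below
#' 1, female depletion.
#'
#' @param fit A `dosage_model_fit` from [fit_dosage_model()].
#' @param gene_set Character vector of fitted X gene ids.
#' @return A single positive number.
#' @export
set_fold_enrichment <- function(fit, gene_set) {
  stopifnot(inherits(fit, "dosage_model_fit"))
  if (length(gene_set) == 0L) stop("gene_set is empty")
  unknown <- setdiff(gene_set, fit$gene_id)
  if (length(unknown)) {
    stop("gene(s) not in the fitted background: ",
         paste(unknown, collapse = ", "))
  }
  i <- match(gene_set, fit$gene_id)
  s <- sum(fit$S[i])
  if (s == 0) stop("fold enrichment undefined: set has zero scaled male density")
  sum(fit$A[i]) / s
}

#' Permutation p-value for a set's fold enrichment
#'
#' Null distribution: the fold enrichment of sets of the same size drawn
#' uniformly (without replacement) from the background of fitted X genes
#' with non-zero scaled density. The p-value is `(b + 1) / (n_perm + 1)`
#' where `b` counts null sets at least as extreme as the observed one
#' (two-sided: `|log FE_null| >= |log FE_obs|`), so it is never zero.
#'
#' @param fit A `dosage_model_fit`.
#' @param gene_set Character vector of fitted X gene ids, a strict subset
#'   of the background.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Random seed, recorded on the result.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A list of class `fe_result`: `fe`, `p_value`, `n_perm`,
#'   `seed`, `set_size`, `background_size`, `alternative`.
#' @export
permutation_pvalue <- function(fit, gene_set, n_perm = 10000, seed = 1L,
                               alternative = c("two_sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(fit, "dosage_model_fit"))
  fe_obs <- set_fold_enrichment(fit, gene_set)
  bg <- fit$gene_id[fit$S > 0]
  k <- length(gene_set)
  if (k >= length(bg)) {
    stop("gene_set must be smaller than the background of fitted genes")
  }
  A <- fit$A[match(bg, fit$gene_id)]
  S <- fit$S[match(bg, fit$gene_id)]
  null_fe <- with_seed(seed, {
    vapply(seq_len(n_perm), function(...) {
      i <- sample.int(length(bg), k)
      sum(A[i]) / sum(S[i])
    }, numeric(1))
  })
  b <- switch(alternative,
    two_sided = sum(abs(log(null_fe)) >= abs(log(fe_obs))),
    greater = sum(null_fe >= fe_obs),
    less = sum(null_fe <= fe_obs)
  )
  structure(list(fe = fe_obs, p_value = (b + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, set_size = k,
                 background_size = length(bg),
                 alternative = alternative),
            class = "fe_result")
}
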