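#' Fold enrichment of the overlap of two gene sets
#'
#' Observed overlap `|A intersect B|` against the expectation
#' `|A| * |B| / |background|` under independent draws from the
#' background, with an upper-tail permutation p-value obtained by
#' redrawing `set_a` uniformly from the background and recounting the
#' overlap; `p = (b + 1) / (n_perm + 1)`.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   `background`.
#' @param background Character vector defining the universe; always
#'   caller-supplied (e.g. all expressed genes, or all detected X genes).
#' @param n_perm Number of permutations.
#' @param seed Random seed, recorded.
#' @return A list of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `n_background`, `expected`, `fold_enrichment`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
overlap_fold_enrichment <- function(set_a, set_b, background,
                                    n_perm = 10000, seed = 1L) {
  if (length(background) == 0L) stop("background is empty")
  background <- unique(background)
  set_a <- unique(set_a); set_b <- unique(set_b)
  for (nm in c("set_a", "set_b")) {
    s <- get(nm)
    out <- setdiff(s, background)
    if (length(out)) {
      stop(nm, " element(s) outside the background: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  expected <- length(set_a) * length(set_b) / length(background)
  if (expected == 0) stop("fold enrichment undefined: expected overlap is 0")
  obs <- length(intersect(set_a, set_b))
  in_b <- background %in% set_b
  null_overlap <- with_seed(seed, {
    vapply(seq_len(n_perm), function(...) {
      sum(in_b[sample.int(length(background), length(set_a))])
    }, numeric(1))
  })
  b <- sum(null_overlap >= obs)
  structure(list(n_a = length(set_a), n_b = length(set_b), n_overlap = obs,
                 n_background = length(background), expected = expected,
                 fold_enrichment = obs / expected,
                 p_value = (b + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "overlap_result")
}

#' Hypergeometric pathway enrichment with a custom background
#'
#' One-sided upper-tail hypergeometric test of each pathway's overlap
#' with the query, after intersecting every pathway with the
#' caller-supplied background. Pathways with empty background
#' intersection are excluded from testing and from the Bonferroni
#' denominator. Rows are sorted by adjusted p.
#'
#' @param query Character vector of gene ids, a subset of `background`.
#' @param pathway_sets Named list mapping pathway id to a character
#'   vector of gene ids (e.g. from [read_gmt()]).
#' @param background Character vector defining the universe.
#' @return A `data.frame` with columns `pathway`, `k` (overlap), `K`
#'   (pathway size in background), `n` (query size), `N` (background
#'   size), `p_value`, `p_bonferroni`.
#' @export
pathway_enrichment <- function(query, pathway_sets, background) {
  if (length(background) == 0L) stop("background is empty")
  background <- unique(background)
  query <- unique(query)
  out <- setdiff(query, background)
  if (length(out)) {
    stop("query element(s) outside the background: ",
         paste(utils::head(out, 5), collapse = ", "))
  }
  sets <- lapply(pathway_sets, intersect, background)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0L) {
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    K <- length(sets[[id]])
    k <- length(intersect(query, sets[[id]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res[order(res$p_bonferroni, res$p_value), , drop = FALSE]
}

#' Read a newline-delimited gene-id list
#'
#' @param path Path to a text file with one gene id per line; blank lines
#'   and `#` comments are ignored.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read pathway sets from a GMT file
#'
#' GMT format: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("malformed GMT line (need >= 3 fields) at line ", bad[1])
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}
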