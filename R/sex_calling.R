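#' Call sample sex from marker-gene expression
#'
#' Assigns each sample to male or female from the expression of a female
#' marker (Xist, X-linked, female-biased) and a male marker (Eif2s3y,
#' Y-linked, male-only). Marker counts are size-factor normalised
#' (library-size fallback when the median-of-ratios estimator is
#' degenerate) and log2(x+1) transformed; samples are then partitioned
#' into two groups in this 2-D space by a deterministic assignment:
#' centres initialised at the two mutually farthest samples, one
#' assignment pass, one centre update, one reassignment pass. The group
#' with higher mean male-marker expression is labelled male.
#'
#' @param counts A [count_matrix()] with at least 2 samples and both
#'   markers among its genes.
#' @param female_marker,male_marker Gene ids of the two markers.
#' @return A `data.frame` of class `sex_call` with columns `sample_id`,
#'   `called_sex`, `female_marker_log2`, `male_marker_log2` and `margin`
#'   (difference between the distances to the two group centres; larger
#'   is a more confident call).
#' @export
call_sex <- function(counts, female_marker = "Xist",
                     male_marker = "Eif2s3y") {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (ncol(m) < 2) stop("need at least 2 samples to call sex")
  for (mk in c(female_marker, male_marker)) {
    if (!mk %in% rownames(m)) stop("marker gene absent from counts: ", mk)
  }
  nm <- normalized_counts(counts)
  pts <- cbind(f = log2(nm[female_marker, ] + 1),
               m = log2(nm[male_marker, ] + 1))
  d <- as.matrix(stats::dist(pts))
  if (max(d) == 0) stop("all samples identical in marker space; cannot call sex")
  # farthest pair initialisation, then a single refinement pass
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  centres <- pts[c(far[1], far[2]), , drop = FALSE]
  assign_to <- function(centres) {
    d1 <- sqrt(rowSums((pts - matrix(centres[1, ], nrow(pts), 2,
                                     byrow = TRUE))^2))
    d2 <- sqrt(rowSums((pts - matrix(centres[2, ], nrow(pts), 2,
                                     byrow = TRUE))^2))
    list(grp = ifelse(d1 <= d2, 1L, 2L), margin = abs(d1 - d2))
  }
  a <- assign_to(centres)
  for (g in 1:2) {
    if (any(a$grp == g)) {
      centres[g, ] <- colMeans(pts[a$grp == g, , drop = FALSE])
    }
  }
  a <- assign_to(centres)
  male_mean <- tapply(pts[, "m"], a$grp, mean)
  male_grp <- as.integer(names(male_mean)[which.max(male_mean)])
  called <- ifelse(a$grp == male_grp, "male", "female")
  out <- data.frame(sample_id = colnames(m), called_sex = called,
                    female_marker_log2 = unname(pts[, "f"]),
                    male_marker_log2 = unname(pts[, "m"]),
                    margin = unname(a$margin),
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_call", "data.frame")
  out
}
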