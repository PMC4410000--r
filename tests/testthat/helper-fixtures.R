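# Small fixtures built in code, shared across test files.

tiny_annotation <- function() {
  gene_annotation(
    gene_id = c("Xist", "Xg1", "Eif2s3y", "a1", "a2"),
    chromosome = c("chrX", "chrX", "chrY", "chr1", "chr2"),
    start = c(100, 5000, 200, 300, 400),
    end = c(900, 6000, 800, 900, 1000),
    strand = c("-", "+", "+", "+", "-")
  )
}

tiny_counts <- function(mat = NULL, sex = c("male", "male", "female", "female")) {
  if (is.null(mat)) {
    mat <- matrix(c(10, 20, 30, 40,
                    5, 5, 5, 5,
                    100, 90, 110, 95), nrow = 3, byrow = TRUE,
                  dimnames = list(c("g1", "g2", "g3"),
                                  paste0("s", 1:4)))
  }
  count_matrix(mat, data.frame(sample_id = colnames(mat), sex = sex,
                               stage = "test"))
}

write_bedgraph <- function(lines) {
  path <- tempfile(fileext = ".bedGraph")
  writeLines(lines, path)
  path
}

# a standard small simulated dataset used by several files
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_autosomal = 300, n_x = 30, n_y = 2, seed = seed, ...)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  list(config = cfg, annotation = ann, counts = sim$counts,
       truth = sim$truth)
}

# build a dosage fit directly from chosen (S, A) pairs
manual_dosage_fit <- function(S, A, ids = sprintf("x%02d", seq_along(S))) {
  fit <- data.frame(gene_id = ids, n_male = S, n_female = A,
                    S = S, A = A, zero = S == 0 & A == 0,
                    stringsAsFactors = FALSE)
  class(fit) <- c("dosage_model_fit", "data.frame")
  fit
}
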