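# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' statistical structure of a low-input mouse embryo RNA-seq study:
#' negative-binomial counts with gene-wise dispersion, X/Y/autosomal gene
#' classes, a 2x female X dosage (log2 shift of 1 before any
#' inactivation), a small planted autosomal dimorphic fraction, sparse
#' marker genes (Xist female-biased, Eif2s3y male-only), and log-normal
#' per-sample library sizes.
#'
#' @param n_autosomal,n_x,n_y Numbers of autosomal, chrX and chrY genes.
#' @param n_male,n_female Samples per sex (defaults 6 and 6, a typical
#'   discovery design for individual eight-cell embryos).
#' @param baseline_log_mean_mu,baseline_log_mean_sd Mean and sd of the
#'   per-gene natural-log expression mean (log-normal across genes).
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha*mu^2`);
#'   scalar or per-gene vector; must be > 0.
#' @param x_dosage_log2 Female-vs-male log2 shift applied to X genes
#'   (1.0 = full 2x dosage; 0 = complete inactivation-balanced dosage).
#' @param dimorphic_fraction Fraction of autosomal genes planted as
#'   dimorphic, balanced in sign.
#' @param effect_size_log2 Magnitude (|log2FC male/female|) of planted
#'   autosomal effects.
#' @param library_size_mu,library_size_cv Mean and coefficient of
#'   variation of the log-normal per-sample depth multiplier.
#' @param xist_log2fc,eif2s3y_log2fc Planted marker log2FC(male/female)
#'   defaults, matching the magnitudes observed for these markers in
#'   eight-cell embryos (-9.01 and +5.94).
#' @param batch_effect_log2 Optional per-gene batch shift applied to a
#'   random half of the samples (off by default; hook for modelling
#'   litter/exposure structure).
#' @param seed Random seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal = 1000, n_x = 60, n_y = 3,
                       n_male = 6, n_female = 6,
                       baseline_log_mean_mu = log(100),
                       baseline_log_mean_sd = 1.5,
                       dispersion = 0.05,
                       x_dosage_log2 = 1.0,
                       dimorphic_fraction = 0.05,
                       effect_size_log2 = 2.0,
                       library_size_mu = 1.0,
                       library_size_cv = 0.2,
                       xist_log2fc = -9.01,
                       eif2s3y_log2fc = 5.94,
                       batch_effect_log2 = 0,
                       seed = 1L) {
  cfg <- list(n_autosomal = n_autosomal, n_x = n_x, n_y = n_y,
              n_male = n_male, n_female = n_female,
              baseline_log_mean_mu = baseline_log_mean_mu,
              baseline_log_mean_sd = baseline_log_mean_sd,
              dispersion = dispersion,
              x_dosage_log2 = x_dosage_log2,
              dimorphic_fraction = dimorphic_fraction,
              effect_size_log2 = effect_size_log2,
              library_size_mu = library_size_mu,
              library_size_cv = library_size_cv,
              xist_log2fc = xist_log2fc,
              eif2s3y_log2fc = eif2s3y_log2fc,
              batch_effect_log2 = batch_effect_log2,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  cnt <- c("n_autosomal", "n_x", "n_y", "n_male", "n_female")
  for (f in cnt) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop("invalid config: ", f, " must be a non-negative integer")
    }
  }
  if (cfg$n_male + cfg$n_female < 2) {
    stop("invalid config: need at least 2 samples in total")
  }
  if (any(cfg$dispersion <= 0)) stop("invalid config: dispersion must be > 0")
  if (cfg$dimorphic_fraction < 0 || cfg$dimorphic_fraction > 1) {
    stop("invalid config: dimorphic_fraction must be in [0,1]")
  }
  if (cfg$library_size_mu <= 0 || cfg$library_size_cv < 0) {
    stop("invalid config: library size parameters out of range")
  }
  invisible(cfg)
}

#' Simulate a gene annotation
#'
#' Places `n_autosomal` genes on chr1..chr19 (round-robin), `n_x` on chrX
#' and `n_y` on chrY with non-overlapping intervals, random strands and
#' unique ids. Whenever at least one X and one Y gene are requested, the
#' marker genes `Xist` (chrX) and `Eif2s3y` (chrY) are included.
#'
#' @param config A [sim_config()].
#' @return A [gene_annotation()] table.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  n_a <- config$n_autosomal; n_x <- config$n_x; n_y <- config$n_y
  ids <- chroms <- character(0)
  if (n_x >= 1) {
    ids <- c(ids, "Xist", if (n_x > 1) sprintf("Xgene%03d", seq_len(n_x - 1)))
    chroms <- c(chroms, rep("chrX", n_x))
  }
  if (n_y >= 1) {
    ids <- c(ids, "Eif2s3y", if (n_y > 1) sprintf("Ygene%03d", seq_len(n_y - 1)))
    chroms <- c(chroms, rep("chrY", n_y))
  }
  if (n_a >= 1) {
    ids <- c(ids, sprintf("Agene%04d", seq_len(n_a)))
    chroms <- c(chroms, paste0("chr", rep(1:19, length.out = n_a)))
  }
  if (length(ids) == 0L) stop("invalid config: no genes requested")
  with_seed(config$seed, {
    # lay genes end to end per chromosome: widths 1-10 kb, 5 kb gaps
    widths <- sample(1000:10000, length(ids), replace = TRUE)
    start <- numeric(length(ids))
    for (ch in unique(chroms)) {
      i <- which(chroms == ch)
      start[i] <- cumsum(c(10000, widths[i][-length(i)] + 5000))
    }
    strand <- sample(c("+", "-"), length(ids), replace = TRUE)
    gene_annotation(ids, chroms, start, start + widths, strand)
  })
}

#' Simulate a count matrix with ground truth
#'
#' Draws NB counts (mean `mu`, variance `mu + alpha*mu^2`) under the
#' generative model the analysis assumes: log-normal per-gene baseline
#' means, female X genes shifted by `x_dosage_log2`, Y genes exactly zero
#' in females, `Xist` female-biased and `Eif2s3y` male-only at the
#' configured marker magnitudes, a balanced set of planted autosomal
#' effects, and log-normal library-size multipliers per sample.
#'
#' Ground truth records `true_log2fc` male-over-female per gene; Y genes
#' carry `Inf` (hard zero in females) and `Xist` the configured marker
#' value.
#'
#' @param annotation A [gene_annotation()], typically from
#'   [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and
#'   `truth` (a `data.frame` with `gene_id`, `class`, `is_dimorphic`,
#'   `true_log2fc`).
#' @export
simulate_counts <- function(annotation, config) {
  validate_sim_config(config)
  stopifnot(inherits(annotation, "gene_annotation"))
  n_genes <- nrow(annotation)
  alpha <- rep_len(config$dispersion, n_genes)
  n_m <- config$n_male; n_f <- config$n_female
  with_seed(config$seed + 1L, {
    base <- exp(stats::rnorm(n_genes, config$baseline_log_mean_mu,
                             config$baseline_log_mean_sd))
    lfc <- numeric(n_genes)   # log2(male/female)
    is_x <- annotation$class == "X"
    is_y <- annotation$class == "Y"
    lfc[is_x] <- -config$x_dosage_log2
    auto_idx <- which(annotation$class == "autosome")
    n_dim <- round(config$dimorphic_fraction * length(auto_idx))
    planted <- if (n_dim > 0) sample(auto_idx, n_dim) else integer(0)
    if (n_dim > 0) {
      signs <- rep(c(1, -1), length.out = n_dim)
      lfc[planted] <- signs * config$effect_size_log2
    }
    i_xist <- match("Xist", annotation$gene_id)
    i_eif <- match("Eif2s3y", annotation$gene_id)
    if (!is.na(i_xist)) {
      base[i_xist] <- 550
      lfc[i_xist] <- config$xist_log2fc
    }
    if (!is.na(i_eif)) base[i_eif] <- 448

    # split the male/female shift symmetrically about the baseline
    mu_m <- base * 2^(lfc / 2)
    mu_f <- base * 2^(-lfc / 2)
    # markers: keep the baseline on the expressing sex, shift the other
    if (!is.na(i_xist)) {
      mu_f[i_xist] <- base[i_xist]
      mu_m[i_xist] <- base[i_xist] * 2^(config$xist_log2fc)
    }
    mu_f[is_y] <- 0
    mu_m[is_y] <- base[is_y]

    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    depth <- stats::rlnorm(n_m + n_f,
                           meanlog = log(config$library_size_mu) - sdlog^2 / 2,
                           sdlog = sdlog)
    sex <- c(rep("male", n_m), rep("female", n_f))
    sample_id <- c(sprintf("M%02d", seq_len(n_m)),
                   sprintf("F%02d", seq_len(n_f)))
    mu <- cbind(matrix(mu_m, n_genes, n_m), matrix(mu_f, n_genes, n_f))
    if (config$batch_effect_log2 != 0) {
      batch <- sample(c(0, 1), n_m + n_f, replace = TRUE)
      gshift <- stats::rnorm(n_genes, 0, 1) * config$batch_effect_log2
      mu <- mu * 2^(outer(gshift, batch))
    }
    mu <- sweep(mu, 2, depth, `*`)
    y <- matrix(stats::rnbinom(n_genes * (n_m + n_f), mu = mu,
                               size = rep(1 / alpha, n_m + n_f)),
                n_genes, n_m + n_f)
    y[is.na(y)] <- 0   # rnbinom(mu = 0) is 0, but guard anyway
    dimnames(y) <- list(annotation$gene_id, sample_id)
    meta <- data.frame(sample_id = sample_id, sex = sex,
                       stage = "simulated", stringsAsFactors = FALSE)
    truth_lfc <- lfc
    truth_lfc[is_y] <- Inf
    if (!is.na(i_eif)) truth_lfc[i_eif] <- Inf
    truth <- data.frame(gene_id = annotation$gene_id,
                        class = annotation$class,
                        is_dimorphic = truth_lfc != 0,
                        true_log2fc = truth_lfc,
                        stringsAsFactors = FALSE)
    list(counts = count_matrix(y, meta), truth = truth)
  })
}

#' Simulate per-sex TSS-window ChIP-seq counts
#'
#' Generates Poisson window read counts for a male and a female track
#' over the same annotation. Per-gene expected male counts are
#' `mean_reads` times a fixed log-normal gene factor; female X-gene
#' expectations are the male ones scaled by
#' `dosage_ratio_female_over_male` (default 2, pure dosage), and genes in
#' `enriched_set` are additionally scaled by `set_effect` in females.
#' Y genes are male-only.
#'
#' @param annotation A [gene_annotation()].
#' @param dosage_ratio_female_over_male Positive scale applied to female
#'   X genes (default 2.0).
#' @param enriched_set Character vector of X gene ids receiving the extra
#'   female `set_effect`; must be annotated X genes.
#' @param set_effect Positive multiplier for the enriched set (1 = none).
#' @param mean_reads Expected male window reads for an average gene.
#' @param halfwidth Window half-width recorded on the tracks (bp).
#' @param seed Random seed.
#' @return A list with `male` and `female` [tss_window_counts()] tracks.
#' @export
simulate_tss_coverage <- function(annotation,
                                  dosage_ratio_female_over_male = 2.0,
                                  enriched_set = character(0),
                                  set_effect = 1.0,
                                  mean_reads = 500,
                                  halfwidth = 1500,
                                  seed = 1L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (dosage_ratio_female_over_male <= 0) stop("dosage_ratio must be > 0")
  if (set_effect <= 0) stop("set_effect must be > 0")
  if (mean_reads < 0) stop("mean_reads must be >= 0")
  x_ids <- annotation$gene_id[annotation$class == "X"]
  unknown <- setdiff(enriched_set, x_ids)
  if (length(unknown)) {
    stop("enriched_set gene(s) not annotated X genes: ",
         paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    n <- nrow(annotation)
    gene_factor <- stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
    mu_m <- mean_reads * gene_factor
    scale_f <- rep(1, n)
    is_x <- annotation$class == "X"
    scale_f[is_x] <- dosage_ratio_female_over_male
    scale_f[annotation$gene_id %in% enriched_set] <-
      dosage_ratio_female_over_male * set_effect
    mu_f <- mu_m * scale_f
    mu_f[annotation$class == "Y"] <- 0
    vm <- stats::rpois(n, mu_m)
    vf <- stats::rpois(n, mu_f)
    names(vm) <- names(vf) <- annotation$gene_id
    list(
      male = tss_window_counts(vm, annotation, sex = "male",
                               halfwidth = halfwidth, kind = "total"),
      female = tss_window_counts(vf, annotation, sex = "female",
                                 halfwidth = halfwidth, kind = "total")
    )
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Writes counts and metadata as TSV, annotation as BED6, ground truth as
#' TSV and the configuration as YAML into `dir`.
#'
#' @param annotation A [gene_annotation()].
#' @param sim Result of [simulate_counts()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_simulation <- function(annotation, sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotation = file.path(dir, "annotation.bed"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  write_counts(sim$counts, paths["counts"], paths["metadata"])
  write_annotation(annotation, paths["annotation"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(config), paths["config"])
  invisible(paths)
}
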