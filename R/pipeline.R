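#' Validate a pipeline configuration
#'
#' A configuration is a YAML file or list with fields:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage.}
#'   \item{output_dir}{directory for the report bundle.}
#'   \item{thresholds}{list with `padj` and `lfc` (defaults 0.1, 0.5).}
#'   \item{discovery}{name of the dataset the signature is defined from.}
#'   \item{call_sex}{logical; re-call sample sex from markers (default
#'     TRUE when any metadata sex is `"unknown"`).}
#'   \item{datasets}{named list; each entry either
#'     `list(simulate = <sim_config fields>)` or
#'     `list(counts =, metadata =, annotation =)` file paths.}
#' }
#' All referenced paths must exist at validation time.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @return The validated config list (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$datasets) || !length(config$datasets) ||
      is.null(names(config$datasets))) {
    stop("config error: 'datasets' must be a named list")
  }
  if (is.null(config$discovery)) {
    stop("config error: 'discovery' dataset name is required")
  }
  if (!config$discovery %in% names(config$datasets)) {
    stop("config error: discovery dataset '", config$discovery,
         "' not among datasets")
  }
  if (is.null(config$output_dir)) stop("config error: 'output_dir' is required")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  thr <- config$thresholds
  config$thresholds <- list(
    padj = if (is.null(thr$padj)) 0.1 else thr$padj,
    lfc = if (is.null(thr$lfc)) 0.5 else thr$lfc
  )
  for (nm in names(config$datasets)) {
    ds <- config$datasets[[nm]]
    if (!is.null(ds$simulate)) next
    for (f in c("counts", "metadata", "annotation")) {
      if (is.null(ds[[f]])) {
        stop("config error: dataset '", nm, "' missing field '", f, "'")
      }
      if (!file.exists(ds[[f]])) {
        stop("config error: dataset '", nm, "' ", f, " file not found: ",
             ds[[f]])
      }
    }
  }
  config
}

load_pipeline_dataset <- function(name, ds, seed) {
  if (!is.null(ds$simulate)) {
    args <- ds$simulate
    if (is.null(args$seed)) args$seed <- seed
    cfg <- do.call(sim_config, args)
    ann <- simulate_annotation(cfg)
    sim <- simulate_counts(ann, cfg)
    list(counts = sim$counts, annotation = ann, truth = sim$truth)
  } else {
    list(counts = read_counts(ds$counts, ds$metadata),
         annotation = read_annotation(ds$annotation,
                                      format = if (grepl("\\.gtf$", ds$annotation))
                                        "gtf" else "bed"),
         truth = NULL)
  }
}

#' Run the end-to-end dimorphism analysis
#'
#' Orchestrates the analysis in the study's order: sex calling of the
#' discovery samples from marker genes, negative-binomial dimorphism
#' testing and signature definition on the discovery dataset, projection
#' of the signature onto every other dataset with directional-consistency
#' statistics, and a per-class summary. Deterministic given the
#' configured seed. Any stage error aborts with the stage name.
#'
#' Outputs written under `output_dir`: `dimorphism_<discovery>.tsv`,
#' `signature.tsv`, `sex_calls.tsv`, `projection_<name>.tsv`,
#' `summary.tsv` and a plain-text `run_log.txt` with ISO timestamps,
#' seeds and thresholds.
#'
#' @param config Path to a YAML file or a config list; see
#'   [validate_pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `sex_calls`,
#'   `table`, `signature`, `projections`, `consistency`, `summary`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...),
               log_con)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  logmsg("run_pipeline seed=", config$seed,
         " padj<", config$thresholds$padj,
         " |lfc|>", config$thresholds$lfc)

  datasets <- stage("load", {
    out <- list()
    for (nm in names(config$datasets)) {
      out[[nm]] <- load_pipeline_dataset(nm, config$datasets[[nm]],
                                         config$seed)
      logmsg("dataset ", nm, ": ", nrow(out[[nm]]$counts$counts), " genes x ",
             ncol(out[[nm]]$counts$counts), " samples")
    }
    out
  })

  disc <- datasets[[config$discovery]]
  do_call <- if (is.null(config$call_sex)) {
    any(disc$counts$metadata$sex == "unknown")
  } else isTRUE(config$call_sex)
  sex_calls <- NULL
  sex <- disc$counts$metadata$sex
  if (do_call) {
    sex_calls <- stage("sex_calling", call_sex(disc$counts))
    sex <- sex_calls$called_sex
    utils::write.table(sex_calls,
                       file.path(config$output_dir, "sex_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  table <- stage("dimorphism_test", test_dimorphism(disc$counts, sex = sex))
  utils::write.table(
    format_dimorphism_table(table, disc$annotation),
    file.path(config$output_dir,
              paste0("dimorphism_", config$discovery, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)

  signature <- stage("signature", define_signature(
    table, padj_threshold = config$thresholds$padj,
    lfc_threshold = config$thresholds$lfc, annotation = disc$annotation))
  utils::write.table(as.data.frame(signature),
                     file.path(config$output_dir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("signature: ", nrow(signature), " genes")

  projections <- list(); consistency <- list()
  for (nm in setdiff(names(datasets), config$discovery)) {
    proj <- stage(paste0("projection_", nm), {
      project_logfc(signature, datasets[[nm]]$counts, dataset = nm)
    })
    projections[[nm]] <- proj
    utils::write.table(as.data.frame(proj),
                       file.path(config$output_dir,
                                 paste0("projection_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    consistency[[nm]] <- stage(paste0("consistency_", nm), {
      directional_consistency(
        stats::setNames(proj$signature_log2fc, proj$gene_id),
        stats::setNames(proj$log2fc, proj$gene_id))
    })
  }

  summ <- stage("summary", {
    cs <- signature_class_summary(signature)
    rows <- data.frame(
      metric = c("signature_size", "signature_n_x", "signature_n_y",
                 "signature_n_autosome", "signature_sex_chromosome_fraction"),
      value = c(cs$n, cs$n_x, cs$n_y, cs$n_autosome,
                round(cs$sex_chromosome_fraction, 4)),
      stringsAsFactors = FALSE)
    for (nm in names(consistency)) {
      cc <- consistency[[nm]]
      rows <- rbind(rows, data.frame(
        metric = paste0(c("consistency_fraction_", "consistency_chisq_",
                          "consistency_p_"), nm),
        value = round(c(cc$fraction_consistent, cc$statistic, cc$p_value), 4)))
    }
    rows
  })
  utils::write.table(summ, file.path(config$output_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("done")
  invisible(list(sex_calls = sex_calls, table = table, signature = signature,
                 projections = projections, consistency = consistency,
                 summary = summ))
}

#' Format a dimorphism table with annotation columns
#'
#' Adds `chromosome`, `start`, `end`, `strand` columns (signature-table
#' style) when an annotation is supplied.
#'
#' @param table A `dimorphism_table`.
#' @param annotation Optional [gene_annotation()].
#' @return A plain `data.frame` ready for TSV export.
#' @export
format_dimorphism_table <- function(table, annotation = NULL) {
  out <- as.data.frame(table)
  if (!is.null(annotation)) {
    i <- match(out$gene_id, annotation$gene_id)
    out <- cbind(out[, "gene_id", drop = FALSE],
                 chromosome = annotation$chromosome[i],
                 start = annotation$start[i], end = annotation$end[i],
                 strand = annotation$strand[i],
                 out[, setdiff(colnames(out), "gene_id"), drop = FALSE])
  }
  out
}
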