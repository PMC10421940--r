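#' Pipeline run configuration
#'
#' Bundles every tunable threshold with the run seed and I/O paths. The
#' defaults are the clinical pipeline's operating constants: discordant
#' insert threshold 2000 bp, cluster distance 500 bp, five unique
#' supporting pairs, MSI-H above 15% unstable loci.
#'
#' @param seed integer seed driving all simulation stages
#' @param insert_threshold discordance insert cutoff, bp
#' @param cluster_distance clustering distance, bp
#' @param min_support minimum unique supporting read pairs
#' @param msi_threshold unstable-locus fraction above which a sample is
#'   MSI-H
#' @param tmb_panel_mb coding footprint of the panel in Mb (assay
#'   dependent)
#' @param msi_unstable_fraction planted unstable fraction for the
#'   simulated tumor
#' @param background_pairs concordant background pairs to simulate
#' @param reference_fasta optional path to a reference FASTA; NULL
#'   simulates the toy genome
#' @param gene_models_gff optional path to a gene-model GFF3; NULL uses
#'   the packaged toy models
#' @param out_dir run directory for stage outputs
#' @return a validated list of class `run_config`
#' @export
run_config <- function(seed = 1, insert_threshold = 2000,
                       cluster_distance = 500, min_support = 5,
                       msi_threshold = 0.15, tmb_panel_mb = 1.2,
                       msi_unstable_fraction = 0.2,
                       background_pairs = 500,
                       reference_fasta = NULL, gene_models_gff = NULL,
                       out_dir = tempfile("ntrkscan_run_")) {
  cfg <- list(seed = as.integer(seed),
              insert_threshold = insert_threshold,
              cluster_distance = cluster_distance,
              min_support = min_support, msi_threshold = msi_threshold,
              tmb_panel_mb = tmb_panel_mb,
              msi_unstable_fraction = msi_unstable_fraction,
              background_pairs = background_pairs,
              reference_fasta = reference_fasta,
              gene_models_gff = gene_models_gff, out_dir = out_dir)
  num <- c("insert_threshold", "cluster_distance", "min_support",
           "msi_threshold", "tmb_panel_mb")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config error: ", f, " must be positive")
    }
  }
  for (f in c("reference_fasta", "gene_models_gff")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config error: ", f, " path does not exist: ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as a flat key=value file
#'
#' @param config a [run_config()]
#' @param path file path
#' @return `path` invisibly (writer); a [run_config()] (reader)
#' @export
write_run_config <- function(config, path) {
  scalars <- Filter(function(x) !is.null(x), unclass(config))
  writeLines(sprintf("%s=%s", names(scalars),
                     vapply(scalars, as.character, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  }), vapply(kv, `[[`, character(1), 1))
  do.call(run_config, vals)
}

# default demonstration events: a recurrent interchromosomal fusion
# (ETV6 intron 5 to NTRK3 intron 14) with strong support, and an
# intrachromosomal one (LMNA intron 2 to NTRK1 intron 10) below the
# support filter
default_events <- function(models, support = c(8, 3)) {
  intron_pos <- function(m, k) {
    ex <- m$exons
    as.integer(ex$end[ex$ordinal == k] + 150L)
  }
  list(planted_fusion("chr12", intron_pos(models$ETV6, 5), "+",
                      "chr15", intron_pos(models$NTRK3, 14), "+",
                      n_support_pairs = support[1]),
       planted_fusion("chr1", intron_pos(models$LMNA, 2), "+",
                      "chr1", intron_pos(models$NTRK1, 10), "+",
                      n_support_pairs = support[2]))
}

#' Run the full pipeline: simulate, call, annotate, measure, report
#'
#' Executes every stage under one seed and writes stage outputs plus a
#' machine-readable summary into the run directory. Identical
#' configuration and seed give an identical summary.
#'
#' @param config a [run_config()]
#' @param events list of [planted_fusion()] events to simulate; the
#'   default plants one well-supported and one under-supported fusion
#' @return the summary list, invisibly; side effects in `config$out_dir`
#'   (`calls.tsv`, `annotations.tsv`, `metrics.tsv`, `cohort_report.tsv`,
#'   `summary.json`, `config.txt`)
#' @export
run_pipeline <- function(config = run_config(), events = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$out_dir, "config.txt"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ref <- stage("reference", {
    if (is.null(config$reference_fasta)) toy_model_reference(config$seed)
    else read_reference_fasta(config$reference_fasta)
  })
  models <- stage("gene_models", {
    if (is.null(config$gene_models_gff)) toy_gene_models()
    else read_gene_models(config$gene_models_gff)
  })
  events <- events %||% default_events(models)

  records <- stage("simulate", {
    recs <- lapply(seq_along(events), function(i) {
      r <- simulate_fusion_reads(ref, events[[i]],
                                 background_pairs = 0,
                                 seed = config$seed + i)
      r$read_id <- paste0("ev", i, "_", r$read_id)
      r
    })
    bg <- simulate_fusion_reads(ref, NULL,
                                background_pairs = config$background_pairs,
                                seed = config$seed)
    do.call(rbind, c(recs, list(bg)))
  })

  calls <- stage("svcall", {
    call_fusions(records, ref,
                 insert_threshold = config$insert_threshold,
                 cluster_distance = config$cluster_distance,
                 min_support = config$min_support)
  })
  utils::write.table(calls, file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  annotations <- stage("annotate", {
    if (nrow(calls) == 0) NULL
    else do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
      annotate_fusion(as.list(calls[i, ]), models)
    }))
  })
  if (!is.null(annotations)) {
    utils::write.table(annotations,
                       file.path(config$out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  metrics <- stage("metrics", {
    nvar <- with_seed(derive_seed(config$seed, "variants"),
                      stats::rpois(1, 5 * config$tmb_panel_mb))
    variants <- data.frame(class = rep("SNV", nvar),
                           coding = rep(TRUE, nvar))
    tmb <- compute_tmb(variants, config$tmb_panel_mb)
    panel <- msi_panel(seed = config$seed)
    prof <- simulate_msi_profiles(panel, config$msi_unstable_fraction,
                                  depth = 60, seed = config$seed)
    msi <- msi_sample_status(prof$tumor, prof$normal,
                             threshold = config$msi_threshold)
    list(tmb = tmb, msi = msi)
  })
  utils::write.table(
    data.frame(tmb = metrics$tmb, n_unstable = metrics$msi$n_unstable,
               n_evaluated = metrics$msi$n_evaluated,
               msi_status = metrics$msi$status),
    file.path(config$out_dir, "metrics.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  report <- stage("cohort_report", cohort_report())
  utils::write.table(report$prevalence_by_tumor_type,
                     file.path(config$out_dir, "cohort_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    n_records = nrow(records),
    n_calls = nrow(calls),
    calls = calls[, setdiff(names(calls), "contig")],
    classifications = if (is.null(annotations)) character(0)
                      else annotations$classification,
    fusions = if (is.null(annotations)) character(0)
              else annotations$fusion,
    tmb = metrics$tmb,
    msi_status = metrics$msi$status,
    headline = list(
      overall_prevalence_pct = report$prevalence_overall$percent,
      n_unique_partners = report$pattern$n_unique_partners,
      n_definite = report$pattern$n_definite,
      n_likely = report$pattern$n_likely,
      msi_fisher_p = report$msi_fisher_p))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
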