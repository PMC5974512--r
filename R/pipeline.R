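## End-to-end orchestration: simulate -> count -> qc -> score -> diff, with
## a manifest. Each stage is an ordinary exported function; run_pipeline
## wires them together from a single config and writes plain-text
## intermediates so stages can be re-run individually.

#' Run the full analysis pipeline
#'
#' Stages, driven by which inputs the config provides:
#' \enumerate{
#'   \item \strong{simulate} — if \code{config$simulate} is a
#'     \code{\link{simulation_config}} (or a list of its arguments), a
#'     synthetic pool is generated; with \code{config$emit_reads = TRUE}
#'     FASTQ files are written and re-counted with the matcher, otherwise
#'     the simulated count table is used directly.
#'   \item \strong{count} — else if \code{config$r1/r2/index} name FASTQ
#'     files, they are counted against \code{config$library}.
#'   \item \strong{load} — else \code{config$counts_file} /
#'     \code{config$samples_file} (long-format TSVs) are read.
#'   \item \strong{score / calls / diff} — \code{\link{score_pool}},
#'     \code{\link{gene_calls}}, \code{\link{call_differentials}} (when
#'     more than one condition) and \code{\link{cluster_conditions}}.
#' }
#' All outputs are TSV/Newick/JSON under \code{out_dir}; a manifest records
#' the thresholds, seed and per-stage record counts. Deterministic given
#' \code{seed}.
#'
#' @param config list or YAML file path; thresholds default to
#'   \code{cxy_min = 30}, \code{linkage_bp = 75000}, \code{replicate_r =
#'   0.5}, \code{q_cutoff = 0.01}, \code{effect_cutoff = 0.075},
#'   \code{delta_effect_cutoff = 0.1}.
#' @param out_dir output directory (created).
#' @param seed integer; overrides \code{config$seed}.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(cxy_min = 30, linkage_bp = 75000, replicate_r = 0.5,
                   q_cutoff = 0.01, effect_cutoff = 0.075,
                   delta_effect_cutoff = 0.1, emit_reads = FALSE,
                   error_rate = 0, seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  thr <- config[c("cxy_min", "linkage_bp", "replicate_r", "q_cutoff",
                  "effect_cutoff", "delta_effect_cutoff")]
  if (any(unlist(thr) <= 0)) stop("all thresholds must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    if (!inherits(simcfg, "sim_config")) {
      simcfg$seed <- config$seed
      simcfg <- do.call(simulation_config, simcfg)
    }
    sim <- simulate_pool(simcfg)
    truth <- sim$truth
    library <- sim$library
    write_barcode_library(library, file.path(out_dir, "barcode_library.tsv"))
    if (isTRUE(config$emit_reads)) {
      rd <- simulate_reads(sim$counts, library, file.path(out_dir, "reads"),
                           error_rate = config$error_rate)
      cnt <- count_fused_barcodes(rd$r1, rd$r2, rd$index, library,
                                  rd$sample_indices, sim$counts$samples)
      counts <- cnt$counts
      write_tsv(cnt$report, file.path(out_dir, "mapping_report.tsv"))
    } else {
      counts <- sim$counts
    }
    write_tsv(truth$gene_class_truth, file.path(out_dir, "truth_gene_pairs.tsv"))
    write_tsv(truth$strains, file.path(out_dir, "truth_strains.tsv"))
  } else if (!is.null(config$r1)) {
    library <- read_barcode_library(config$library)
    samples <- utils::read.table(config$samples_file, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
    sample_indices <- utils::read.table(config$sample_indices, sep = "\t",
                                        header = TRUE,
                                        stringsAsFactors = FALSE)
    cnt <- count_fused_barcodes(config$r1, config$r2, config$index, library,
                                sample_indices, samples)
    counts <- cnt$counts
    write_tsv(cnt$report, file.path(out_dir, "mapping_report.tsv"))
  } else if (!is.null(config$counts_file)) {
    library <- read_barcode_library(config$library)
    counts <- read_count_table(config$counts_file, config$samples_file)
  } else {
    stop("config must provide one of: simulate, r1/r2/index, counts_file")
  }
  write_count_table(counts, file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "samples.tsv"))

  scores <- score_pool(counts, library, cxy_min = config$cxy_min,
                       linkage_bp = config$linkage_bp,
                       replicate_r = config$replicate_r)
  write_tsv(scores$records, file.path(out_dir, "barcode_scores.tsv"))
  write_tsv(scores$qc, file.path(out_dir, "pair_qc.tsv"))
  write_tsv(scores$replicate_qc, file.path(out_dir, "replicate_qc.tsv"))

  genes <- gene_calls(scores, q_cutoff = config$q_cutoff,
                      effect_cutoff = config$effect_cutoff)
  write_tsv(genes, file.path(out_dir, "gene_scores.tsv"))

  diffs <- NULL
  clust <- NULL
  n_cond <- length(unique(genes$condition))
  if (n_cond >= 2) {
    diffs <- call_differentials(genes, q_cutoff = config$q_cutoff,
                                effect_cutoff = config$delta_effect_cutoff)
    write_tsv(diffs$records, file.path(out_dir, "differential_scores.tsv"))
    write_tsv(diffs$summary, file.path(out_dir, "differential_summary.tsv"))
    clust <- cluster_conditions(genes)
    writeLines(clust$newick, file.path(out_dir, "condition_dendrogram.nwk"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gipool")),
    seed = config$seed, thresholds = thr,
    n_pairs = nrow(counts$pairs), n_samples = ncol(counts$counts),
    n_retained_pairs = sum(scores$retained),
    n_excluded_replicates = length(scores$excluded_replicates),
    n_barcode_records = nrow(scores$records),
    n_gene_records = nrow(genes),
    n_significant_differentials =
      if (!is.null(diffs)) sum(diffs$records$significant) else 0L
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(counts = counts, library = library, truth = truth,
                 scores = scores, genes = genes, differentials = diffs,
                 clustering = clust, manifest = manifest))
}
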