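#' Fused-barcode count table
#'
#' The central container of the pipeline: one non-negative integer count per
#' (donor barcode, recipient barcode) strain pair and sequencing sample,
#' together with the sample sheet. Samples are either the heterozygous-diploid
#' reference pool (\code{stage = "hetdip"}, the "time zero" of the growth
#' model) or haploid double-mutant pools grown under a condition
#' (\code{stage = "haploid"}), usually as two technical replicates.
#'
#' @param counts integer matrix, pairs x samples. Row names are pair ids
#'   (\code{"<donor_bc>:<recipient_bc>"}), column names are sample ids.
#' @param pairs data.frame with columns \code{pair_id}, \code{donor_bc},
#'   \code{recipient_bc}, one row per row of \code{counts}.
#' @param samples data.frame with columns \code{sample_id}, \code{condition},
#'   \code{tech_replicate}, \code{stage} (\code{"hetdip"} or
#'   \code{"haploid"}) and \code{gen_pool} (generations of pool growth;
#'   ignored for the hetdip reference), one row per column of \code{counts}.
#' @return An object of class \code{"fused_counts"}.
#' @export
fused_counts <- function(counts, pairs, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  stopifnot(
    nrow(counts) == nrow(pairs),
    ncol(counts) == nrow(samples),
    all(counts >= 0),
    all(counts == round(counts)),
    all(c("pair_id", "donor_bc", "recipient_bc") %in% names(pairs)),
    all(c("sample_id", "condition", "stage", "gen_pool") %in% names(samples))
  )
  if (!any(samples$stage == "hetdip"))
    stop("no heterozygous-diploid reference sample (stage == 'hetdip') designated")
  if (!any(samples$stage == "haploid"))
    stop("no haploid pool samples present")
  bad_g <- samples$stage == "haploid" & (is.na(samples$gen_pool) | samples$gen_pool <= 0)
  if (any(bad_g))
    stop("missing or non-positive gen_pool for sample(s): ",
         paste(samples$sample_id[bad_g], collapse = ", "))
  rownames(counts) <- pairs$pair_id
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, pairs = as.data.frame(pairs),
                 samples = as.data.frame(samples)),
            class = "fused_counts")
}

#' @export
print.fused_counts <- function(x, ...) {
  cat("fused_counts:", nrow(x$counts), "strain pairs x", ncol(x$counts),
      "samples\n")
  cat("  conditions:",
      paste(unique(x$samples$condition[x$samples$stage == "haploid"]),
            collapse = ", "), "\n")
  cat("  total reads:", format(sum(x$counts), big.mark = ","), "\n")
  invisible(x)
}

#' @export
dim.fused_counts <- function(x) dim(x$counts)

pair_id <- function(donor_bc, recipient_bc) paste(donor_bc, recipient_bc, sep = ":")

#' Validate a barcode library table
#'
#' A barcode library maps each 20-nt strain barcode to its side of the cross
#' (donor or recipient), its strain and gene, the gene's functional class
#' (\code{"repair"} or \code{"neutral"}) and its chromosomal coordinate
#' (1-based). Sequences must be unique within each side; the mismatch-tolerant
#' matcher assumes a minimum pairwise Hamming distance of 5 for unambiguous
#' assignment, which \code{\link{generate_barcodes}} guarantees.
#'
#' @param library data.frame with columns \code{barcode_id}, \code{sequence},
#'   \code{side}, \code{strain_id}, \code{gene}, \code{gene_class},
#'   \code{chromosome}, \code{position_bp}.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_barcode_library <- function(library) {
  need <- c("barcode_id", "sequence", "side", "strain_id", "gene",
            "gene_class", "chromosome", "position_bp")
  miss <- setdiff(need, names(library))
  if (length(miss))
    stop("barcode library is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(library$side %in% c("donor", "recipient")))
    stop("side must be 'donor' or 'recipient'")
  if (!all(library$gene_class %in% c("repair", "neutral")))
    stop("gene_class must be 'repair' or 'neutral'")
  if (!all(nchar(library$sequence) == 20L) ||
      !all(grepl("^[ACGT]+$", library$sequence)))
    stop("barcode sequences must be 20 nt over {A,C,G,T}")
  for (sd in c("donor", "recipient")) {
    seqs <- library$sequence[library$side == sd]
    if (anyDuplicated(seqs))
      stop("duplicated barcode sequences on side '", sd, "'")
    ids <- library$barcode_id[library$side == sd]
    if (anyDuplicated(ids))
      stop("duplicated barcode ids on side '", sd, "'")
  }
  if (any(is.na(library$position_bp)) || any(library$position_bp < 1))
    stop("position_bp must be a positive 1-based coordinate")
  as.data.frame(library)
}

## ---- plain-text interchange (long-format TSV) ----

#' Write / read a fused-barcode count table as long-format TSV
#'
#' Columns: donor_barcode, recipient_barcode, sample_id, count; the sample
#' sheet travels in a companion TSV. Round-trips byte-identically.
#'
#' @param x a \code{\link{fused_counts}} object.
#' @param counts_file,samples_file output (or input) TSV paths.
#' @return \code{write_count_table} returns the paths invisibly;
#'   \code{read_count_table} returns a \code{fused_counts} object.
#' @export
write_count_table <- function(x, counts_file, samples_file) {
  stopifnot(inherits(x, "fused_counts"))
  long <- data.frame(
    donor_barcode = rep(x$pairs$donor_bc, ncol(x$counts)),
    recipient_barcode = rep(x$pairs$recipient_bc, ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  utils::write.table(long, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, samples_file))
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_file, samples_file) {
  long <- utils::read.table(counts_file, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "character", "integer"))
  samples <- utils::read.table(samples_file, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  pid <- pair_id(long$donor_barcode, long$recipient_barcode)
  upairs <- !duplicated(pid)
  pairs <- data.frame(pair_id = pid[upairs],
                      donor_bc = long$donor_barcode[upairs],
                      recipient_bc = long$recipient_barcode[upairs])
  mat <- matrix(0, nrow(pairs), nrow(samples),
                dimnames = list(pairs$pair_id, samples$sample_id))
  mat[cbind(match(pid, pairs$pair_id), match(long$sample_id, samples$sample_id))] <-
    long$count
  fused_counts(mat, pairs, samples)
}

#' @rdname validate_barcode_library
#' @param file TSV path.
#' @export
read_barcode_library <- function(file) {
  lib <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  lib$position_bp <- as.integer(lib$position_bp)
  validate_barcode_library(lib)
}

#' @rdname validate_barcode_library
#' @export
write_barcode_library <- function(library, file) {
  utils::write.table(validate_barcode_library(library), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
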