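## Pair classification and exclusion rules applied before scoring.
## Filter order is fixed: hetdip coverage -> linkage classification ->
## replicate profile correlation, each followed by one recomputation pass.
## All filters are masks; raw counts are never mutated.

#' Annotate strain pairs with gene, class, and linkage information
#'
#' Joins each (donor barcode, recipient barcode) pair to the library and
#' derives the flags that drive quality control and neutral-based
#' normalization: same-gene status, genetic linkage
#' (\code{\link{classify_linkage}}), whether the pair can serve in the
#' wild-type baseline (unlinked, distinct-gene, neutral-neutral), in the
#' neutral null (unlinked, distinct-gene, at least one neutral gene), and as
#' a neutral partner for each side's single-mutant fitness estimate.
#'
#' @param pairs data.frame with \code{pair_id}, \code{donor_bc},
#'   \code{recipient_bc}.
#' @param library barcode library.
#' @param linkage_bp linkage cutoff in bp.
#' @return annotated data.frame, one row per pair.
#' @export
annotate_pairs <- function(pairs, library, linkage_bp = 75000) {
  library <- validate_barcode_library(library)
  di <- match(pairs$donor_bc, library$barcode_id[library$side == "donor"])
  ri <- match(pairs$recipient_bc,
              library$barcode_id[library$side == "recipient"])
  if (anyNA(di) || anyNA(ri))
    stop("count table references barcodes absent from the library")
  don <- library[library$side == "donor", ][di, ]
  rec <- library[library$side == "recipient", ][ri, ]
  ann <- data.frame(
    pair_id = pairs$pair_id, donor_bc = pairs$donor_bc,
    recipient_bc = pairs$recipient_bc,
    donor_gene = don$gene, recipient_gene = rec$gene,
    donor_class = don$gene_class, recipient_class = rec$gene_class,
    donor_chrom = don$chromosome, donor_pos = don$position_bp,
    recipient_chrom = rec$chromosome, recipient_pos = rec$position_bp
  )
  ann$same_gene <- ann$donor_gene == ann$recipient_gene
  ann$linked <- classify_linkage(ann, linkage_bp)
  ann$null_neutral <- ann$donor_class == "neutral" &
    ann$recipient_class == "neutral" & !ann$linked & !ann$same_gene
  ann$neutral_pair <- (ann$donor_class == "neutral" |
                         ann$recipient_class == "neutral") &
    !ann$linked & !ann$same_gene
  ann$partner_for_donor <- ann$recipient_class == "neutral" &
    !ann$linked & !ann$same_gene
  ann$partner_for_recipient <- ann$donor_class == "neutral" &
    !ann$linked & !ann$same_gene
  ann
}

#' Flag pairs poorly measured in the heterozygous-diploid reference
#'
#' A pair's hetdip count \code{C_xy} (summed over hetdip samples) measures
#' how well its starting abundance is known; pairs with \code{C_xy} below
#' the threshold yield unreliable frequency ratios and are excluded from all
#' downstream denominators and neutral means, after which scores are
#' recomputed.
#'
#' @param counts a \code{\link{fused_counts}}.
#' @param threshold minimum hetdip count (default 30; \code{C_xy >= 30} is
#'   retained).
#' @return list with \code{C_xy} (per pair) and logical
#'   \code{well_measured}.
#' @export
filter_hetdip_coverage <- function(counts, threshold = 30) {
  stopifnot(inherits(counts, "fused_counts"))
  hd <- counts$samples$stage == "hetdip"
  cxy <- rowSums(counts$counts[, hd, drop = FALSE])
  list(C_xy = unname(cxy), well_measured = unname(cxy >= threshold),
       threshold = threshold)
}

#' Classify strain pairs as genetically linked or unlinked
#'
#' Two loci on the same chromosome closer than the cutoff segregate
#' together during meiosis, depleting their double-mutant recombinants
#' independently of any genetic interaction. Linked pairs are excluded from
#' the wild-type baseline, the single-mutant means and the neutral null,
#' but are still scored and reported with a linked flag. Same-gene pairs
#' are tracked separately, not as linked.
#'
#' @param ann pair annotation with \code{donor_chrom}, \code{donor_pos},
#'   \code{recipient_chrom}, \code{recipient_pos} (gene midpoint
#'   coordinates), \code{same_gene}.
#' @param cutoff_bp linkage distance cutoff (strict \code{<}).
#' @return logical vector, one per pair.
#' @export
classify_linkage <- function(ann, cutoff_bp = 75000) {
  bad <- is.na(ann$donor_pos) | is.na(ann$recipient_pos) |
    is.na(ann$donor_chrom) | is.na(ann$recipient_chrom)
  if (any(bad))
    stop("missing coordinates for gene(s): ",
         paste(unique(c(ann$donor_gene[bad], ann$recipient_gene[bad])),
               collapse = ", "))
  same_gene <- if (!is.null(ann$same_gene)) ann$same_gene
               else ann$donor_gene == ann$recipient_gene
  ann$donor_chrom == ann$recipient_chrom &
    abs(ann$donor_pos - ann$recipient_pos) < cutoff_bp & !same_gene
}

#' Exclude barcode replicates with decorrelated interaction profiles
#'
#' Barcode replicates of the same gene should show near-identical genetic
#' interaction profiles; a replicate whose profile decorrelates from its
#' siblings (empirically, aneuploid strains) is an artifact. For each
#' replicate, its GIS profile — the vector over (partner gene x condition)
#' of mean GIS — is correlated (Pearson) against the element-wise mean
#' profile of the other replicates of the same gene on the same side.
#' Replicates with \code{r < r_cutoff} are excluded and scoring is
#' recomputed on the survivors, with two guards: a gene with exactly two
#' disagreeing replicates has both flagged for review but neither
#' auto-excluded (the correlation cannot say which is wrong), and if
#' exclusion would empty a gene's replicate set the replicate with the
#' highest hetdip coverage is retained with a warning. A replicate with no
#' sibling has undefined correlation and is retained.
#'
#' @param records barcode-level records from a first scoring pass (columns
#'   \code{donor_bc}, \code{recipient_bc}, \code{donor_gene},
#'   \code{recipient_gene}, \code{condition}, \code{gis}).
#' @param r_cutoff minimum Pearson correlation (default 0.5).
#' @param cxy optional per-pair hetdip counts (aligned with \code{ann}),
#'   used only for the empty-gene guard.
#' @param ann optional pair annotation (for the coverage guard).
#' @return list with \code{excluded} (barcode ids), \code{flagged}
#'   (two-replicate disagreements) and \code{table} (per-replicate r).
#' @export
filter_replicates_by_profile <- function(records, r_cutoff = 0.5,
                                         cxy = NULL, ann = NULL) {
  all_bcs <- list(donor = unique(records$donor_bc),
                  recipient = unique(records$recipient_bc))
  per_side <- function(side) {
    bc_col <- if (side == "donor") "donor_bc" else "recipient_bc"
    gene_col <- if (side == "donor") "donor_gene" else "recipient_gene"
    pgene_col <- if (side == "donor") "recipient_gene" else "donor_gene"
    bcs <- intersect(all_bcs[[side]], records[[bc_col]])
    ## profile matrix: replicate x (partner gene x condition)
    key <- paste(records[[pgene_col]], records$condition, sep = "|")
    ukey <- sort(unique(key))
    prof <- matrix(NA_real_, length(bcs), length(ukey),
                   dimnames = list(bcs, ukey))
    agg <- tapply(records$gis,
                  list(factor(records[[bc_col]], bcs), factor(key, ukey)),
                  mean)
    prof[] <- agg
    gene_of <- records[[gene_col]][match(bcs, records[[bc_col]])]

    out <- data.frame(barcode_id = bcs, side = side, gene = gene_of,
                      r = NA_real_, n_siblings = NA_integer_)
    for (i in seq_along(bcs)) {
      sibs <- which(gene_of == gene_of[i])
      sibs <- setdiff(sibs, i)
      out$n_siblings[i] <- length(sibs)
      if (length(sibs) == 0) next
      ref <- colMeans(prof[sibs, , drop = FALSE], na.rm = TRUE)
      both <- is.finite(prof[i, ]) & is.finite(ref)
      if (sum(both) >= 3 && stats::sd(prof[i, both]) > 0 &&
          stats::sd(ref[both]) > 0)
        out$r[i] <- stats::cor(prof[i, both], ref[both])
    }
    out
  }
  tab <- rbind(per_side("donor"), per_side("recipient"))

  excluded <- character(0)
  flagged <- character(0)
  for (g in unique(paste(tab$side, tab$gene))) {
    rows <- tab[paste(tab$side, tab$gene) == g, ]
    low <- !is.na(rows$r) & rows$r < r_cutoff
    if (!any(low)) next
    if (nrow(rows) == 2 && all(low)) {
      ## two disagreeing replicates: the correlation is symmetric and
      ## cannot identify the culprit; flag both, exclude neither
      flagged <- c(flagged, rows$barcode_id)
    } else if (all(low)) {
      keep <- pick_best_covered(rows$barcode_id, cxy, ann)
      warning("all replicates of ", g, " fall below r = ", r_cutoff,
              "; retaining ", keep, " (highest hetdip coverage)")
      excluded <- c(excluded, setdiff(rows$barcode_id[low], keep))
    } else {
      excluded <- c(excluded, rows$barcode_id[low])
    }
  }
  list(excluded = excluded, flagged = flagged, table = tab)
}

pick_best_covered <- function(bcs, cxy, ann) {
  if (is.null(cxy) || is.null(ann)) return(bcs[1])
  cov <- vapply(bcs, function(b) {
    sel <- ann$donor_bc == b | ann$recipient_bc == b
    sum(cxy[sel])
  }, numeric(1))
  bcs[which.max(cov)]
}
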