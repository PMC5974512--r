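#' Match a barcode read against one side of the library
#'
#' Scans every offset at which a 20-nt barcode fits inside the read and
#' returns the library barcode with the smallest Hamming distance. A match is
#' accepted only if the best distance is <= \code{max_mismatch} (3 of 20,
#' i.e. >= 85\% identity); if two distinct barcodes tie at the best accepted
#' distance the read is ambiguous. Matching is orientation-fixed: amplicon
#' reads are primer-anchored, so no reverse-complement scan is performed, and
#' no indels are modeled.
#'
#' @param reads character vector of reads (>= 20 nt each).
#' @param library barcode library data.frame (see
#'   \code{\link{validate_barcode_library}}).
#' @param side \code{"donor"} or \code{"recipient"}.
#' @param max_mismatch mismatch budget over the 20-nt barcode.
#' @return character vector: the matched \code{barcode_id}, or \code{NA} with
#'   attribute-free sentinel values \code{"unmatched"} / \code{"ambiguous"}
#'   reported via \code{\link{match_barcode_detail}}. For convenience this
#'   wrapper returns \code{barcode_id} or \code{NA_character_}.
#' @export
match_barcode <- function(reads, library, side = c("donor", "recipient"),
                          max_mismatch = 3L) {
  det <- match_barcode_detail(reads, library, side, max_mismatch)
  ifelse(det$status == "matched", det$barcode_id, NA_character_)
}

#' @rdname match_barcode
#' @return \code{match_barcode_detail} returns a data.frame with columns
#'   \code{barcode_id}, \code{distance} and \code{status} in
#'   \code{c("matched", "unmatched", "ambiguous")}.
#' @export
match_barcode_detail <- function(reads, library,
                                 side = c("donor", "recipient"),
                                 max_mismatch = 3L) {
  side <- match.arg(side)
  library <- validate_barcode_library(library)
  bc <- library[library$side == side, ]
  if (nrow(bc) == 0) stop("library has no ", side, " barcodes")
  n <- length(reads)
  out <- data.frame(barcode_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    status = rep("unmatched", n))
  if (n == 0) return(out)
  width <- 20L
  lens <- nchar(reads)
  ok <- !is.na(reads) & lens >= width
  if (!any(ok)) return(out)

  ## collapse to unique reads: amplicon data is highly redundant
  ureads <- unique(reads[ok])
  ulen <- nchar(ureads)
  bmat <- matrix(utf8ToInt(paste(bc$sequence, collapse = "")),
                 ncol = width, byrow = TRUE)

  best_d <- rep(Inf, length(ureads))
  best_i <- rep(NA_integer_, length(ureads))
  tied <- rep(FALSE, length(ureads))
  for (L in unique(ulen)) {
    sel <- which(ulen == L)
    rmat <- matrix(utf8ToInt(paste(ureads[sel], collapse = "")),
                   ncol = L, byrow = TRUE)
    for (off in 0:(L - width)) {
      slice <- rmat[, (off + 1):(off + width), drop = FALSE]
      for (b in seq_len(nrow(bmat))) {
        d <- rowSums(slice != matrix(bmat[b, ], nrow(slice), width,
                                     byrow = TRUE))
        lt <- d < best_d[sel]
        eq <- d == best_d[sel] & is.finite(d) & best_i[sel] != b
        tied[sel][eq & !is.na(eq)] <- TRUE
        if (any(lt)) {
          idx <- sel[lt]
          best_d[idx] <- d[lt]
          best_i[idx] <- b
          tied[idx] <- FALSE
        }
      }
    }
  }
  status <- ifelse(!is.finite(best_d) | best_d > max_mismatch, "unmatched",
                   ifelse(tied, "ambiguous", "matched"))
  m <- match(reads[ok], ureads)
  out$status[ok] <- status[m]
  out$distance[ok] <- ifelse(is.finite(best_d), as.integer(best_d),
                             NA_integer_)[m]
  out$barcode_id[ok] <- ifelse(status == "matched", bc$barcode_id[best_i],
                               NA_character_)[m]
  out
}

read_fastq_seqs <- function(path) {
  if (file.size(path) == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count fused barcode pairs from paired FASTQ
#'
#' Demultiplexes reads by exact 6-nt sample index, assigns R1 to a donor
#' barcode and R2 to a recipient barcode with the <= 3-mismatch Hamming
#' matcher, and tallies one count per read pair for which all three
#' assignments succeed uniquely. Every read pair is accounted for: table
#' counts plus the report's rejection tallies sum to the number of input
#' read pairs.
#'
#' @param r1,r2,index FASTQ paths (gzip accepted) of equal record counts.
#' @param library barcode library.
#' @param sample_indices data.frame with columns \code{sample_id},
#'   \code{index} mapping each sample to its 6-nt index sequence.
#' @param samples sample sheet (see \code{\link{fused_counts}}); rows must
#'   match \code{sample_indices$sample_id}.
#' @param max_mismatch mismatch budget for barcode matching.
#' @return list with \code{counts} (a \code{\link{fused_counts}} over every
#'   observed pair) and \code{report} (per-sample totals plus global
#'   rejection tallies).
#' @export
count_fused_barcodes <- function(r1, r2, index, library, sample_indices,
                                 samples, max_mismatch = 3L) {
  library <- validate_barcode_library(library)
  s1 <- read_fastq_seqs(r1)
  s2 <- read_fastq_seqs(r2)
  si <- read_fastq_seqs(index)
  if (length(s1) != length(s2) || length(s1) != length(si))
    stop("R1/R2/index record counts differ (", length(s1), "/", length(s2),
         "/", length(si), ")")
  n <- length(s1)
  samp <- sample_indices$sample_id[match(si, sample_indices$index)]
  d <- match_barcode_detail(s1, library, "donor", max_mismatch)
  r <- match_barcode_detail(s2, library, "recipient", max_mismatch)

  ok <- !is.na(samp) & d$status == "matched" & r$status == "matched"
  report <- data.frame(
    total_read_pairs = n,
    matched = sum(ok),
    unmatched_index = sum(is.na(samp)),
    unmatched_donor = sum(!is.na(samp) & d$status == "unmatched"),
    ambiguous_donor = sum(!is.na(samp) & d$status == "ambiguous"),
    unmatched_recipient = sum(!is.na(samp) & d$status == "matched" &
                                r$status == "unmatched"),
    ambiguous_recipient = sum(!is.na(samp) & d$status == "matched" &
                                r$status == "ambiguous"),
    matched_fraction = if (n > 0) sum(ok) / n else NA_real_
  )

  ## full donor x recipient grid so zero cells are represented
  don <- library$barcode_id[library$side == "donor"]
  rec <- library$barcode_id[library$side == "recipient"]
  pairs <- data.frame(
    pair_id = pair_id(rep(don, times = length(rec)),
                      rep(rec, each = length(don))),
    donor_bc = rep(don, times = length(rec)),
    recipient_bc = rep(rec, each = length(don)))
  mat <- matrix(0L, nrow(pairs), nrow(samples),
                dimnames = list(pairs$pair_id, samples$sample_id))
  if (any(ok)) {
    pid <- pair_id(d$barcode_id[ok], r$barcode_id[ok])
    tab <- table(pid, samp[ok])
    mat[rownames(tab), colnames(tab)] <-
      mat[rownames(tab), colnames(tab)] + as.integer(tab)
  }
  per_sample <- data.frame(sample_id = samples$sample_id,
                           reads = colSums(mat))
  list(counts = fused_counts(mat, pairs, samples),
       report = report, per_sample = per_sample)
}
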