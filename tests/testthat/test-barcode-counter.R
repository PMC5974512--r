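lib <- toy_library(c("A", "B", "C"), c("repair", "repair", "neutral"))

mutate_at <- function(seq, pos, to = NULL) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), s[p])
    s[p] <- if (is.null(to)) alt[1] else to
  }
  paste(s, collapse = "")
}

test_that("exact reads match at distance 0; mismatch budget is 3 of 20", {
  bc <- lib[lib$side == "donor", ][1, ]
  read0 <- paste0(bc$sequence, "ACGTA")
  det <- match_barcode_detail(read0, lib, "donor")
  expect_equal(det$status, "matched")
  expect_equal(det$barcode_id, bc$barcode_id)
  expect_equal(det$distance, 0L)

  for (k in 1:3) {
    rk <- paste0(mutate_at(bc$sequence, seq_len(k)), "ACGTA")
    det <- match_barcode_detail(rk, lib, "donor")
    expect_equal(det$status, "matched")
    expect_equal(det$distance, k)
  }
  ## 4 substitutions: below 85% identity, rejected
  r4 <- paste0(mutate_at(bc$sequence, 1:4), "ACGTA")
  expect_equal(match_barcode_detail(r4, lib, "donor")$status, "unmatched")
  expect_true(is.na(match_barcode(r4, lib, "donor")))
})

test_that("matching scans offsets within the read", {
  bc <- lib[lib$side == "recipient", ][2, ]
  shifted <- paste0("GT", bc$sequence, "AAA")  # barcode at offset 2
  det <- match_barcode_detail(shifted, lib, "recipient")
  expect_equal(det$status, "matched")
  expect_equal(det$barcode_id, bc$barcode_id)
  expect_equal(det$distance, 0L)
})

test_that("equidistant barcodes give an ambiguous call", {
  ## two barcodes at Hamming distance 4; a read at distance 2 from each ties
  b1 <- paste0("AAAA", strrep("ACGT", 4))
  b2 <- paste0("CCCC", strrep("ACGT", 4))
  mid <- paste0("AACC", strrep("ACGT", 4))
  tielib <- data.frame(
    barcode_id = c("d1", "d2"), sequence = c(b1, b2), side = "donor",
    strain_id = c("s1", "s2"), gene = c("A", "B"),
    gene_class = c("repair", "neutral"),
    chromosome = c("chr1", "chr2"), position_bp = 1L)
  det <- match_barcode_detail(paste0(mid, "ACGTA"), tielib, "donor")
  expect_equal(det$status, "ambiguous")
  expect_equal(det$distance, 2L)
})

test_that("reads shorter than a barcode are unmatched", {
  expect_equal(match_barcode_detail("ACGTACGTACGT", lib, "donor")$status,
               "unmatched")
})

test_that("error-free reads round-trip to the exact simulated count table", {
  sim <- small_sim(seed = 31, reads = 4e3, conditions = "c1")
  dir <- withr::local_tempdir()
  rd <- simulate_reads(sim$counts, sim$library, dir, error_rate = 0)
  res <- count_fused_barcodes(rd$r1, rd$r2, rd$index, sim$library,
                              rd$sample_indices, sim$counts$samples)
  expect_equal(res$report$matched_fraction, 1.0)
  m <- res$counts$counts[rownames(sim$counts$counts),
                         colnames(sim$counts$counts)]
  expect_identical(unname(m), unname(sim$counts$counts))
})

test_that("read pairs are conserved across table and rejection tallies", {
  sim <- small_sim(seed = 32, reads = 2e3, conditions = "c1")
  dir <- withr::local_tempdir()
  rd <- simulate_reads(sim$counts, sim$library, dir, error_rate = 0.02)
  res <- count_fused_barcodes(rd$r1, rd$r2, rd$index, sim$library,
                              rd$sample_indices, sim$counts$samples)
  r <- res$report
  expect_equal(sum(res$counts$counts), r$matched)
  expect_equal(r$matched + r$unmatched_index + r$unmatched_donor +
                 r$ambiguous_donor + r$unmatched_recipient +
                 r$ambiguous_recipient,
               r$total_read_pairs)
})

test_that("an unknown index lands only in the unmatched-index tally", {
  dir <- withr::local_tempdir()
  bcs <- lib$sequence
  write_one <- function(path, seqs) {
    writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                               strrep("I", nchar(seqs)))), path)
  }
  r1 <- file.path(dir, "r1.fastq"); r2 <- file.path(dir, "r2.fastq")
  ix <- file.path(dir, "i1.fastq")
  write_one(r1, paste0(lib$sequence[lib$side == "donor"][1], "ACGTA"))
  write_one(r2, paste0(lib$sequence[lib$side == "recipient"][1], "ACGTA"))
  write_one(ix, "NNNNNN")
  samples <- data.frame(sample_id = c("HetDip", "S1", "S2"),
                        condition = c("HetDip", "c1", "c1"),
                        tech_replicate = c(1L, 1L, 2L),
                        stage = c("hetdip", "haploid", "haploid"),
                        gen_pool = c(NA, 5, 5))
  res <- count_fused_barcodes(r1, r2, ix, lib,
                              data.frame(sample_id = samples$sample_id,
                                         index = c("AAAAAA", "CCCCCC",
                                                   "GGGGGG")),
                              samples)
  expect_equal(res$report$unmatched_index, 1)
  expect_equal(res$report$matched, 0)
  expect_equal(sum(res$counts$counts), 0)
})

test_that("mismatched record counts raise an error", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fastq"); f2 <- file.path(dir, "b.fastq")
  fi <- file.path(dir, "i.fastq")
  writeLines(c("@r1", strrep("A", 25), "+", strrep("I", 25),
               "@r2", strrep("A", 25), "+", strrep("I", 25)), f1)
  writeLines(c("@r1", strrep("A", 25), "+", strrep("I", 25)), f2)
  writeLines(c("@r1", "AAAAAA", "+", "IIIIII"), fi)
  samples <- data.frame(sample_id = c("HetDip", "S1", "S2"),
                        condition = c("HetDip", "c1", "c1"),
                        tech_replicate = c(1L, 1L, 2L),
                        stage = c("hetdip", "haploid", "haploid"),
                        gen_pool = c(NA, 5, 5))
  expect_error(
    count_fused_barcodes(f1, f2, fi, lib,
                         data.frame(sample_id = samples$sample_id,
                                    index = c("AAAAAA", "CCCCCC", "GGGGGG")),
                         samples),
    "record counts differ")
})
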