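test_that("config validation rejects inconsistent inputs", {
  expect_error(simulation_config(reads_per_sample = 0), "reads_per_sample")
  expect_error(
    simulation_config(true_epsilon = data.frame(
      gene_i = "NOPE", gene_j = "REP01", condition = "NoDrug", epsilon = -1)),
    "unknown gene")
  expect_error(
    simulation_config(true_epsilon = data.frame(
      gene_i = "REP01", gene_j = "REP02", condition = "Mars", epsilon = -1)),
    "unknown condition")
  expect_error(simulation_config(true_single_fitness = c(REP01 = 2)),
               "\\[0, 1.5\\]")
})

test_that("read conservation: every sample carries exactly reads_per_sample", {
  sim <- small_sim(seed = 3, reads = 5e4)
  expect_true(all(colSums(sim$counts$counts) == 5e4))
})

test_that("simulation is seed-deterministic", {
  s1 <- small_sim(seed = 11, reads = 2e4)
  s2 <- small_sim(seed = 11, reads = 2e4)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$library, s2$library)
  s3 <- small_sim(seed = 12, reads = 2e4)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("same-gene pairs are depleted ~2^-gen_pool relative to hetdip", {
  ## w_xy = 0 forces g.t = 0, so the final-pool share of a same-gene pair
  ## shrinks by 2^(0 - gen_pool) relative to its hetdip share
  cfg <- simulation_config(n_repair_genes = 4, n_neutral_genes = 4,
                           replicates_per_gene = 1, conditions = "c1",
                           gen_pool = 5, reads_per_sample = 2e6, seed = 5)
  sim <- simulate_pool(cfg)
  cc <- sim$counts$counts
  f_hd <- cc[, "HetDip"] / sum(cc[, "HetDip"])
  f_c <- (cc[, "c1_R1"] + cc[, "c1_R2"]) / sum(cc[, c("c1_R1", "c1_R2")])
  sg <- sim$truth$pair_fitness$same_gene
  ## every non-same-gene pair here has w = 1, so its share grows by
  ## 2^gen_pool relative to a same-gene pair; ratio of relative shares = 32
  rel <- (f_hd / f_c)[sg] / median((f_hd / f_c)[!sg])
  expect_equal(median(rel), 2^5, tolerance = 0.15)
})

test_that("null config gives symmetric expected shares", {
  cfg <- simulation_config(n_repair_genes = 5, n_neutral_genes = 5,
                           replicates_per_gene = 1, conditions = "c1",
                           reads_per_sample = 1e6, samegene_included = FALSE,
                           hetdip_dispersion = 1e6, seed = 8)
  sim <- simulate_pool(cfg)
  cc <- sim$counts$counts
  ## all fitness 1, epsilon 0, near-equal starting abundance: all pairs
  ## should have equal expected share in every sample
  expected <- 1e6 / nrow(cc)
  expect_lt(max(abs(cc - expected)) / expected, 0.1)
})

test_that("raising true fitness raises the expected final share", {
  eps <- data.frame(gene_i = c("REP01", "REP01"), gene_j = c("REP02", "REP03"),
                    condition = "c1", epsilon = c(-0.3, 0.3))
  cfg <- simulation_config(n_repair_genes = 4, n_neutral_genes = 3,
                           replicates_per_gene = 1, conditions = "c1",
                           true_epsilon = eps, reads_per_sample = 1e6,
                           gen_pool = 8, seed = 9)
  sim <- simulate_pool(cfg)
  pf <- sim$truth$pair_fitness
  cc <- sim$counts$counts
  lo <- pf$donor_gene == "REP01" & pf$recipient_gene == "REP02"
  hi <- pf$donor_gene == "REP01" & pf$recipient_gene == "REP03"
  expect_true(all(cc[hi, c("c1_R1", "c1_R2")] > cc[lo, c("c1_R1", "c1_R2")]))
})

test_that("simulate_reads reproduces counts exactly and respects error_rate", {
  sim <- small_sim(seed = 21, reads = 3e3)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(sim$counts, sim$library, dir, error_rate = 0)
  r1 <- readLines(rd$r1)
  expect_length(r1, 4 * sum(sim$counts$counts))
  ## error_rate = 0 reproduces barcodes verbatim: all reads match at 0
  seqs <- r1[seq(2, length(r1), by = 4)]
  det <- match_barcode_detail(unique(seqs), sim$library, "donor")
  expect_true(all(det$status == "matched" & det$distance == 0))
  expect_error(simulate_reads(sim$counts, sim$library, dir, error_rate = 0.3),
               "error_rate")
})

test_that("one pair with count 7 yields exactly 7 read triplets", {
  lib <- toy_library(c("A", "B"), c("repair", "neutral"))
  mat <- matrix(0L, 4, 2)
  mat[2, 2] <- 7L
  cnt <- toy_counts(mat, lib)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(cnt, lib, dir, error_rate = 0)
  seqs <- readLines(rd$r1)[seq(2, 4 * 7, by = 4)]
  don <- cnt$pairs$donor_bc[2]
  expect_length(seqs, 7)
  expect_true(all(substr(seqs, 1, 20) ==
                    lib$sequence[lib$barcode_id == don]))
  idx <- readLines(rd$index)[seq(2, 4 * 7, by = 4)]
  expect_true(all(idx == rd$sample_indices$index[2]))
})

test_that("empty count table gives valid empty FASTQ files", {
  lib <- toy_library(c("A", "B"), c("repair", "neutral"))
  cnt <- toy_counts(matrix(0L, 4, 2), lib)
  dir <- withr::local_tempdir()
  rd <- simulate_reads(cnt, lib, dir)
  expect_true(file.exists(rd$r1) && file.size(rd$r1) == 0)
  expect_true(file.exists(rd$r2) && file.size(rd$r2) == 0)
})

test_that("generated barcodes respect the minimum Hamming distance", {
  set.seed(1)
  bcs <- generate_barcodes(40)
  m <- matrix(utf8ToInt(paste(bcs, collapse = "")), ncol = 20, byrow = TRUE)
  dmin <- min(sapply(seq_len(39), function(i)
    min(rowSums(m[(i + 1):40, , drop = FALSE] !=
                  matrix(m[i, ], 40 - i, 20, byrow = TRUE)))))
  expect_gte(dmin, 5)
})
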