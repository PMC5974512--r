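# Shared fixture builders. Everything is generated in code; no stored data.

# small two-condition pool with one planted negative interaction
small_sim <- function(seed = 42, reads = 2e5, epsilon = -0.4,
                      conditions = c("NoDrug", "MMS")) {
  cfg <- simulation_config(
    n_repair_genes = 8, n_neutral_genes = 6, replicates_per_gene = 2,
    conditions = conditions,
    true_epsilon = data.frame(gene_i = "REP01", gene_j = "REP02",
                              condition = conditions[length(conditions)],
                              epsilon = epsilon),
    reads_per_sample = reads, seed = seed)
  simulate_pool(cfg)
}

# hand-sized library: n donor + n recipient barcodes, all genes unlinked
toy_library <- function(genes, classes, reps = 1, seed = 7) {
  set.seed(seed)
  n <- length(genes) * reps
  seqs <- generate_barcodes(2 * n)
  mk <- function(side, offset) {
    data.frame(
      barcode_id = sprintf("%s_%s_b%d", substr(side, 1, 1),
                           rep(genes, each = reps),
                           rep(seq_len(reps), length(genes))),
      sequence = seqs[offset + seq_len(n)],
      side = side,
      strain_id = sprintf("%s_%s", side, rep(genes, each = reps)),
      gene = rep(genes, each = reps),
      gene_class = rep(classes, each = reps),
      chromosome = paste0("chr", rep(seq_along(genes), each = reps)),
      position_bp = 100000L
    )
  }
  rbind(mk("donor", 0), mk("recipient", n))
}

# fused_counts from a dense pair x sample count matrix given a library
toy_counts <- function(mat, library, gen_pool = 5) {
  don <- library$barcode_id[library$side == "donor"]
  rec <- library$barcode_id[library$side == "recipient"]
  pairs <- data.frame(
    pair_id = paste(rep(don, times = length(rec)),
                    rep(rec, each = length(don)), sep = ":"),
    donor_bc = rep(don, times = length(rec)),
    recipient_bc = rep(rec, each = length(don)))
  stopifnot(nrow(mat) == nrow(pairs))
  ns <- ncol(mat)
  samples <- data.frame(
    sample_id = c("HetDip", paste0("C_R", seq_len(ns - 1))),
    condition = c("HetDip", rep("cond1", ns - 1)),
    tech_replicate = c(1L, seq_len(ns - 1)),
    stage = c("hetdip", rep("haploid", ns - 1)),
    gen_pool = c(NA_real_, rep(gen_pool, ns - 1)))
  fused_counts(mat, pairs, samples)
}
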