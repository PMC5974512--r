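#' Configuration for a synthetic pooled double-mutant screen
#'
#' Defines the ground truth and sampling conditions of a simulated
#' many-by-many haploid double-mutant pool. Each gene is represented by
#' \code{replicates_per_gene} independently barcoded strains on each side of
#' the cross (donor and recipient). Strain pairs grow exponentially from a
#' heterozygous-diploid "time zero" reference; the true double-mutant fitness
#' is \code{w_xy = w_x * w_y + epsilon} (clipped at 0), same-gene pairs are
#' synthetic lethals (\code{w_xy = 0}), and genetically linked pairs are
#' depleted among haploid recombinants by reduced meiotic segregation.
#'
#' @param n_repair_genes,n_neutral_genes number of DNA-repair and neutral
#'   genes (per side; the same gene set is barcoded on both sides).
#' @param replicates_per_gene barcode replicates per gene per side.
#' @param conditions character vector of condition names; each gets
#'   \code{tech_replicates} technical-replicate samples.
#' @param true_single_fitness named numeric vector, gene -> fitness in
#'   [0, 1.5]; genes absent from it default to 1 (no single-mutant defect).
#' @param true_epsilon data.frame with columns \code{gene_i}, \code{gene_j},
#'   \code{condition}, \code{epsilon}: planted interactions, added to
#'   \code{w_i * w_j}. Pairs absent default to epsilon = 0.
#' @param gen_pool generations of pool growth for haploid samples. Either a
#'   single number or a named vector per condition.
#' @param reads_per_sample sequencing depth per sample (multinomial total).
#' @param tech_replicates technical replicates per condition.
#' @param linked_fraction approximate fraction of gene pairs placed < 75 kbp
#'   apart on a shared chromosome (0 disables linkage).
#' @param linked_depletion multiplicative depletion of linked pairs in
#'   post-sporulation (haploid) pools relative to the hetdip reference.
#' @param samegene_included include same-gene (synthetic-lethal control)
#'   pairs in the pool.
#' @param aneuploid_replicate_rate probability that a barcode replicate is an
#'   aneuploid-like artifact whose whole fitness profile is redrawn
#'   independently of its gene.
#' @param hetdip_dispersion gamma shape of starting strain abundances around
#'   a common mean (>= 1; larger = more even pool; coefficient of variation
#'   is \code{1/sqrt(hetdip_dispersion)}).
#' @param seed integer seed; all randomness in \code{\link{simulate_pool}}
#'   derives from it.
#' @return A \code{"sim_config"} list.
#' @export
simulation_config <- function(n_repair_genes = 10,
                              n_neutral_genes = 6,
                              replicates_per_gene = 2,
                              conditions = c("NoDrug", "MMS"),
                              true_single_fitness = NULL,
                              true_epsilon = NULL,
                              gen_pool = 10,
                              reads_per_sample = 1e6,
                              tech_replicates = 2,
                              linked_fraction = 0,
                              linked_depletion = 0.05,
                              samegene_included = TRUE,
                              aneuploid_replicate_rate = 0,
                              hetdip_dispersion = 3,
                              seed = 1L) {
  stopifnot(n_repair_genes >= 1, n_neutral_genes >= 1,
            replicates_per_gene >= 1, length(conditions) >= 1,
            !anyDuplicated(conditions),
            all(gen_pool > 0), tech_replicates >= 1,
            linked_fraction >= 0, linked_fraction < 1,
            linked_depletion > 0, linked_depletion <= 1,
            aneuploid_replicate_rate >= 0, aneuploid_replicate_rate <= 1,
            hetdip_dispersion >= 1)
  if (reads_per_sample <= 0) stop("reads_per_sample must be positive")
  genes <- c(sprintf("REP%02d", seq_len(n_repair_genes)),
             sprintf("NEU%02d", seq_len(n_neutral_genes)))
  classes <- c(rep("repair", n_repair_genes), rep("neutral", n_neutral_genes))
  fit <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(true_single_fitness)) {
    unknown <- setdiff(names(true_single_fitness), genes)
    if (length(unknown))
      stop("true_single_fitness names not in the gene set: ",
           paste(unknown, collapse = ", "))
    if (any(true_single_fitness < 0 | true_single_fitness > 1.5))
      stop("single-mutant fitness must lie in [0, 1.5]")
    fit[names(true_single_fitness)] <- true_single_fitness
  }
  if (!is.null(true_epsilon)) {
    stopifnot(all(c("gene_i", "gene_j", "condition", "epsilon") %in%
                    names(true_epsilon)))
    unknown <- setdiff(c(true_epsilon$gene_i, true_epsilon$gene_j), genes)
    if (length(unknown))
      stop("true_epsilon references unknown gene(s): ",
           paste(unique(unknown), collapse = ", "))
    unknown <- setdiff(true_epsilon$condition, conditions)
    if (length(unknown))
      stop("true_epsilon references unknown condition(s): ",
           paste(unique(unknown), collapse = ", "))
  }
  gp <- if (length(gen_pool) == 1L && is.null(names(gen_pool))) {
    stats::setNames(rep(gen_pool, length(conditions)), conditions)
  } else {
    if (!all(conditions %in% names(gen_pool)))
      stop("gen_pool must name every condition")
    gen_pool[conditions]
  }
  structure(list(
    genes = genes, gene_class = stats::setNames(classes, genes),
    replicates_per_gene = as.integer(replicates_per_gene),
    conditions = conditions, true_single_fitness = fit,
    true_epsilon = true_epsilon, gen_pool = gp,
    reads_per_sample = as.integer(reads_per_sample),
    tech_replicates = as.integer(tech_replicates),
    linked_fraction = linked_fraction, linked_depletion = linked_depletion,
    samegene_included = isTRUE(samegene_included),
    aneuploid_replicate_rate = aneuploid_replicate_rate,
    hetdip_dispersion = hetdip_dispersion, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a barcode library with guaranteed separation
#'
#' Draws random 20-nt barcodes, greedily keeping only those at Hamming
#' distance >= \code{min_dist} from every accepted barcode (across both
#' sides), so that the <= 3-mismatch matcher is unambiguous on error-free
#' reads.
#'
#' @param n number of barcodes.
#' @param min_dist minimum pairwise Hamming distance.
#' @param width barcode length in nt.
#' @return character vector of \code{n} barcode sequences.
#' @export
generate_barcodes <- function(n, min_dist = 5L, width = 20L) {
  bases <- c("A", "C", "G", "T")
  accepted <- matrix(integer(0), nrow = 0, ncol = width)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place ", n, " barcodes at distance ",
                               min_dist)
    cand <- sample.int(4L, width, replace = TRUE)
    if (nrow(accepted) == 0 ||
        min(rowSums(accepted != matrix(cand, nrow(accepted), width,
                                       byrow = TRUE))) >= min_dist) {
      accepted <- rbind(accepted, cand)
      out <- c(out, paste(bases[cand], collapse = ""))
    }
  }
  out
}

## gene coordinates: every gene on its own chromosome unless linked clusters
## are requested, in which case disjoint gene couples share a chromosome
## 50 kbp apart (inside the 75-kbp linkage cutoff).
place_genes <- function(genes, linked_fraction) {
  n <- length(genes)
  chrom <- paste0("chr", seq_len(n))
  pos <- rep(100000L, n)
  n_pairs <- n * (n - 1) / 2
  n_couples <- min(floor(n / 2), round(linked_fraction * n_pairs))
  if (n_couples > 0) {
    picked <- sample(n, 2L * n_couples)
    for (k in seq_len(n_couples)) {
      a <- picked[2 * k - 1]; b <- picked[2 * k]
      chrom[b] <- chrom[a]
      pos[b] <- pos[a] + 50000L
    }
  }
  data.frame(gene = genes, chromosome = chrom, position_bp = pos)
}

#' Simulate a pooled double-mutant screen
#'
#' Forward model inverted by the scoring engine: starting abundances
#' \code{N0} are gamma-dispersed around a common mean; the hetdip reference
#' sample is a multinomial draw with probabilities proportional to
#' \code{N0}; each haploid sample under condition c is a multinomial draw
#' with probabilities proportional to \code{N0 * d * 2^(w_xy * gen_pool)},
#' where \code{d} is the meiotic depletion factor for linked pairs and
#' same-gene pairs have \code{w_xy = 0}. Technical replicates are
#' independent draws from identical probabilities.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{truth} (strain table, true pairwise
#'   fitness/epsilon per condition, true interaction class per gene pair),
#'   \code{counts} (a \code{\link{fused_counts}}) and \code{library} (a
#'   barcode library data.frame).
#' @export
simulate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  reps <- config$replicates_per_gene

  ## strain (barcode replicate) tables, one per side
  coords <- place_genes(genes, config$linked_fraction)
  mk_side <- function(side) {
    g <- rep(genes, each = reps)
    data.frame(
      barcode_id = sprintf("%s_%s_b%d", substr(side, 1, 1), g,
                           rep(seq_len(reps), length(genes))),
      side = side, gene = g,
      gene_class = unname(config$gene_class[g]),
      strain_id = sprintf("%s_%s_r%d", side, g, rep(seq_len(reps), length(genes))),
      chromosome = coords$chromosome[match(g, coords$gene)],
      position_bp = coords$position_bp[match(g, coords$gene)],
      aneuploid = stats::runif(length(g)) < config$aneuploid_replicate_rate
    )
  }
  donors <- mk_side("donor")
  recipients <- mk_side("recipient")
  seqs <- generate_barcodes(nrow(donors) + nrow(recipients))
  donors$sequence <- seqs[seq_len(nrow(donors))]
  recipients$sequence <- seqs[nrow(donors) + seq_len(nrow(recipients))]
  library <- validate_barcode_library(
    rbind(donors[, c("barcode_id", "sequence", "side", "strain_id", "gene",
                     "gene_class", "chromosome", "position_bp")],
          recipients[, c("barcode_id", "sequence", "side", "strain_id", "gene",
                         "gene_class", "chromosome", "position_bp")]))

  ## all donor x recipient pairs
  di <- rep(seq_len(nrow(donors)), times = nrow(recipients))
  ri <- rep(seq_len(nrow(recipients)), each = nrow(donors))
  pairs <- data.frame(
    pair_id = pair_id(donors$barcode_id[di], recipients$barcode_id[ri]),
    donor_bc = donors$barcode_id[di],
    recipient_bc = recipients$barcode_id[ri],
    donor_gene = donors$gene[di],
    recipient_gene = recipients$gene[ri]
  )
  same_gene <- pairs$donor_gene == pairs$recipient_gene
  linked <- donors$chromosome[di] == recipients$chromosome[ri] &
    abs(donors$position_bp[di] - recipients$position_bp[ri]) < 75000 &
    !same_gene
  if (!config$samegene_included) {
    keep <- !same_gene
    pairs <- pairs[keep, ]; di <- di[keep]; ri <- ri[keep]
    same_gene <- same_gene[keep]; linked <- linked[keep]
  }
  n_pairs <- nrow(pairs)

  ## true fitness per strain pair per condition
  eps_lookup <- function(gi, gj, cond) {
    te <- config$true_epsilon
    if (is.null(te)) return(numeric(length(gi)))
    key <- function(a, b, cc) paste(pmin(a, b), pmax(a, b), cc, sep = "|")
    tab <- stats::setNames(te$epsilon, key(te$gene_i, te$gene_j, te$condition))
    v <- tab[key(gi, gj, cond)]
    v[is.na(v)] <- 0
    unname(v)
  }
  ## aneuploid replicates: whole profile redrawn, decorrelated from the gene
  aneu_d <- donors$aneuploid[di]
  aneu_r <- recipients$aneuploid[ri]
  w_true <- matrix(NA_real_, n_pairs, length(config$conditions),
                   dimnames = list(pairs$pair_id, config$conditions))
  eps_true <- w_true
  for (cond in config$conditions) {
    wx <- unname(config$true_single_fitness[pairs$donor_gene])
    wy <- unname(config$true_single_fitness[pairs$recipient_gene])
    eps <- eps_lookup(pairs$donor_gene, pairs$recipient_gene, cond)
    w <- pmax(wx * wy + eps, 0)
    w[same_gene] <- 0
    ## aneuploid-like artifact replicates: the entire fitness row is
    ## redrawn (an independent single fitness per condition plus iid
    ## pair-level noise), overriding even same-gene lethality -- the
    ## artifact decouples the strain from its expected behavior
    for (side in c("d", "r")) {
      aneu <- if (side == "d") aneu_d else aneu_r
      if (!any(aneu)) next
      strains <- if (side == "d") donors$barcode_id[di] else recipients$barcode_id[ri]
      for (s in unique(strains[aneu])) {
        idx <- which(strains == s)
        w_alt <- if (side == "d") stats::runif(1, 0.5, 1.1) * wy[idx]
                 else wx[idx] * stats::runif(1, 0.5, 1.1)
        w[idx] <- pmax(w_alt + stats::rnorm(length(idx), 0, 0.2), 0)
        eps[idx] <- NA_real_
      }
    }
    w_true[, cond] <- w
    eps_true[, cond] <- eps
  }

  ## starting abundances and sampling
  n0 <- stats::rgamma(n_pairs, shape = config$hetdip_dispersion,
                      rate = config$hetdip_dispersion)
  depl <- ifelse(linked, config$linked_depletion, 1)
  sample_rows <- list(data.frame(sample_id = "HetDip", condition = "HetDip",
                                 tech_replicate = 1L, stage = "hetdip",
                                 gen_pool = NA_real_))
  count_cols <- list(HetDip = stats::rmultinom(1, config$reads_per_sample,
                                               n0 / sum(n0))[, 1])
  for (cond in config$conditions) {
    share <- n0 * depl * 2^(w_true[, cond] * config$gen_pool[[cond]])
    p <- share / sum(share)
    for (tr in seq_len(config$tech_replicates)) {
      sid <- sprintf("%s_R%d", cond, tr)
      sample_rows[[length(sample_rows) + 1L]] <-
        data.frame(sample_id = sid, condition = cond, tech_replicate = tr,
                   stage = "haploid", gen_pool = config$gen_pool[[cond]])
      count_cols[[sid]] <- stats::rmultinom(1, config$reads_per_sample, p)[, 1]
    }
  }
  samples <- do.call(rbind, sample_rows)
  counts <- fused_counts(do.call(cbind, count_cols), pairs[, 1:3], samples)

  ## gene-pair truth classes
  gp <- unique(data.frame(
    gene1 = pmin(pairs$donor_gene, pairs$recipient_gene),
    gene2 = pmax(pairs$donor_gene, pairs$recipient_gene)))
  truth_class <- do.call(rbind, lapply(config$conditions, function(cond) {
    eps <- eps_lookup(gp$gene1, gp$gene2, cond)
    data.frame(gene1 = gp$gene1, gene2 = gp$gene2, condition = cond,
               epsilon = eps,
               class = ifelse(gp$gene1 == gp$gene2, "same_gene",
                              ifelse(eps > 0, "positive",
                                     ifelse(eps < 0, "negative", "neutral"))))
  }))

  strains <- rbind(donors, recipients)
  truth <- list(
    strains = strains[, c("barcode_id", "side", "gene", "gene_class",
                          "strain_id", "chromosome", "position_bp",
                          "aneuploid")],
    pair_fitness = data.frame(pairs, same_gene = same_gene, linked = linked,
                              n0 = n0),
    w_true = w_true, epsilon_true = eps_true,
    gene_class_truth = truth_class
  )
  list(truth = truth, counts = counts, library = library)
}

#' Emit sequencing reads for a simulated count table
#'
#' Writes three FASTQ files: R1 (donor barcode read), R2 (recipient barcode
#' read) and I1 (6-nt sample index). Barcode reads are 25 nt: the 20-nt
#' barcode followed by a 5-nt constant flank, with iid per-base substitution
#' errors at \code{error_rate}; index reads are emitted verbatim (indices
#' are matched exactly downstream). Qualities are fixed at 'I' (Phred 40).
#' Read counts per (pair, sample) match the count table exactly.
#'
#' @param counts a \code{\link{fused_counts}}.
#' @param library barcode library with sequences for every barcode in
#'   \code{counts}.
#' @param dir output directory (created if needed).
#' @param error_rate per-base substitution probability in [0, 0.25].
#' @param flank 5-nt constant flank appended to each barcode read.
#' @param shuffle interleave reads across pairs/samples (default) rather
#'   than emitting them grouped.
#' @return list with paths \code{r1}, \code{r2}, \code{index},
#'   \code{sample_indices} (data.frame sample_id -> index sequence).
#' @export
simulate_reads <- function(counts, library, dir, error_rate = 0,
                           flank = "ACGTA", shuffle = TRUE) {
  stopifnot(inherits(counts, "fused_counts"))
  if (error_rate < 0 || error_rate > 0.25)
    stop("error_rate must lie in [0, 0.25]")
  library <- validate_barcode_library(library)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dseq <- stats::setNames(library$sequence[library$side == "donor"],
                          library$barcode_id[library$side == "donor"])
  rseq <- stats::setNames(library$sequence[library$side == "recipient"],
                          library$barcode_id[library$side == "recipient"])
  miss <- setdiff(counts$pairs$donor_bc, names(dseq))
  miss <- c(miss, setdiff(counts$pairs$recipient_bc, names(rseq)))
  if (length(miss))
    stop("count table references barcodes absent from the library: ",
         paste(unique(miss), collapse = ", "))

  n_samp <- ncol(counts$counts)
  idx_seqs <- make_sample_indices(n_samp)
  sample_indices <- data.frame(sample_id = colnames(counts$counts),
                               index = idx_seqs)

  per_cell <- as.integer(counts$counts)
  pair_rep <- rep(rep(seq_len(nrow(counts$pairs)), n_samp), per_cell)
  samp_rep <- rep(rep(seq_len(n_samp), each = nrow(counts$pairs)), per_cell)
  n_reads <- length(pair_rep)
  if (n_reads > 0 && shuffle) {
    ord <- sample.int(n_reads)
    pair_rep <- pair_rep[ord]; samp_rep <- samp_rep[ord]
  }
  if (n_reads > 0) {
    r1 <- paste0(unname(dseq[counts$pairs$donor_bc[pair_rep]]), flank)
    r2 <- paste0(unname(rseq[counts$pairs$recipient_bc[pair_rep]]), flank)
    i1 <- idx_seqs[samp_rep]
  } else {
    r1 <- r2 <- i1 <- character(0)
  }
  if (error_rate > 0 && n_reads > 0) {
    r1 <- add_substitutions(r1, error_rate)
    r2 <- add_substitutions(r2, error_rate)
  }
  ids <- if (n_reads > 0) sprintf("read%07d", seq_len(n_reads)) else character(0)
  paths <- list(r1 = file.path(dir, "reads_R1.fastq"),
                r2 = file.path(dir, "reads_R2.fastq"),
                index = file.path(dir, "reads_I1.fastq"),
                sample_indices = sample_indices)
  write_fastq(ids, r1, paths$r1)
  write_fastq(ids, r2, paths$r2)
  write_fastq(ids, i1, paths$index)
  write_tsv(sample_indices, file.path(dir, "sample_indices.tsv"))
  paths
}

## deterministic, well-separated 6-nt sample indices
make_sample_indices <- function(n) {
  bases <- c("A", "C", "G", "T")
  ## enumerate codon-style triplets and double them: pairwise Hamming >= 2
  combos <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                        stringsAsFactors = FALSE)
  if (n > nrow(combos)) stop("too many samples for 6-nt indices")
  apply(combos[seq_len(n), ], 1, function(r) paste0(paste(r, collapse = ""),
                                                    paste(rev(r), collapse = "")))
}

add_substitutions <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  width <- nchar(reads[1])
  m <- matrix(unlist(strsplit(reads, "")), ncol = width, byrow = TRUE)
  hit <- which(matrix(stats::runif(length(m)) < rate, nrow(m), width))
  if (length(hit)) {
    ## substitute with one of the three other bases, uniformly
    cur <- match(m[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  apply(m, 1, paste, collapse = "")
}

write_fastq <- function(ids, seqs, path) {
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
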