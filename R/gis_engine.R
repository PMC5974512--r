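## Core scoring engine: pooled exponential growth model.
##
## A strain pair's frequency ratio between a haploid pool sample and the
## heterozygous-diploid reference ("time zero") gives its number of
## doublings, g.t = log2(f_t/f_0) + gen_pool. Doublings relative to the
## wild-type baseline (mean over neutral-neutral pairs) give relative
## fitness w; the genetic interaction score is the deviation from the
## multiplicative expectation, GIS = w_xy - w_x * w_y, with negative w
## clipped to 0.

#' Strain frequencies with pseudocount
#'
#' \code{f_s = (N_s + 0.5) / sum(N_i + 0.5)} over retained strain pairs; the
#' 0.5 pseudocount keeps every downstream ratio finite.
#'
#' @param counts non-negative count vector (one sample) or matrix
#'   (pairs x samples, normalized per column) of retained pairs.
#' @param pseudocount added to every count before normalizing.
#' @return frequencies of the same shape as \code{counts}; columns sum to 1.
#' @export
strain_frequencies <- function(counts, pseudocount = 0.5) {
  if (length(counts) == 0) stop("empty retained set")
  if (is.matrix(counts)) {
    p <- counts + pseudocount
    sweep(p, 2, colSums(p), "/")
  } else {
    p <- counts + pseudocount
    p / sum(p)
  }
}

#' Per-strain doublings from frequency ratios
#'
#' \code{g.t = log2(f_t / f_0) + gen_pool}: the frequency ratio between a
#' grown pool and the hetdip reference, offset by the generations of pool
#' growth, measures a strain pair's absolute number of doublings.
#'
#' @param f_t,f_0 frequencies in the grown sample and the reference.
#' @param gen_pool generations of pool growth (> 0).
#' @return doublings, same shape as \code{f_t}.
#' @export
doublings <- function(f_t, f_0, gen_pool) {
  stopifnot(all(gen_pool > 0))
  log2(f_t / f_0) + gen_pool
}

#' Wild-type doublings baseline
#'
#' Arithmetic mean of \code{g.t} over qualifying (retained, unlinked,
#' distinct-gene neutral-neutral) pairs, with its sample standard deviation
#' as the uncertainty.
#'
#' @param gt doublings of the qualifying pairs.
#' @return list with \code{g_wt} and \code{sigma}.
#' @export
wildtype_doublings <- function(gt) {
  gt <- gt[is.finite(gt)]
  if (length(gt) < 3)
    stop("need >= 3 neutral-neutral pairs to estimate wild-type growth, got ",
         length(gt))
  list(g_wt = mean(gt), sigma = stats::sd(gt))
}

#' Delta-method uncertainty of the genetic interaction score
#'
#' Propagates the four error terms through
#' \code{GIS = w_xy - g_x g_y / g_wt^2} (the doublings-space restatement of
#' \code{w_xy - w_x w_y}), ignoring covariances:
#' \deqn{\sigma_{GIS}^2 = \sigma_{w_{xy}}^2 +
#'   (g_y/g_{wt}^2)^2 \sigma_{g_x}^2 + (g_x/g_{wt}^2)^2 \sigma_{g_y}^2 +
#'   (2 g_x g_y / g_{wt}^3)^2 \sigma_{g_{wt}}^2}
#'
#' @param sigma_wxy global per-condition double-mutant fitness error.
#' @param g_x,g_y,g_wt single-mutant and wild-type doublings (g.t values).
#' @param sigma_gx,sigma_gy,sigma_gwt their standard deviations.
#' @return \code{sigma_GIS}, vectorized over pairs.
#' @export
sigma_gis <- function(sigma_wxy, g_x, g_y, g_wt, sigma_gx, sigma_gy,
                      sigma_gwt) {
  if (any(g_wt == 0)) stop("g_wt is zero; wild-type baseline undefined")
  sqrt(sigma_wxy^2 +
         (g_y / g_wt^2)^2 * sigma_gx^2 +
         (g_x / g_wt^2)^2 * sigma_gy^2 +
         (2 * g_x * g_y / g_wt^3)^2 * sigma_gwt^2)
}

#' Fit the empirical neutral null
#'
#' Few or no interactions are expected among unlinked pairs involving a
#' neutral gene, so the distribution of their Z scores serves as the null.
#' It is summarized by a normal with the sample mean and SD.
#'
#' @param z finite Z scores of neutral pairs.
#' @param min_n minimum number of neutral pairs required.
#' @return list with \code{mu}, \code{sigma} and \code{n}.
#' @export
fit_neutral_null <- function(z, min_n = 20) {
  z <- z[is.finite(z)]
  if (length(z) < min_n)
    stop("need >= ", min_n, " neutral pairs with finite Z, got ", length(z))
  s <- stats::sd(z)
  if (s == 0) stop("neutral Z scores are all identical; null degenerate")
  list(mu = mean(z), sigma = s, n = length(z))
}

#' Two-tailed empirical-null p-value
#'
#' \code{p = min(P(Z_null >= z), P(Z_null <= z)) * 2}, capped at 1: the
#' probability of a score at least as extreme among neutral pairs.
#'
#' @param z Z scores.
#' @param null a fit from \code{\link{fit_neutral_null}} (list with
#'   \code{mu}, \code{sigma}).
#' @return p-values in (0, 1].
#' @export
p_neutral <- function(z, null) {
  ppos <- stats::pnorm(z, null$mu, null$sigma, lower.tail = FALSE)
  pneg <- stats::pnorm(z, null$mu, null$sigma, lower.tail = TRUE)
  ## keep extreme scores representable: p must stay in (0, 1]
  pmax(pmin(pmin(ppos, pneg) * 2, 1), .Machine$double.xmin)
}

## ---- full barcode-level scoring over a masked count table ----

## ann: per-pair annotation from annotate_pairs(); retained: logical mask.
## Returns per-condition barcode records plus condition-level error terms.
compute_barcode_gis <- function(counts, ann, retained, min_null = 3) {
  samples <- counts$samples
  mat <- counts$counts
  if (!any(retained)) stop("empty retained set")
  idx <- which(retained)
  hd <- samples$stage == "hetdip"
  hap <- which(samples$stage == "haploid")

  c0 <- rowSums(mat[idx, hd, drop = FALSE])
  f0 <- strain_frequencies(c0)
  f <- strain_frequencies(mat[idx, hap, drop = FALSE])
  g <- sweep(log2(f / f0), 2, samples$gen_pool[hap], "+")

  nn <- ann$null_neutral[idx]
  if (sum(nn) < min_null)
    stop("need >= ", min_null, " unlinked neutral-neutral pairs, got ", sum(nn))
  g_wt_s <- colMeans(g[nn, , drop = FALSE])
  w_s <- sweep(g, 2, g_wt_s, "/")

  conds <- unique(samples$condition[hap])
  rec_list <- vector("list", length(conds))
  stat_list <- vector("list", length(conds))
  for (k in seq_along(conds)) {
    cond <- conds[k]
    reps <- which(samples$condition[hap] == cond)
    if (length(reps) < 2)
      stop("condition '", cond, "' has a single technical replicate; ",
           "sigma_wxy is not estimable")
    g_c <- rowMeans(g[, reps, drop = FALSE])
    w_c <- rowMeans(w_s[, reps, drop = FALSE])
    g_wt_c <- mean(g_wt_s[reps])
    sigma_gwt_c <- stats::sd(g_c[nn])

    ## global fitness error: median |w(Ri) - w(Rj)| over replicate pairs
    diffs <- numeric(0)
    for (i in seq_along(reps)) for (j in seq_along(reps)) if (i < j)
      diffs <- c(diffs, abs(w_s[, reps[i]] - w_s[, reps[j]]))
    sigma_wxy_c <- stats::median(diffs)

    ## single-mutant doublings: mean over retained unlinked neutral partners
    gx_tab <- side_stats(ann$donor_bc[idx], g_c, ann$partner_for_donor[idx])
    gy_tab <- side_stats(ann$recipient_bc[idx], g_c,
                         ann$partner_for_recipient[idx])
    g_x <- gx_tab$mean[match(ann$donor_bc[idx], gx_tab$bc)]
    s_gx <- gx_tab$sd[match(ann$donor_bc[idx], gx_tab$bc)]
    g_y <- gy_tab$mean[match(ann$recipient_bc[idx], gy_tab$bc)]
    s_gy <- gy_tab$sd[match(ann$recipient_bc[idx], gy_tab$bc)]

    usable <- !is.na(g_x) & !is.na(g_y)
    if (!all(usable))
      warning(sum(!usable), " pair(s) skipped in condition '", cond,
              "': no retained unlinked neutral partner on one side")
    w_x <- g_x / g_wt_c
    w_y <- g_y / g_wt_c
    gis <- pmax(w_c, 0) - pmax(w_x, 0) * pmax(w_y, 0)
    sg <- sigma_gis(sigma_wxy_c, g_x, g_y, g_wt_c, s_gx, s_gy, sigma_gwt_c)
    z <- ifelse(sg > 0, gis / sg, NA_real_)

    rec_list[[k]] <- data.frame(
      pair_id = ann$pair_id[idx], donor_bc = ann$donor_bc[idx],
      recipient_bc = ann$recipient_bc[idx],
      donor_gene = ann$donor_gene[idx], recipient_gene = ann$recipient_gene[idx],
      condition = cond, w_x = w_x, w_y = w_y, w_xy = w_c,
      g_x = g_x, g_y = g_y, gis = gis, sigma_gis = sg, z_gis = z,
      same_gene = ann$same_gene[idx], linked = ann$linked[idx],
      neutral_pair = ann$neutral_pair[idx]
    )[usable, ]
    stat_list[[k]] <- data.frame(condition = cond, g_wt = g_wt_c,
                                 sigma_gwt = sigma_gwt_c,
                                 sigma_wxy = sigma_wxy_c)
  }
  list(records = do.call(rbind, rec_list),
       condition_stats = do.call(rbind, stat_list))
}

## per-barcode mean and sample SD of g over its neutral partner pairs
side_stats <- function(bc, g_c, partner_ok) {
  sel <- which(partner_ok)
  if (length(sel) == 0)
    return(data.frame(bc = character(0), mean = numeric(0), sd = numeric(0)))
  f <- factor(bc[sel])
  m <- tapply(g_c[sel], f, mean)
  s <- tapply(g_c[sel], f, function(v) if (length(v) > 1) stats::sd(v) else 0)
  data.frame(bc = levels(f), mean = as.numeric(m), sd = as.numeric(s))
}

#' Score a pooled double-mutant screen at barcode level
#'
#' Runs the full barcode-level analysis: heterozygous-diploid coverage
#' filter, linkage classification, a first scoring pass, the replicate
#' profile-correlation filter, a final scoring pass on the survivors, and
#' empirical-null p-values per condition. Raw counts are never mutated;
#' all exclusions are masks.
#'
#' @param counts a \code{\link{fused_counts}}.
#' @param library a barcode library covering every barcode in \code{counts}.
#' @param cxy_min minimum hetdip count for a pair to be well-measured.
#' @param linkage_bp genetic-linkage cutoff (same chromosome, distance
#'   below this) in bp.
#' @param replicate_r minimum profile correlation for a barcode replicate
#'   to be retained.
#' @param min_null minimum neutral pairs for the null fit.
#' @return A \code{"gipool_scores"} list: \code{records} (barcode-level GIS
#'   with errors, Z and p per condition), \code{qc} (per-pair
#'   classification), \code{replicate_qc}, \code{excluded_replicates},
#'   \code{nulls}, \code{condition_stats}, \code{retained}, \code{ann}.
#' @export
score_pool <- function(counts, library, cxy_min = 30, linkage_bp = 75000,
                       replicate_r = 0.5, min_null = 20) {
  stopifnot(inherits(counts, "fused_counts"))
  library <- validate_barcode_library(library)
  ann <- annotate_pairs(counts$pairs, library, linkage_bp)
  cov <- filter_hetdip_coverage(counts, cxy_min)
  retained <- cov$well_measured

  pass1 <- compute_barcode_gis(counts, ann, retained)
  repqc <- filter_replicates_by_profile(pass1$records, replicate_r,
                                        cxy = cov$C_xy, ann = ann)
  excl <- repqc$excluded
  if (length(excl)) {
    retained <- retained & !(ann$donor_bc %in% excl) &
      !(ann$recipient_bc %in% excl)
  }
  final <- compute_barcode_gis(counts, ann, retained)

  rec <- final$records
  nulls <- list()
  rec$p_neutral <- NA_real_
  for (cond in unique(rec$condition)) {
    in_c <- rec$condition == cond
    nz <- rec$z_gis[in_c & rec$neutral_pair]
    nulls[[cond]] <- fit_neutral_null(nz, min_n = min_null)
    rec$p_neutral[in_c] <- p_neutral(rec$z_gis[in_c], nulls[[cond]])
  }

  qc <- data.frame(
    pair_id = ann$pair_id, donor_bc = ann$donor_bc,
    recipient_bc = ann$recipient_bc, C_xy = cov$C_xy,
    well_measured = cov$well_measured, same_gene = ann$same_gene,
    linked = ann$linked, retained = retained
  )
  structure(list(records = rec, qc = qc, replicate_qc = repqc$table,
                 excluded_replicates = excl, flagged_replicates = repqc$flagged,
                 nulls = nulls, condition_stats = final$condition_stats,
                 retained = retained, ann = ann,
                 thresholds = list(cxy_min = cxy_min, linkage_bp = linkage_bp,
                                   replicate_r = replicate_r)),
            class = "gipool_scores")
}

#' @export
print.gipool_scores <- function(x, ...) {
  cat("gipool_scores:", nrow(x$records), "barcode-pair records over",
      length(x$nulls), "condition(s)\n")
  cat("  retained pairs:", sum(x$retained), "/", length(x$retained), "\n")
  if (length(x$excluded_replicates))
    cat("  excluded replicates:", paste(x$excluded_replicates, collapse = ", "),
        "\n")
  invisible(x)
}
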