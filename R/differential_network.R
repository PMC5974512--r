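## Differential (condition-dependent) genetic interactions: for each pair of
## conditions, the change in a gene pair's score is standardized against the
## combined uncertainty, calibrated on the neutral-pair null, and called at
## FDR and effect-size cutoffs.

#' Differential score and standardized difference between two conditions
#'
#' \code{dGIS = GIS_a - GIS_b}; \code{dZ = dGIS / sqrt(sigma_a^2 +
#' sigma_b^2)}. Both negate when the conditions are swapped.
#'
#' @param gis_a,gis_b gene-level scores in conditions a and b.
#' @param sigma_a,sigma_b their uncertainties.
#' @return list with \code{dgis} and \code{dz} (vectorized).
#' @export
delta_gis_z <- function(gis_a, gis_b, sigma_a, sigma_b) {
  denom <- sqrt(sigma_a^2 + sigma_b^2)
  if (any(denom == 0))
    stop("both conditions report zero uncertainty; dZ undefined")
  dgis <- gis_a - gis_b
  list(dgis = dgis, dz = dgis / denom)
}

#' Call differential genetic interactions across all condition pairs
#'
#' For every unordered condition pair (a, b), a canonical orientation with
#' a < b alphabetically: the per-gene-pair \code{dGIS} and \code{dZ} are
#' computed; a normal null is fitted to \code{dZ} over neutral gene pairs
#' (unlinked, distinct-gene pairs involving at least one neutral gene);
#' two-tailed p-values follow as for the per-condition scores; q-values are
#' computed within the condition pair over repair-repair gene pairs; and a
#' record is significant when \code{q < q_cutoff} and
#' \code{|dGIS| > effect_cutoff}. The interaction-type change (e.g.
#' \code{"- -> n"}) is attached from the per-condition calls.
#'
#' @param genes gene-level records from \code{\link{gene_calls}}.
#' @param q_cutoff,effect_cutoff differential calling thresholds (defaults
#'   FDR < 0.01, |dGIS| > 0.1).
#' @param min_null minimum neutral gene pairs for the null fit.
#' @return list with \code{records} (one row per gene pair x condition
#'   pair) and \code{summary} (per condition pair: significant and
#'   type-changing counts).
#' @export
call_differentials <- function(genes, q_cutoff = 0.01, effect_cutoff = 0.1,
                               min_null = 20) {
  conds <- sort(unique(genes$condition))
  if (length(conds) < 2) stop("need >= 2 scored conditions")
  genes$pair_key <- paste(genes$gene1, genes$gene2, sep = "\r")
  code <- c(positive = "+", negative = "-", neutral = "n")
  rec_list <- list()
  sum_list <- list()
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (i >= j) next
    a <- conds[i]; b <- conds[j]
    ga <- genes[genes$condition == a, ]
    gb <- genes[genes$condition == b, ]
    m <- match(ga$pair_key, gb$pair_key)
    ok <- !is.na(m)
    ga <- ga[ok, ]; gb <- gb[m[ok], ]
    d <- delta_gis_z(ga$gis, gb$gis, ga$sigma, gb$sigma)
    rec <- data.frame(
      gene1 = ga$gene1, gene2 = ga$gene2, cond_a = a, cond_b = b,
      dgis = d$dgis, dz = d$dz,
      call_a = ga$call, call_b = gb$call,
      neutral_pair = ga$neutral_pair, same_gene = ga$same_gene,
      linked = ga$linked
    )
    nullset <- rec$neutral_pair & !rec$same_gene & !rec$linked
    if (sum(nullset) < min_null)
      stop("condition pair ", a, "-", b, ": only ", sum(nullset),
           " neutral gene pairs for the dZ null (need >= ", min_null, ")")
    if (stats::sd(rec$dz[nullset]) == 0) {
      ## degenerate null (e.g. two identical condition profiles): any
      ## nonzero shift is off-null, no shift is fully null
      mu0 <- mean(rec$dz[nullset])
      rec$p_delta <- ifelse(rec$dz == mu0, 1, .Machine$double.xmin)
    } else {
      null <- fit_neutral_null(rec$dz[nullset], min_n = min_null)
      rec$p_delta <- p_neutral(rec$dz, null)
    }
    rec$q_delta <- NA_real_
    scored <- !rec$same_gene & !rec$linked & !rec$neutral_pair
    if (any(scored)) rec$q_delta[scored] <- storey_qvalue(rec$p_delta[scored])
    rec$significant <- !is.na(rec$q_delta) & rec$q_delta < q_cutoff &
      abs(rec$dgis) > effect_cutoff
    rec$type_change <- ifelse(
      is.na(rec$call_a) | is.na(rec$call_b), NA_character_,
      paste(code[rec$call_a], "->", code[rec$call_b]))
    rec$type_changed <- !is.na(rec$type_change) &
      rec$call_a != rec$call_b
    rec_list[[paste(a, b)]] <- rec
    sum_list[[paste(a, b)]] <- data.frame(
      cond_a = a, cond_b = b,
      n_tested = sum(scored),
      n_significant = sum(rec$significant),
      n_type_changing = sum(rec$significant & rec$type_changed)
    )
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  list(records = records, summary = do.call(rbind, sum_list))
}

#' Hierarchically cluster conditions by their interaction profiles
#'
#' Pairwise Chebyshev (maximum) distance between condition profiles over
#' commonly scored gene pairs, followed by complete-linkage agglomeration.
#' Conditions are ordered lexicographically before clustering so ties break
#' deterministically; missing gene pairs are dropped pairwise, never
#' imputed.
#'
#' @param genes gene-level records from \code{\link{gene_calls}}, or a
#'   numeric matrix conditions x gene pairs.
#' @return list with \code{hclust} (a \code{stats::hclust} tree),
#'   \code{newick} (the tree in Newick format) and \code{dist}.
#' @export
cluster_conditions <- function(genes) {
  if (is.matrix(genes)) {
    m <- genes[order(rownames(genes)), , drop = FALSE]
  } else {
    conds <- sort(unique(genes$condition))
    pairs <- sort(unique(paste(genes$gene1, genes$gene2, sep = "\r")))
    m <- matrix(NA_real_, length(conds), length(pairs),
                dimnames = list(conds, pairs))
    m[cbind(match(genes$condition, conds),
            match(paste(genes$gene1, genes$gene2, sep = "\r"), pairs))] <-
      genes$gis
  }
  if (nrow(m) < 2) stop("need >= 2 conditions to cluster")
  all_missing <- rowSums(is.finite(m)) == 0
  if (any(all_missing))
    stop("condition(s) with all-missing profiles: ",
         paste(rownames(m)[all_missing], collapse = ", "))
  d <- stats::dist(m, method = "maximum")
  hc <- stats::hclust(d, method = "complete")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)), dist = d)
}

#' Cells required for a genome-scale pooled screen
#'
#' Pool-size arithmetic for scaling the assay: every step of the pooled
#' procedure must carry enough cells to represent every cross, i.e.
#' \code{n_donors * n_recipients * cells_per_cross} cells. A 5,500 x 5,500
#' gene matrix at 1,000 cells per cross needs ~3e10 cells.
#'
#' @param n_donors,n_recipients strains per side.
#' @param cells_per_cross representative cells per double mutant.
#' @return total cells required.
#' @export
pool_cells_required <- function(n_donors, n_recipients,
                                cells_per_cross = 1000) {
  stopifnot(n_donors > 0, n_recipients > 0, cells_per_cross > 0)
  n_donors * n_recipients * cells_per_cross
}
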