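## Gene-level aggregation: barcode-pair records for the same gene pair are
## combined by inverse-variance weighting, p-values by weighted Stouffer,
## and per-condition false-discovery rates by Storey's q-value.

#' Inverse-variance combination of barcode-level records
#'
#' Weights \code{w_b = 1/sigma_b^2}; the combined score is the weighted
#' mean, and its uncertainty follows from propagating the weighted average:
#' \code{sigma = sqrt(sum(w^2 sigma^2)) / sum(w)}, which for these weights
#' equals \code{1/sqrt(sum(w))}. A record with \code{sigma = 0} carries
#' infinite weight and dominates; if every record has \code{sigma = 0} the
#' unweighted mean is returned with \code{sigma = 0} and a flag.
#'
#' @param gis barcode-level scores.
#' @param sigma their uncertainties (>= 0).
#' @param extra optional data.frame of columns (e.g. w_x, w_y, w_xy) to
#'   aggregate with the same weights.
#' @return list with \code{gis}, \code{sigma}, \code{z}, \code{weights},
#'   \code{degenerate} flag and (if given) aggregated \code{extra}.
#' @export
combine_barcode_records <- function(gis, sigma, extra = NULL) {
  stopifnot(length(gis) >= 1, length(gis) == length(sigma), all(sigma >= 0))
  zero <- sigma == 0
  degenerate <- FALSE
  if (all(zero)) {
    degenerate <- TRUE
    w <- rep(1, length(gis))
    g <- mean(gis); s <- 0
  } else if (any(zero)) {
    ## zero-uncertainty records dominate an inverse-variance average
    w <- as.numeric(zero)
    g <- mean(gis[zero]); s <- 0
  } else {
    w <- 1 / sigma^2
    g <- sum(w * gis) / sum(w)
    s <- sqrt(sum(w^2 * sigma^2)) / sum(w)
  }
  out <- list(gis = g, sigma = s,
              z = if (s > 0) g / s else NA_real_,
              weights = w, degenerate = degenerate)
  if (!is.null(extra))
    out$extra <- vapply(extra, function(col) sum(w * col) / sum(w), numeric(1))
  out
}

#' Weighted Stouffer combination of two-tailed p-values
#'
#' Each record's two-tailed p is converted back to a signed z
#' (\code{z_b = sign_b * qnorm(1 - p_b/2)}, the sign taken from its score so
#' that conflicting replicates cancel), combined as
#' \code{Z = sum(w z) / sqrt(sum(w^2))}, and returned as the two-tailed
#' \code{p = 2 (1 - pnorm(|Z|))}.
#'
#' @param p two-tailed p-values in (0, 1]; exact zeros are clamped to the
#'   smallest representable positive value with a warning.
#' @param sign direction of each record's score (+1/-1; 0 allowed).
#' @param w positive weights.
#' @return list with \code{p} and \code{z}.
#' @export
stouffer_combine <- function(p, sign, w) {
  stopifnot(length(p) == length(sign), length(p) == length(w), all(w >= 0))
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to the smallest representable value")
    p <- pmax(p, .Machine$double.xmin)
  }
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  if (all(w == 0)) w <- rep(1, length(w))
  z_b <- sign(sign) * stats::qnorm(1 - p / 2)
  z <- sum(w * z_b) / sqrt(sum(w^2))
  ## extreme |z| underflows the two-tailed p; keep it representable
  list(p = max(2 * stats::pnorm(abs(z), lower.tail = FALSE),
               .Machine$double.xmin),
       z = z)
}

#' Storey q-values
#'
#' Converts p-values to false-discovery-rate q-values with the proportion of
#' true nulls estimated by Storey's smoother: \code{pi0(lambda) =
#' mean(p > lambda) / (1 - lambda)} on \code{lambda = 0.05, ..., 0.95},
#' smoothed by a cubic spline and read off at the largest lambda, clamped to
#' (0, 1]. With fewer than 20 p-values the estimate is unstable and
#' \code{pi0 = 1} is used (equivalent to Benjamini-Hochberg) with a warning.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning grid for the pi0 smoother.
#' @param pi0 override the pi0 estimate (e.g. \code{pi0 = 1} for BH).
#' @return q-values, monotone in p.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  stopifnot(all(p > 0), all(p <= 1))
  n <- length(p)
  if (is.null(pi0)) {
    if (n < 20) {
      warning("fewer than 20 p-values; using pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, .Machine$double.eps))
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * p[o] * n / (n:1)
  q <- cummin(q)
  pmin(q[ro], 1)
}

#' Classify a gene-pair interaction
#'
#' Positive if \code{q < q_cutoff} and \code{gis > effect_cutoff}; negative
#' if \code{q < q_cutoff} and \code{gis < -effect_cutoff}; neutral
#' otherwise. Defaults mirror the screen-wide cutoffs FDR < 0.01 and
#' |GIS| > 0.075.
#'
#' @param gis,q gene-level score and q-value (vectorized).
#' @param q_cutoff,effect_cutoff calling thresholds.
#' @return character vector in \code{c("positive", "negative", "neutral")}.
#' @export
call_interaction <- function(gis, q, q_cutoff = 0.01, effect_cutoff = 0.075) {
  ifelse(q < q_cutoff & gis > effect_cutoff, "positive",
         ifelse(q < q_cutoff & gis < -effect_cutoff, "negative", "neutral"))
}

#' Aggregate barcode-level scores to gene-pair calls
#'
#' Groups retained barcode records by (gene pair, condition) — gene pairs
#' oriented alphabetically — combines scores by inverse-variance weighting
#' and p-values by weighted Stouffer, converts p to q within each condition
#' with \code{\link{storey_qvalue}}, and calls interactions with
#' \code{\link{call_interaction}}. Same-gene and linked gene pairs are
#' aggregated and reported with their flags but kept out of the q-value
#' computation and called \code{NA}.
#'
#' @param scores a \code{"gipool_scores"} object from
#'   \code{\link{score_pool}}.
#' @param q_cutoff,effect_cutoff calling thresholds.
#' @return data.frame of gene-level records: gene1, gene2, condition,
#'   gis, sigma, z, p, q, call, n_barcodes, flags.
#' @export
gene_calls <- function(scores, q_cutoff = 0.01, effect_cutoff = 0.075) {
  rec <- scores$records
  rec$gene1 <- pmin(rec$donor_gene, rec$recipient_gene)
  rec$gene2 <- pmax(rec$donor_gene, rec$recipient_gene)
  keyf <- interaction(rec$gene1, rec$gene2, rec$condition, drop = TRUE,
                      sep = "\r")
  groups <- split(seq_len(nrow(rec)), keyf)
  out <- lapply(groups, function(ii) {
    r <- rec[ii, ]
    comb <- combine_barcode_records(r$gis, r$sigma_gis,
                                    extra = r[, c("w_x", "w_y", "w_xy")])
    st <- stouffer_combine(r$p_neutral, sign(r$gis), comb$weights)
    data.frame(gene1 = r$gene1[1], gene2 = r$gene2[1],
               condition = r$condition[1],
               gis = comb$gis, sigma = comb$sigma, z = comb$z,
               w_x = comb$extra[["w_x"]], w_y = comb$extra[["w_y"]],
               w_xy = comb$extra[["w_xy"]],
               p = st$p, n_barcodes = nrow(r),
               same_gene = r$gene1[1] == r$gene2[1],
               linked = all(r$linked), neutral_pair = any(r$neutral_pair),
               degenerate = comb$degenerate)
  })
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  g$q <- NA_real_
  g$call <- NA_character_
  scorable <- !g$same_gene & !g$linked
  for (cond in unique(g$condition)) {
    sel <- g$condition == cond & scorable
    g$q[sel] <- storey_qvalue(g$p[sel])
    g$call[sel] <- call_interaction(g$gis[sel], g$q[sel], q_cutoff,
                                    effect_cutoff)
  }
  attr(g, "q_cutoff") <- q_cutoff
  attr(g, "effect_cutoff") <- effect_cutoff
  g
}
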