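test_that("strain frequencies follow the 0.5-pseudocount arithmetic", {
  f <- strain_frequencies(c(A = 10, B = 0))
  expect_equal(unname(f), c(10.5 / 11, 0.5 / 11))
  expect_equal(sum(f), 1)
  f <- strain_frequencies(c(99, 0, 0))
  expect_equal(f[2], 0.5 / 100.5)
  expect_equal(f[3], 0.5 / 100.5)
  expect_equal(unname(strain_frequencies(rep(7, 5))), rep(0.2, 5))
  expect_error(strain_frequencies(numeric(0)), "empty")
})

test_that("doublings = log2 frequency ratio + generations of pool growth", {
  expect_equal(doublings(0.1, 0.1, 5), 5)
  expect_equal(doublings(0.2, 0.1, 5), 6)
  expect_equal(doublings(0.1 / 32, 0.1, 5), 0)
})

test_that("wild-type doublings are the neutral-neutral mean with sample SD", {
  expect_equal(wildtype_doublings(c(5, 5, 5)), list(g_wt = 5, sigma = 0))
  expect_equal(wildtype_doublings(c(4, 5, 6)), list(g_wt = 5, sigma = 1))
  expect_error(wildtype_doublings(c(5, 5)), ">= 3")
})

test_that("sigma_gis matches the closed-form partials", {
  ## only the global fitness-error term survives
  expect_equal(sigma_gis(0.07, 5, 5, 5, 0, 0, 0), 0.07)
  ## stated partial for the wild-type term: 2 g_x g_y / g_wt^3
  expect_equal(sigma_gis(0, 5, 5, 5, 0, 0, 1), 2 * 25 / 125)
  expect_error(sigma_gis(0.1, 5, 5, 0, 0, 0, 0), "g_wt")
})

test_that("neutral null fit is the sample mean and SD", {
  n <- fit_neutral_null(c(-1, 0, 1), min_n = 3)
  expect_equal(n$mu, 0)
  expect_equal(n$sigma, 1)
  expect_error(fit_neutral_null(rep(2, 50)), "identical")
  expect_error(fit_neutral_null(rnorm(10), min_n = 20), ">= 20")
})

test_that("neutral null recovers N(0,1) parameters at n = 1e4", {
  set.seed(123)
  n <- fit_neutral_null(rnorm(1e4))
  expect_lt(abs(n$mu), 0.05)
  expect_lt(abs(n$sigma - 1), 0.05)
})

test_that("two-tailed empirical p behaves at the null centre and tails", {
  null <- list(mu = 0, sigma = 1)
  expect_equal(p_neutral(0, null), 1)
  expect_equal(p_neutral(1.959964, null), 0.05, tolerance = 1e-5)
  expect_equal(p_neutral(-1.959964, null), 0.05, tolerance = 1e-5)
  shifted <- list(mu = 2, sigma = 0.5)
  expect_equal(p_neutral(2, shifted), 1)
})

## independent oracle: plain-loop recomputation of the whole barcode-level
## model on a 5x5 toy pool (2 repair + 3 neutral genes, 2 tech replicates)
test_that("vectorized engine matches a loop-based oracle to 1e-12", {
  genes <- c("A", "B", "N1", "N2", "N3")
  classes <- c("repair", "repair", "neutral", "neutral", "neutral")
  lib <- toy_library(genes, classes)
  set.seed(77)
  mat <- matrix(sample(40:400, 75, replace = TRUE), 25, 3)
  cnt <- toy_counts(mat, lib, gen_pool = 6)
  sc <- score_pool(cnt, lib, cxy_min = 30, min_null = 10)
  rec <- sc$records

  don_gene <- rep(genes, times = 5)
  rec_gene <- rep(genes, each = 5)
  same <- don_gene == rec_gene
  is_neu <- function(g) classes[match(g, genes)] == "neutral"
  nn <- is_neu(don_gene) & is_neu(rec_gene) & !same

  f0 <- (mat[, 1] + 0.5) / sum(mat[, 1] + 0.5)
  g <- matrix(NA_real_, 25, 2)
  for (s in 1:2) {
    f <- (mat[, s + 1] + 0.5) / sum(mat[, s + 1] + 0.5)
    g[, s] <- log2(f / f0) + 6
  }
  gwt_s <- c(mean(g[nn, 1]), mean(g[nn, 2]))
  w <- cbind(g[, 1] / gwt_s[1], g[, 2] / gwt_s[2])
  w_c <- rowMeans(w)
  g_c <- rowMeans(g)
  gwt_c <- mean(gwt_s)
  s_wxy <- median(abs(w[, 1] - w[, 2]))
  s_gwt <- sd(g_c[nn])

  for (p in sample(25, 8)) {
    dpart <- which(don_gene == don_gene[p] & is_neu(rec_gene) & !same)
    rpart <- which(rec_gene == rec_gene[p] & is_neu(don_gene) & !same)
    g_x <- mean(g_c[dpart]); s_gx <- sd(g_c[dpart])
    g_y <- mean(g_c[rpart]); s_gy <- sd(g_c[rpart])
    w_x <- g_x / gwt_c; w_y <- g_y / gwt_c
    gis <- max(w_c[p], 0) - max(w_x, 0) * max(w_y, 0)
    sg <- sqrt(s_wxy^2 + (g_y / gwt_c^2)^2 * s_gx^2 +
                 (g_x / gwt_c^2)^2 * s_gy^2 +
                 (2 * g_x * g_y / gwt_c^3)^2 * s_gwt^2)
    row <- rec[rec$pair_id == cnt$pairs$pair_id[p], ]
    expect_equal(row$w_x, w_x, tolerance = 1e-12)
    expect_equal(row$w_y, w_y, tolerance = 1e-12)
    expect_equal(row$w_xy, w_c[p], tolerance = 1e-12)
    expect_equal(row$gis, gis, tolerance = 1e-12)
    expect_equal(row$sigma_gis, sg, tolerance = 1e-12)
    expect_equal(row$z_gis, gis / sg, tolerance = 1e-12)
  }
})

test_that("doubling all counts leaves well-covered scores nearly unchanged", {
  ## depth invariance holds up to pseudocount effects, so compare pairs
  ## whose counts dominate the pseudocount; fix the coverage mask so both
  ## runs score the identical retained set
  sim <- small_sim(seed = 61, reads = 1e5, conditions = "c1")
  sc1 <- score_pool(sim$counts, sim$library, cxy_min = 1)
  cnt2 <- sim$counts
  cnt2$counts <- cnt2$counts * 2L
  sc2 <- score_pool(cnt2, sim$library, cxy_min = 1)
  m <- match(sc1$records$pair_id, sc2$records$pair_id)
  deep <- apply(sim$counts$counts, 1, min)[match(sc1$records$pair_id,
                                                 rownames(sim$counts$counts))]
  sel <- deep >= 30
  expect_gt(sum(sel), 100)
  expect_lt(max(abs(sc1$records$gis[sel] - sc2$records$gis[m][sel])), 0.02)
})

test_that("delta-method sigma tracks a Monte-Carlo SD within 25%", {
  set.seed(202)
  for (k in 1:5) {
    g_wt <- runif(1, 5, 15)
    g_x <- runif(1, 0.3, 1.2) * g_wt
    g_y <- runif(1, 0.3, 1.2) * g_wt
    s_wxy <- runif(1, 0.01, 0.05)
    s_gx <- runif(1, 0.05, 0.3)
    s_gy <- runif(1, 0.05, 0.3)
    s_gwt <- runif(1, 0.02, 0.2)
    n <- 1e5
    gis_mc <- rnorm(n, 1, s_wxy) -
      (rnorm(n, g_x, s_gx) * rnorm(n, g_y, s_gy)) / rnorm(n, g_wt, s_gwt)^2
    ratio <- sigma_gis(s_wxy, g_x, g_y, g_wt, s_gx, s_gy, s_gwt) / sd(gis_mc)
    expect_gt(ratio, 0.75)
    expect_lt(ratio, 1.25)
  }
})
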