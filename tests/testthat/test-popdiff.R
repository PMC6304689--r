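permissive_markers <- marker_config(min_called = 2, min_maf = 0, max_het = 1)

test_that("fixed differences give theta = 1 exactly", {
  g <- cbind(matrix(2L, 20, 10), matrix(0L, 20, 10))
  panel <- make_toy_panel(g, rep(c("B", "R"), each = 10))
  comp <- site_fst(panel, "B", "R")
  expect_equal(comp$fst, rep(1, 20))
  expect_equal(genomewide_fst(comp), 1)
})

test_that("identical groups show no differentiation on average", {
  set.seed(2)
  p <- runif(400, 0.2, 0.8)
  g <- matrix(rbinom(400 * 40, 2, p), 400, 40)
  panel <- make_toy_panel(g, rep(c("B", "R"), each = 20))
  comp <- site_fst(panel, "B", "R", permissive_markers)
  expect_lt(abs(mean(comp$fst)), 0.02)
})

test_that("components match the independent formula transcription", {
  # direct formula check at stated inputs
  o <- oracle_wc(10, 0.3, 0.2, 8, 0.7, 0.125)
  w <- heteropool:::wc_components(10, 0.3, 0.2, 8, 0.7, 0.125)
  expect_equal(w$a, o$a, tolerance = 1e-12)
  expect_equal(w$b, o$b, tolerance = 1e-12)
  expect_equal(w$c, o$c, tolerance = 1e-12)
  expect_equal(w$d, o$d, tolerance = 1e-12)

  # genotype-level path vs counting + formula oracle
  set.seed(3)
  for (rep in 1:20) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    g <- random_geno(30, na + nb, miss = 0.1)
    panel <- make_toy_panel(g, rep(c("B", "R"), c(na, nb)))
    comp <- site_fst(panel, "B", "R", permissive_markers)
    key <- paste0(comp$chrom, ":", comp$pos)
    for (i in seq_len(nrow(panel$sites))) {
      oa <- oracle_group_stats(g[i, seq_len(na)])
      ob <- oracle_group_stats(g[i, na + seq_len(nb)])
      row <- match(paste0(panel$sites$chrom[i], ":", panel$sites$pos[i]), key)
      if (oa$n < 2 || ob$n < 2) { expect_true(is.na(row)); next }
      o <- oracle_wc(oa$n, oa$p, oa$h, ob$n, ob$p, ob$h)
      expect_equal(comp$a[row], o$a, tolerance = 1e-10)
      expect_equal(comp$d[row], o$d, tolerance = 1e-10)
    }
  }
})

test_that("site_fst is symmetric in the two groups", {
  set.seed(4)
  g <- random_geno(100, 16, miss = 0.1)
  panel <- make_toy_panel(g, rep(c("B", "R"), each = 8))
  c1 <- site_fst(panel, "B", "R")
  c2 <- site_fst(panel, "R", "B")
  expect_equal(c1$a, c2$a)
  expect_equal(c1$d, c2$d)
  expect_equal(c1$fst, c2$fst)
})

test_that("marker requirements exclude under-called and high-het markers", {
  g <- matrix(c(
    2L, 2L, NA, NA, 0L, 0L, 0L, 0L,   # only 2 called in B... fine (>=2)
    2L, NA, NA, NA, 0L, 0L, 0L, 0L,   # 1 called in B -> excluded
    1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L    # het 1 -> excluded at max_het 0.6
  ), 3, 8, byrow = TRUE)
  panel <- make_toy_panel(g, rep(c("B", "R"), each = 4))
  comp <- site_fst(panel, "B", "R", marker_config(min_maf = 0))
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$pos, panel$sites$pos[1])
})

test_that("windowed F_ST is the ratio of sums, not the mean of ratios", {
  comp <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    a = c(0.1, 0.2, -0.05), d = c(0.5, 0.4, 0.3)
  )
  w <- window_fst(comp, window_bp = 1000)
  expect_identical(nrow(w), 1L)
  expect_equal(w$fst, 0.25 / 1.2)
  expect_false(isTRUE(all.equal(w$fst, mean(comp$a / comp$d))))

  # single-marker windows reproduce the site values
  w1 <- window_fst(comp, window_bp = 10)
  expect_identical(nrow(w1), 3L)
  expect_equal(w1$fst, comp$a / comp$d)

  # window assignment is 0-based half-open anchored at 0
  comp2 <- data.table::data.table(chrom = "chr1", pos = c(1000L, 1001L),
                                  a = c(0.1, 0.1), d = c(0.2, 0.2))
  w2 <- window_fst(comp2, window_bp = 1000)
  expect_equal(w2$start, c(0, 1000))
})

test_that("empty windows are reported when chromosome lengths are known", {
  comp <- data.table::data.table(chrom = "chr1", pos = 2500L, a = 0.1, d = 0.2)
  w <- window_fst(comp, window_bp = 1000, chrom_lengths = c(chr1 = 4000))
  expect_identical(nrow(w), 4L)
  expect_identical(w$n_markers, c(0L, 0L, 1L, 0L))
  expect_true(all(is.na(w$fst[c(1, 2, 4)])))
})

test_that("top-window flagging follows the percentile-with-ties rule", {
  w <- data.table::data.table(chrom = "chr1", start = (0:99) * 1000,
                              end = (1:100) * 1000, fst = sample(1:100) / 100)
  f <- top_windows(w, pct = 5)
  expect_identical(sum(f$top), 5L)
  expect_true(all(f$fst[f$top] >= 0.96))

  w$fst <- 0.5
  expect_true(all(top_windows(w, pct = 5)$top))

  set.seed(9)
  w$fst <- rnorm(100)
  w$fst[sample(100, 10)] <- NA
  f <- top_windows(w, pct = 10)
  v <- w$fst
  k <- ceiling(sum(!is.na(v)) * 0.1)
  oracle_set <- order(v, decreasing = TRUE, na.last = TRUE)[seq_len(k)]
  expect_identical(sort(which(f$top)), sort(oracle_set))
})

test_that("LD pruning removes correlated sites and matches all-pairs oracle", {
  set.seed(12)
  g <- random_geno(10, 20, miss = 0)
  g[2, ] <- g[1, ]  # duplicate -> r2 = 1
  keep <- ld_prune(g, r2_max = 0.2, window_sites = 50)
  expect_false(2 %in% keep)
  expect_true(1 %in% keep)

  # orthogonal dosage vectors all retained
  go <- matrix(0L, 3, 6)
  go[1, 1:2] <- 2L; go[2, 3:4] <- 2L; go[3, 5:6] <- 2L
  expect_identical(ld_prune(go, r2_max = 0.5, window_sites = 10), 1:3)

  # greedy all-window oracle on 50 sites
  set.seed(13)
  gbig <- random_geno(50, 15, miss = 0.05)
  x <- gbig
  for (i in 1:50) {
    r <- x[i, ]
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    x[i, ] <- r
  }
  kept <- integer()
  for (i in 1:50) {
    ok <- TRUE
    for (j in kept) {
      r2 <- suppressWarnings(cor(x[i, ], x[j, ])^2)
      if (!is.na(r2) && r2 > 0.2) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  expect_identical(ld_prune(gbig, r2_max = 0.2, window_sites = 100), kept)
})

test_that("PCA matches a dense SVD oracle up to sign", {
  set.seed(14)
  g <- matrix(sample(0:2, 12 * 6, replace = TRUE), 12, 6)
  colnames(g) <- sprintf("s%d", 1:6)
  res <- panel_pca(g, n_components = 3)

  # oracle: standardize independently, svd
  p <- rowMeans(g) / 2
  keep <- p > 0 & p < 1 & apply(g, 1, var) > 0
  xs <- (g[keep, ] - 2 * p[keep]) / sqrt(2 * p[keep] * (1 - p[keep]))
  sv <- svd(t(xs))
  m <- sum(keep)
  for (k in 1:3) {
    expect_equal(abs(res$scores[, k]), abs(sv$u[, k] * sv$d[k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(res$eigenvalues[k], sv$d[k]^2 / m, tolerance = 1e-8)
  }
  expect_true(all(diff(res$eigenvalues) <= 1e-8))
})

test_that("PCA separates planted clusters and maps identical samples together", {
  set.seed(15)
  base <- rbinom(200, 2, 0.5)
  gA <- replicate(6, pmin(2L, base + rbinom(200, 1, 0.05)))
  gB <- replicate(6, pmax(0L, 2L - base + rbinom(200, 1, 0.05)))
  g <- cbind(gA, gA[, 1], gB)  # sample 7 identical to sample 1
  res <- panel_pca(g, n_components = 2)
  expect_equal(res$scores[1, ], res$scores[7, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  cl <- c(rep(1, 7), rep(2, 6))
  pc1 <- res$scores[, 1]
  within <- var(pc1[cl == 1]) + var(pc1[cl == 2])
  between <- (mean(pc1[cl == 1]) - mean(pc1[cl == 2]))^2
  expect_gt(between, within)
})

test_that("candidate-gene search requires keyword, chromosome and high F_ST", {
  wins <- data.table::data.table(
    chrom = c("chr13", "chr13", "chr2"),
    start = c(0, 100000, 0), end = c(100000, 200000, 100000),
    n_markers = 5L, sum_a = 1, sum_d = 2, fst = c(0.25, 0.1, 0.9)
  )
  genes <- data.table::data.table(
    gene_id = c("ppr1", "ppr2", "other", "ppr3"),
    chrom = c("chr13", "chr13", "chr13", "chr2"),
    start = c(50000L, 150000L, 60000L, 10L),
    end = c(52000L, 152000L, 62000L, 2000L),
    keyword = c("Pentatricopeptide repeat", "pentatricopeptide",
                "kinase", "pentatricopeptide")
  )
  hits <- candidate_genes(wins, genes, fst_min = 0.2, chrom = "chr13")
  expect_identical(hits$gene_id, "ppr1")  # ppr2 low fst, ppr3 wrong chrom
  # boundary: fst exactly at the threshold is not "high"
  wins$fst[2] <- 0.2
  expect_identical(candidate_genes(wins, genes, chrom = "chr13")$gene_id, "ppr1")
})

test_that("planted keyword genes in the chr13 block are recovered exactly", {
  cfg <- sim_config(n_opv = 5, n_b = 25, n_r = 20, n_chrom = 13,
                    chrom_length_bp = 2e6, n_sites = 26000, n_genes = 300,
                    ppr_frac = 0, n_ppr_block_genes = 4,
                    introgression_blocks = data.table::data.table(
                      chrom = "chr13", start = 2e5, end = 5e5,
                      carrier_group = "R", ancestry_level = 0.8),
                    seed = 31)
  r <- suppressMessages(generate_genotypes(cfg))
  planted <- r$truth$genes[grepl("pentatricopeptide", keyword), gene_id]
  expect_identical(length(planted), 4L)
  f <- apply_site_filters(r$panel)
  comp <- site_fst(f$panel, "B", "R")
  wins <- window_fst(comp, window_bp = 1e5)
  hits <- candidate_genes(wins, r$truth$genes, fst_min = 0.2,
                          keyword = "pentatricopeptide", chrom = "chr13")
  expect_setequal(hits$gene_id, planted)
})
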