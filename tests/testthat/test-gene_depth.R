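test_that("gene depth from a per-base track averages over the full interval", {
  genes <- data.table::data.table(gene_id = c("g1", "g2", "g3"),
                                  chrom = "chr1",
                                  start = c(1L, 101L, 201L),
                                  end = c(100L, 200L, 300L))
  track <- data.table::data.table(
    chrom = "chr1", pos = 1:200,
    s1 = c(rep(4, 100), rep(2, 50), rep(6, 50))
  )
  gd <- suppressWarnings(compute_gene_depth(track, genes))
  expect_equal(unname(gd$depth[, 1]), c(4, 4, 0))
  expect_warning(compute_gene_depth(track, genes), "no track records")
})

test_that("copy-state boundaries follow the zero / 3x-median rules exactly", {
  genes <- data.table::data.table(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                                  start = (1:5) * 1000L, end = (1:5) * 1000L + 99L)
  samples <- data.table::data.table(sample_id = "s1", group = "B")
  d <- matrix(c(0, 12.1, 12.0, 4, 4), 5, 1)  # median m_s = 4
  st <- classify_copy_state(gene_depth_matrix(genes, samples, d))
  expect_equal(unname(st$median_depth), 4)
  expect_identical(unname(st$state[, 1]),
                   c("absent", "amplified", "present", "present", "present"))

  # median includes zero-depth genes (6, not the zero-excluded 8)
  d2 <- matrix(c(0, 0, 6, 8, 10), 5, 1)
  st2 <- classify_copy_state(gene_depth_matrix(genes, samples, d2))
  expect_equal(unname(st2$median_depth), 6)

  # all-zero median is uninterpretable
  d3 <- matrix(c(0, 0, 0, 0, 1), 5, 1)
  expect_error(classify_copy_state(gene_depth_matrix(genes, samples, d3)),
               "median gene depth")
})

test_that("every gene x sample lands in exactly one state", {
  cfg <- sim_config(n_opv = 3, n_b = 8, n_r = 8, n_chrom = 3,
                    chrom_length_bp = 2e6, n_sites = 50, n_genes = 300,
                    seed = 41)
  r <- suppressMessages(generate_genotypes(cfg))
  gd <- generate_gene_depths(cfg, r$truth)
  st <- classify_copy_state(gd$depths)
  tab <- table(st$state)
  expect_identical(sum(tab), length(st$state))
  expect_true(all(names(tab) %in% c("absent", "present", "amplified")))
  # absent <=> zero depth
  expect_identical(st$state == "absent", gd$depths$depth == 0)
})

test_that("PAV summaries match a brute-force counting oracle", {
  set.seed(42)
  ab <- matrix(runif(50 * 20) < 0.15, 50, 20)
  am <- matrix(runif(50 * 20) < 0.05, 50, 20) & !ab
  st <- make_states(ab, rep(c("B", "R"), each = 10), amplified = am)
  s <- pav_summaries(st)
  for (j in 1:20) {
    expect_identical(s$per_sample$n_absent[j], sum(ab[, j]))
    expect_identical(s$per_sample$n_amplified[j], sum(am[, j]))
  }
  for (i in 1:50) {
    expect_identical(s$per_gene$n_absent[i], sum(ab[i, ]))
  }
  expect_setequal(s$sets$absent_any, st$genes$gene_id[rowSums(ab) >= 1])
  expect_setequal(s$sets$absent_multi, st$genes$gene_id[rowSums(ab) > 1])
  # a gene absent everywhere lands in the absent-in-all set
  ab2 <- ab; ab2[7, ] <- TRUE
  s2 <- pav_summaries(make_states(ab2, rep(c("B", "R"), each = 10)))
  expect_true("g007" %in% s2$sets$absent_all)
})

test_that("group PAV frequencies and deltas follow the sign convention", {
  ab <- matrix(FALSE, 3, 10)
  ab[1, 6:10] <- TRUE   # absent in all R, no B
  st <- make_states(ab, rep(c("B", "R"), each = 5))
  gp <- group_pav_freq(st)
  expect_equal(gp$delta_absent, c(-1, 0, 0))
  expect_equal(gp$absent_R, c(1, 0, 0))

  set.seed(43)
  ab2 <- matrix(runif(40 * 12) < 0.3, 40, 12)
  st2 <- make_states(ab2, rep(c("B", "R"), each = 6))
  gp2 <- group_pav_freq(st2)
  for (i in 1:40) {
    expect_equal(gp2$delta_absent[i],
                 mean(ab2[i, 1:6]) - mean(ab2[i, 7:12]))
  }
})

test_that("top-differentiated flagging mirrors the sort oracle", {
  set.seed(44)
  ab <- matrix(runif(200 * 10) < 0.2, 200, 10)
  st <- make_states(ab, rep(c("B", "R"), each = 5))
  gp <- group_pav_freq(st)
  td <- top_differentiated(gp, pct = 5)
  v <- abs(gp$delta_absent)
  k <- ceiling(200 * 0.05)
  cutoff <- sort(v, decreasing = TRUE)[k]
  expect_identical(td$top, v >= cutoff)
  expect_gte(sum(td$top), k)  # ties all flagged
  gp0 <- data.table::copy(gp)[, delta_absent := 0.5]
  expect_true(all(top_differentiated(gp0, pct = 1)$top))
})

test_that("permutation test matches exact enumeration on 3+3 samples", {
  set.seed(45)
  ab <- matrix(runif(4 * 6) < 0.5, 4, 6)
  st <- make_states(ab, rep(c("B", "R"), each = 3))
  thr <- 0.5

  # observed statistic equals the identity-permutation statistic
  f_b <- rowMeans(ab[, 1:3]); f_r <- rowMeans(ab[, 4:6])
  obs_oracle <- sum(abs(f_b - f_r) >= thr)
  res <- permutation_differentiation_test(st, diff_threshold = thr,
                                          n_perm = 4000, seed = 1)
  expect_identical(res$absent$observed, obs_oracle)

  # exact null: all 20 assignments of 3 labels among 6 samples
  combos <- combn(6, 3)
  null_exact <- apply(combos, 2, function(idx) {
    sum(abs(rowMeans(ab[, idx, drop = FALSE]) -
              rowMeans(ab[, -idx, drop = FALSE])) >= thr)
  })
  p_exact <- mean(null_exact >= obs_oracle)
  expect_lt(abs(res$absent$p_value - p_exact), 0.04)
})

test_that("planted pool-specific deletions exceed every permutation", {
  set.seed(46)
  ng <- 300
  ab <- matrix(runif(ng * 40) < 0.05, ng, 40)
  diff_genes <- 1:30
  ab[diff_genes, 21:40] <- matrix(runif(30 * 20) < 0.6, 30, 20)
  st <- make_states(ab, rep(c("B", "R"), each = 20))
  res <- permutation_differentiation_test(st, diff_threshold = 0.3,
                                          n_perm = 199, seed = 2)
  expect_gt(res$absent$observed, max(res$absent$null_counts))
  expect_equal(res$absent$p_value, 1 / 200)
})

test_that("nested depth regression matches the normal-equations oracle", {
  set.seed(47)
  depth <- c(2, 3, 4, 5, 6, 7, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5)
  grp <- rep(c("B", "R"), each = 6)
  y <- round(100 - 8 * depth + c(rep(0, 6), rep(12, 6)) + rnorm(12, 0, 3))
  reg <- depth_absence_regression(
    data.frame(median_depth = depth, group = grp, n_absent = y))

  # oracle: explicit least squares via solve(X'X) X'y
  X2 <- cbind(1, depth, grp == "R")
  b2 <- solve(t(X2) %*% X2, t(X2) %*% y)
  expect_equal(unname(reg$coefficients), as.numeric(b2), tolerance = 1e-10)
  rss <- function(X) sum((y - X %*% solve(t(X) %*% X, t(X) %*% y))^2)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- rss(cbind(1, depth)); rss2 <- rss(X2)
  f_depth <- (rss0 - rss1) / 1 / (rss2 / (12 - 3))
  f_group <- (rss1 - rss2) / 1 / (rss2 / (12 - 3))
  expect_equal(reg$anova$f, c(f_depth, f_group), tolerance = 1e-10)
  expect_equal(reg$r2[["depth_group"]], 1 - rss2 / rss0, tolerance = 1e-10)
  expect_true(all(reg$group_slopes$slope < 0))
})

test_that("degenerate regressions are reported, not computed", {
  ps <- data.frame(median_depth = c(1, 2, 3, 4, 5, 6),
                   group = rep(c("B", "R"), each = 3), n_absent = 7)
  reg <- depth_absence_regression(ps)
  expect_true(all(is.na(reg$anova$f)))
  expect_equal(unname(reg$r2), c(0, 0, 0))

  ps2 <- transform(ps, n_absent = 2 * median_depth + 1)
  reg2 <- depth_absence_regression(ps2)
  expect_equal(reg2$r2[["depth"]], 1)
  # perfect linear fit: the group term explains (numerically) nothing
  expect_lt(abs(reg2$anova$sum_sq[2]), 1e-20)
})

test_that("length bias statistic and p match rank-sum oracles", {
  # identical length distributions: z near 0
  ab <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), 20, 1)
  lens <- as.integer(rep(c(100, 200, 300, 400, 500), 4))
  st <- make_states(ab, "B", lengths = lens)
  lb <- pav_length_bias(st)
  expect_lt(abs(lb$z), 0.1)

  # complete separation: PAV all shorter -> W = 0
  lens2 <- as.integer(c(1:10 * 10, 1:10 * 10000))
  st2 <- make_states(ab, "B", lengths = lens2)
  lb2 <- pav_length_bias(st2)
  expect_equal(lb2$statistic, 0)
  expect_lt(lb2$median_pav, lb2$median_other)

  # exact p vs enumeration oracle on small tie-free lists
  set.seed(48)
  ab3 <- matrix(c(rep(TRUE, 4), rep(FALSE, 5)), 9, 1)
  lens3 <- as.integer(sample(1000, 9))
  st3 <- make_states(ab3, "B", lengths = lens3)
  lb3 <- pav_length_bias(st3)
  o <- oracle_ranksum_exact(lens3[1:4], lens3[5:9])
  expect_equal(lb3$statistic, o$u)
  expect_equal(lb3$p_value, o$p, tolerance = 1e-10)

  # one empty class: warning, no test
  ab4 <- matrix(TRUE, 5, 1)
  expect_warning(lb4 <- pav_length_bias(make_states(ab4, "B")), "empty")
  expect_true(is.na(lb4$p_value))
})

test_that("PAV PCA separates planted absence structure", {
  set.seed(49)
  ab <- matrix(runif(100 * 12) < 0.05, 100, 12)
  ab[1:30, 7:12] <- matrix(runif(30 * 6) < 0.7, 30, 6)
  st <- make_states(ab, rep(c("B", "R"), each = 6))
  res <- pav_pca(st, n_components = 2)
  pc1 <- res$scores[, 1]
  expect_gt((mean(pc1[1:6]) - mean(pc1[7:12]))^2,
            var(pc1[1:6]) + var(pc1[7:12]))

  # identical samples get identical scores
  ab2 <- cbind(ab, ab[, 1])
  st2 <- make_states(ab2, c(rep(c("B", "R"), each = 6), "B"))
  r2 <- pav_pca(st2, n_components = 2)
  expect_equal(r2$scores[1, ], r2$scores[13, ], tolerance = 1e-8,
               ignore_attr = TRUE)

  # mean-centred eigen oracle
  x <- t(ab * 1)
  x <- x[, apply(x, 2, var) > 0]
  xs <- sweep(x, 2, colMeans(x))
  sv <- svd(xs)
  expect_equal(abs(res$scores[, 1]), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})
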