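# Independent oracles, written before the implementation paths they check.
# They deliberately share no code with R/: scalar loops, textbook formulas.

# Weir & Cockerham (1984) two-population diploid estimator, transcribed
# independently from the published equations (scalar form).
oracle_wc <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  ssq <- sum(c(n1, n2)^2)
  nc <- (r * nbar - ssq / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, d = a + b + cc,
       theta = if ((a + b + cc) != 0) a / (a + b + cc) else NA_real_)
}

# brute-force per-group allele counting from a dosage matrix slice
oracle_group_stats <- function(geno_rows) {
  n <- 0L; alt <- 0L; het <- 0L
  for (g in geno_rows) {
    if (is.na(g)) next
    n <- n + 1L
    alt <- alt + g
    if (g == 1L) het <- het + 1L
  }
  list(n = n, p = if (n > 0) alt / (2 * n) else NA_real_,
       h = if (n > 0) het / n else NA_real_)
}

# textbook Pearson chi-squared on a 2x2 table
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# brute-force Mann-Whitney U (count of x > y pairs, ties half) and the
# matching rank-sum W; exact two-sided p by enumeration over all
# reassignments of the pooled values
oracle_ranksum_exact <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    uu <- 0
    for (xi in xs) for (yi in ys) uu <- uu + (xi > yi) + 0.5 * (xi == yi)
    uu
  })
  p <- 2 * min(mean(us <= u), mean(us >= u))
  list(u = u, p = min(1, p))
}

# small hand-built panel: geno is a sites x samples dosage matrix
make_toy_panel <- function(geno, groups, chrom = NULL, pos = NULL,
                           qual = NULL, depth = NULL, extra_site_cols = list()) {
  ns <- nrow(geno)
  sites <- data.table::data.table(
    chrom = if (is.null(chrom)) rep("chr1", ns) else chrom,
    pos = if (is.null(pos)) seq_len(ns) * 100L else pos,
    ref = rep("A", ns), alt = rep("C", ns),
    qual = if (is.null(qual)) rep(100, ns) else qual,
    is_snp = rep(TRUE, ns), n_alt = rep(1L, ns)
  )
  for (nm in names(extra_site_cols)) sites[[nm]] <- extra_site_cols[[nm]]
  samples <- data.table::data.table(
    sample_id = sprintf("s%02d", seq_len(ncol(geno))), group = groups
  )
  genotype_panel(sites, samples, geno, depth)
}

# random dosage matrix with missingness
random_geno <- function(n_sites, n_samples, miss = 0.1) {
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  g[matrix(runif(n_sites * n_samples) < miss, n_sites, n_samples)] <- NA_integer_
  g
}

# small copy-state matrix built directly from a logical absence matrix
make_states <- function(absent, groups, amplified = NULL, lengths = NULL) {
  ng <- nrow(absent); ns <- ncol(absent)
  st <- matrix("present", ng, ns)
  st[absent] <- "absent"
  if (!is.null(amplified)) st[amplified] <- "amplified"
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", seq_len(ng)), chrom = "chr1",
    start = seq_len(ng) * 1000L, end = seq_len(ng) * 1000L + 499L,
    length = if (is.null(lengths)) rep(500L, ng) else lengths
  )
  samples <- data.table::data.table(
    sample_id = sprintf("s%02d", seq_len(ns)), group = groups
  )
  dimnames(st) <- list(genes$gene_id, samples$sample_id)
  structure(list(genes = genes, samples = samples, state = st,
                 median_depth = stats::setNames(rep(5, ns), samples$sample_id)),
            class = "copy_state_matrix")
}
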