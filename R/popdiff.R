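#' Marker requirements for a pairwise F_ST comparison
#'
#' Markers entering a pairwise comparison must be called in more than one
#' sample per group, have minor allele frequency above `min_maf` and observed
#' heterozygosity below `max_het`. MAF and heterozygosity are computed over
#' the union of the two compared groups by default (`pool = "pair"`), or over
#' the whole panel (`pool = "all"`).
#'
#' @param min_called minimum called samples per group (default 2, i.e.
#'   "more than one").
#' @param min_maf strict lower bound on minor allele frequency.
#' @param max_het strict upper bound on observed heterozygosity.
#' @param pool `"pair"` or `"all"`: samples over which MAF/het are computed.
#' @return A `marker_config` list.
#' @export
marker_config <- function(min_called = 2L, min_maf = 0.05, max_het = 0.6,
                          pool = c("pair", "all")) {
  structure(list(min_called = as.integer(min_called), min_maf = min_maf,
                 max_het = max_het, pool = match.arg(pool)),
            class = "marker_config")
}

#' Per-site Weir-Cockerham F_ST variance components for two groups
#'
#' Computes, for every retained marker, the among-population variance
#' component `a` and the total `d = a + b + c` of the two-population diploid
#' Weir & Cockerham (1984) estimator, from group sample sizes, alt-allele
#' frequencies and observed heterozygote proportions. The per-site estimate
#' is `fst = a / d`; negative values are retained so that windowed
#' ratio-of-sums averaging stays unbiased.
#'
#' @param panel a filtered, biallelic [genotype_panel()].
#' @param group_a,group_b the two pool labels to compare.
#' @param marker_cfg a [marker_config()] of marker requirements; markers
#'   failing them are excluded (not an error).
#' @return `data.table` of class `fst_components`: `chrom`, `pos`, `a`, `b`,
#'   `c`, `d`, `fst`, `n_called_a`, `n_called_b`, with the compared groups in
#'   attribute `groups`.
#' @export
site_fst <- function(panel, group_a, group_b, marker_cfg = marker_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  ja <- group_columns(panel, group_a)
  jb <- group_columns(panel, group_b)
  ga <- panel$geno[, ja, drop = FALSE]
  gb <- panel$geno[, jb, drop = FALSE]
  snp <- panel$sites$is_snp & panel$sites$n_alt == 1L

  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- ifelse(n1 > 0, rowSums(ga, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, rowSums(gb, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, rowSums(ga == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, rowSums(gb == 1L, na.rm = TRUE) / n2, NA_real_)

  pool_idx <- if (marker_cfg$pool == "pair") c(ja, jb) else
    seq_len(ncol(panel$geno))
  gp <- panel$geno[, pool_idx, drop = FALSE]
  np <- rowSums(!is.na(gp))
  pp <- ifelse(np > 0, rowSums(gp, na.rm = TRUE) / (2 * np), NA_real_)
  hetp <- ifelse(np > 0, rowSums(gp == 1L, na.rm = TRUE) / np, NA_real_)
  mafp <- pmin(pp, 1 - pp)

  keep <- snp & n1 >= marker_cfg$min_called & n2 >= marker_cfg$min_called &
    !is.na(mafp) & mafp > marker_cfg$min_maf & hetp < marker_cfg$max_het
  comp <- wc_components(n1[keep], p1[keep], h1[keep],
                        n2[keep], p2[keep], h2[keep])
  out <- data.table(
    chrom = panel$sites$chrom[keep], pos = panel$sites$pos[keep],
    a = comp$a, b = comp$b, c = comp$c, d = comp$d,
    fst = ifelse(comp$d != 0, comp$a / comp$d, NA_real_),
    n_called_a = n1[keep], n_called_b = n2[keep]
  )
  setattr(out, "groups", c(group_a, group_b))
  setattr(out, "class", c("fst_components", class(out)))
  out
}

# Two-population diploid Weir & Cockerham (1984) variance components.
# n_i: called diploids, p_i: alt-allele frequency, h_i: observed
# heterozygote proportion. r = 2 populations.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, d = a + b + c)
}

#' Windowed F_ST by summing variance components
#'
#' Markers are assigned to fixed-width windows anchored at position 0 of each
#' chromosome (0-based half-open); the window estimate is the ratio of sums
#' `sum(a) / sum(d)` over all markers in the window, not the mean of per-site
#' ratios.
#'
#' @param components output of [site_fst()].
#' @param window_bp window width in bp (default 500 kb).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, empty windows are reported with `n_markers = 0` and `fst = NA`.
#' @return `data.table`: `chrom`, `start` (0-based), `end`, `n_markers`,
#'   `sum_a`, `sum_d`, `fst`.
#' @export
window_fst <- function(components, window_bp = 5e5, chrom_lengths = NULL) {
  comp <- as.data.table(components)
  w <- comp[, .(n_markers = .N, sum_a = sum(a), sum_d = sum(d)),
            by = .(chrom, start = floor((pos - 1) / window_bp) * window_bp)]
  w[, end := start + window_bp]
  w[, fst := ifelse(sum_d > 0, sum_a / sum_d, NA_real_)]
  if (!is.null(chrom_lengths)) {
    full <- rbindlist(lapply(names(chrom_lengths), function(cn) {
      st <- seq(0, max(0, chrom_lengths[[cn]] - 1), by = window_bp)
      data.table(chrom = cn, start = st,
                 end = pmin(st + window_bp, chrom_lengths[[cn]]))
    }))
    w <- merge(full, w[, .(chrom, start, n_markers, sum_a, sum_d, fst)],
               by = c("chrom", "start"), all.x = TRUE)
    w[is.na(n_markers), n_markers := 0L]
  }
  setorder(w, chrom, start)
  w[, .(chrom, start, end, n_markers, sum_a, sum_d, fst)]
}

#' Flag the top windows of a windowed scan
#'
#' Flags windows whose value is at or above the `(100 - pct)` percentile of
#' defined windows, i.e. at least the k-th largest value with
#' `k = ceiling(n_defined * pct / 100)`; ties at the cutoff are all flagged.
#'
#' @param windows output of [window_fst()] (or any table with an `fst`
#'   column).
#' @param pct percentage of windows to flag (default 5).
#' @param column column holding the score.
#' @return The input with a logical `top` column added.
#' @export
top_windows <- function(windows, pct = 5, column = "fst") {
  w <- as.data.table(windows)
  v <- w[[column]]
  defined <- !is.na(v)
  if (!any(defined)) stop("no defined windows")
  k <- max(1L, ceiling(sum(defined) * pct / 100))
  cutoff <- sort(v[defined], decreasing = TRUE)[k]
  w[, top := defined & v >= cutoff]
  w[]
}

#' Genome-wide F_ST (ratio of sums over all markers)
#'
#' @param components output of [site_fst()].
#' @return A single number, `sum(a) / sum(d)`.
#' @export
genomewide_fst <- function(components) {
  sum(components$a) / sum(components$d)
}

#' Greedy LD pruning of a dosage panel
#'
#' Left-to-right scan: a site is removed when its squared Pearson correlation
#' of dosages (missing values mean-imputed) with any already-retained site
#' within the trailing `window_sites` sites on the same chromosome exceeds
#' `r2_max`. Output preserves genomic order.
#'
#' @param panel a [genotype_panel()] or a sites x samples dosage matrix.
#' @param r2_max r-squared threshold (default 0.2).
#' @param window_sites size of the trailing comparison window, in sites; use
#'   a value at least the panel size for exhaustive all-pairs pruning.
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_sites = 50L) {
  if (inherits(panel, "genotype_panel")) {
    g <- panel$geno
    chroms <- panel$sites$chrom
  } else {
    g <- as.matrix(panel)
    chroms <- rep("chr0", nrow(g))
  }
  x <- impute_rows(g)
  n <- nrow(x)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    cand <- kept_idx[kept_idx > i - window_sites & chroms[kept_idx] == chroms[i]]
    ok <- TRUE
    if (length(cand) && sd(x[i, ]) > 0) {
      r2 <- suppressWarnings(cor(x[i, ], t(x[cand, , drop = FALSE]))^2)
      r2[is.na(r2)] <- 0
      ok <- all(r2 <= r2_max)
    }
    if (ok) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  which(keep)
}

impute_rows <- function(g) {
  x <- g * 1.0
  rm <- rowMeans(x, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- rm[idx[, 1]]
  x
}

#' Principal component analysis of a dosage panel
#'
#' Sites are optionally randomly subsampled (seeded) and LD-pruned, then
#' standardized per site: mean-centred and, when `standardize = TRUE`,
#' divided by the binomial dosage standard deviation `sqrt(2 p (1-p))` under
#' the site's allele frequency. Missing dosages are mean-imputed and
#' zero-variance sites dropped. Scores are the projections of samples onto
#' the principal axes of the sample covariance matrix; eigenvalues are
#' returned in non-increasing order.
#'
#' @param panel a [genotype_panel()] or a sites x samples numeric matrix.
#' @param n_components number of components to return.
#' @param subsample_frac optional fraction of sites to draw at random before
#'   pruning (the published analysis used ~1%).
#' @param seed RNG seed for the subsample.
#' @param ld_r2 optional r-squared threshold for LD pruning; `NULL` skips.
#' @param window_sites pruning window (see [ld_prune()]).
#' @param standardize scale by the binomial standard deviation (set `FALSE`
#'   for binary indicator matrices such as gene-absence calls).
#' @return A list: `scores` (samples x components), `eigenvalues`
#'   (all sample-covariance eigenvalues, non-increasing), `n_sites_used`,
#'   `sites_used` (indices into the input).
#' @export
panel_pca <- function(panel, n_components = 10L, subsample_frac = NULL,
                      seed = NULL, ld_r2 = NULL, window_sites = 50L,
                      standardize = TRUE) {
  g <- if (inherits(panel, "genotype_panel")) panel$geno else as.matrix(panel)
  ids <- colnames(g)
  if (ncol(g) < 2) stop("need at least 2 samples")
  used <- seq_len(nrow(g))
  if (!is.null(subsample_frac) && subsample_frac < 1) {
    if (!is.null(seed)) set.seed(seed)
    used <- sort(sample(used, max(2, round(length(used) * subsample_frac))))
  }
  sub <- if (inherits(panel, "genotype_panel"))
    subset_panel(panel, sites = used) else g[used, , drop = FALSE]
  if (!is.null(ld_r2)) {
    kept <- ld_prune(sub, r2_max = ld_r2, window_sites = window_sites)
    used <- used[kept]
  }
  x <- impute_rows(g[used, , drop = FALSE])
  mu <- rowMeans(x)
  if (standardize) {
    p <- mu / 2
    sdv <- sqrt(2 * p * (1 - p))
  } else {
    sdv <- rep(1, nrow(x))
  }
  ok <- sdv > 0 & apply(x, 1, function(r) any(r != r[1]))
  x <- (x[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  used <- used[ok]
  m <- nrow(x)
  if (m < 1) stop("no variable sites left for PCA")
  xs <- t(x)  # samples x sites
  K <- tcrossprod(xs) / m
  ev <- eigen(K, symmetric = TRUE)
  k <- min(n_components, ncol(xs) - 1L)
  if (k < n_components)
    warning("fewer usable components than requested; returning ", k)
  vals <- pmax(ev$values, 0)
  scores <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)] * m), k)
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = vals, n_sites_used = m,
       sites_used = used)
}

#' Extract candidate genes in high-F_ST windows
#'
#' Returns genes whose interval overlaps (by at least 1 bp) any window with
#' `fst > fst_min` on the stated chromosome and whose annotation contains
#' the keyword (case-insensitive). With the defaults this is the Rf1-style
#' restorer-locus search: "pentatricopeptide" genes in high-F_ST 100-kb
#' windows on chromosome 13.
#'
#' @param windows a [window_fst()] table, typically recomputed at 100-kb
#'   width.
#' @param genes gene models (`data.table` with `gene_id`, `chrom`, `start`,
#'   `end`, `keyword`).
#' @param fst_min strict lower bound on window F_ST.
#' @param keyword annotation keyword to require.
#' @param chrom chromosome to restrict to; `NULL` searches genome-wide.
#' @return The matching subset of `genes`.
#' @export
candidate_genes <- function(windows, genes, fst_min = 0.2,
                            keyword = "pentatricopeptide", chrom = "chr13") {
  w <- as.data.table(windows)
  # compute selections outside `[` so argument names never collide with
  # column names under data.table scoping
  sel <- !is.na(w[["fst"]]) & w[["fst"]] > fst_min
  if (!is.null(chrom)) sel <- sel & w[["chrom"]] == chrom
  w <- w[which(sel)]
  genes <- as.data.table(genes)
  if (!nrow(w) || !nrow(genes)) return(genes[0])
  kw <- grepl(keyword, genes$keyword, ignore.case = TRUE)
  hit <- overlaps_any(genes$chrom, genes$start, genes$end,
                      w$chrom, w$start + 1L, w$end)
  genes[kw & hit]
}

# 1-based inclusive interval overlap (>= 1 bp) per chromosome.
overlaps_any <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  hit <- logical(length(q_chrom))
  for (cn in unique(s_chrom)) {
    qi <- which(q_chrom == cn)
    si <- which(s_chrom == cn)
    if (!length(qi) || !length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi], q_end[qi]),
      IRanges::IRanges(s_start[si], s_end[si])
    )
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}
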