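#' Gene x sample mean read-depth matrix
#'
#' @param genes `data.table` with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `length`; a `keyword` column is kept if present.
#' @param samples `data.table` with `sample_id` and optionally `group`.
#' @param depth numeric genes x samples matrix of mean per-base depths.
#' @return An object of class `gene_depth_matrix`.
#' @export
gene_depth_matrix <- function(genes, samples, depth) {
  genes <- as.data.table(genes)
  samples <- as.data.table(samples)
  depth <- as.matrix(depth)
  if (!"length" %in% names(genes) && all(c("start", "end") %in% names(genes)))
    genes[, length := end - start + 1L]
  stopifnot("gene_id" %in% names(genes), "sample_id" %in% names(samples))
  if (nrow(depth) != nrow(genes) || ncol(depth) != nrow(samples))
    stop("depth must be n_genes x n_samples")
  if (any(depth < 0)) stop("depths must be non-negative")
  dimnames(depth) <- list(genes$gene_id, samples$sample_id)
  structure(list(genes = genes, samples = samples, depth = depth),
            class = "gene_depth_matrix")
}

#' @export
print.gene_depth_matrix <- function(x, ...) {
  cat(sprintf("gene_depth_matrix: %d genes x %d samples\n",
              nrow(x$genes), nrow(x$samples)))
  invisible(x)
}

#' Mean per-base gene depth from a per-base depth track
#'
#' Computes, for each gene and sample, the average per-base read depth over
#' the full gene interval: positions absent from the track count as depth 0,
#' and mapping quality is deliberately not considered. The track is a
#' long-format table of covered positions with one depth column per sample
#' (as produced by `samtools depth`).
#'
#' @param track `data.table`/`data.frame` with columns `chrom`, `pos`
#'   (1-based) and one numeric depth column per sample.
#' @param genes gene models (`gene_id`, `chrom`, `start`, `end`).
#' @param samples optional sample table; defaults to the track's depth
#'   column names.
#' @return A [gene_depth_matrix()].
#' @export
compute_gene_depth <- function(track, genes, samples = NULL) {
  track <- as.data.table(track)
  genes <- as.data.table(genes)
  sample_ids <- setdiff(names(track), c("chrom", "pos"))
  if (!length(sample_ids)) stop("track has no depth columns")
  if (is.null(samples)) samples <- data.table(sample_id = sample_ids)
  dep <- matrix(0, nrow(genes), length(sample_ids))
  for (i in seq_len(nrow(genes))) {
    sel <- track$chrom == genes$chrom[i] &
      track$pos >= genes$start[i] & track$pos <= genes$end[i]
    len <- genes$end[i] - genes$start[i] + 1L
    if (any(sel)) {
      dep[i, ] <- colSums(as.matrix(track[sel, ..sample_ids])) / len
    } else {
      warning("gene ", genes$gene_id[i], " has no track records; depth 0")
    }
  }
  gene_depth_matrix(genes, samples, dep)
}

#' Three-state copy classification from gene depths
#'
#' For each sample the median gene depth `m_s` is taken over all genes
#' (zero-depth genes included), and each gene is classified as `absent`
#' (depth exactly 0), `amplified` (depth strictly greater than `3 m_s`) or
#' `present` (positive depth at or below `3 m_s`).
#'
#' @param depths a [gene_depth_matrix()].
#' @param amp_factor multiple of the sample median defining amplification.
#' @return An object of class `copy_state_matrix`: the gene and sample
#'   tables, a character `state` matrix and the per-sample `median_depth`
#'   used for classification.
#' @export
classify_copy_state <- function(depths, amp_factor = 3) {
  stopifnot(inherits(depths, "gene_depth_matrix"))
  m_s <- apply(depths$depth, 2, median)
  if (any(m_s <= 0)) {
    stop("sample(s) with non-positive median gene depth: ",
         paste(depths$samples$sample_id[m_s <= 0], collapse = ", "))
  }
  d <- depths$depth
  state <- matrix("present", nrow(d), ncol(d), dimnames = dimnames(d))
  state[d == 0] <- "absent"
  state[d > rep(amp_factor * m_s, each = nrow(d))] <- "amplified"
  structure(list(genes = depths$genes, samples = depths$samples,
                 state = state, median_depth = setNames(m_s, colnames(d))),
            class = "copy_state_matrix")
}

#' @export
print.copy_state_matrix <- function(x, ...) {
  tab <- table(x$state)
  cat(sprintf("copy_state_matrix: %d genes x %d samples (%s)\n",
              nrow(x$genes), nrow(x$samples),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Presence/absence and amplification summaries
#'
#' @param states a [classify_copy_state()] result.
#' @return A list: `per_sample` (`sample_id`, `n_absent`, `n_amplified`),
#'   `per_gene` (`gene_id`, `n_absent`, `n_amplified`), and `sets` of gene
#'   ids — absent in >= 1 sample, absent in > 1 sample, absent in all,
#'   amplified in >= 1, amplified in all.
#' @export
pav_summaries <- function(states) {
  stopifnot(inherits(states, "copy_state_matrix"))
  ab <- states$state == "absent"
  am <- states$state == "amplified"
  per_sample <- data.table(
    sample_id = states$samples$sample_id,
    group = if ("group" %in% names(states$samples)) states$samples$group else NA,
    n_absent = as.integer(colSums(ab)), n_amplified = as.integer(colSums(am))
  )
  per_gene <- data.table(
    gene_id = states$genes$gene_id,
    n_absent = as.integer(rowSums(ab)), n_amplified = as.integer(rowSums(am))
  )
  ns <- ncol(ab)
  sets <- list(
    absent_any = per_gene$gene_id[per_gene$n_absent >= 1],
    absent_multi = per_gene$gene_id[per_gene$n_absent > 1],
    absent_all = per_gene$gene_id[per_gene$n_absent == ns],
    amplified_any = per_gene$gene_id[per_gene$n_amplified >= 1],
    amplified_all = per_gene$gene_id[per_gene$n_amplified == ns]
  )
  list(per_sample = per_sample, per_gene = per_gene, sets = sets)
}

#' Per-pool absence/amplification frequencies and their difference
#'
#' For each gene, the within-pool frequencies of absent and amplified calls,
#' and the maintainer-minus-restorer differences
#' `delta_absent = freq_absent_B - freq_absent_R` (positive means more often
#' absent in B lines).
#'
#' @param states a [classify_copy_state()] result whose sample table carries
#'   a `group` column.
#' @param groups the two pools to difference (default B and R).
#' @return `data.table` with per-group frequencies and `delta_absent`,
#'   `delta_amplified`.
#' @export
group_pav_freq <- function(states, groups = c("B", "R")) {
  stopifnot(inherits(states, "copy_state_matrix"))
  gl <- states$samples$group
  out <- data.table(gene_id = states$genes$gene_id,
                    chrom = states$genes$chrom,
                    start = states$genes$start, end = states$genes$end)
  for (g in unique(gl)) {
    j <- which(gl == g)
    out[[paste0("absent_", g)]] <- rowMeans(states$state[, j, drop = FALSE] == "absent")
    out[[paste0("amplified_", g)]] <- rowMeans(states$state[, j, drop = FALSE] == "amplified")
  }
  for (g in groups) if (!any(gl == g)) stop("empty group: ", g)
  out$delta_absent <- out[[paste0("absent_", groups[1])]] -
    out[[paste0("absent_", groups[2])]]
  out$delta_amplified <- out[[paste0("amplified_", groups[1])]] -
    out[[paste0("amplified_", groups[2])]]
  out
}

#' Flag the most pool-differentiated genes
#'
#' Flags genes whose |delta| is at or above the `(100 - pct)` percentile
#' (k-th largest with `k = ceiling(n * pct / 100)`); ties all flagged.
#'
#' @param pav a [group_pav_freq()] table.
#' @param pct percentage to flag (default 1).
#' @param what `"absent"` or `"amplified"`.
#' @return The input with a logical `top` column.
#' @export
top_differentiated <- function(pav, pct = 1, what = c("absent", "amplified")) {
  what <- match.arg(what)
  pav <- as.data.table(pav)
  v <- abs(pav[[paste0("delta_", what)]])
  k <- max(1L, ceiling(sum(!is.na(v)) * pct / 100))
  cutoff <- sort(v, decreasing = TRUE)[k]
  pav[, top := !is.na(v) & v >= cutoff]
  pav[]
}

#' Permutation test of pool differentiation in gene content
#'
#' The observed statistic is the number of genes whose absence (and,
#' separately, amplification) frequency differs between the two pools by at
#' least `diff_threshold`. The null is built by permuting pool labels over
#' samples (pool sizes preserved) and recomputing the statistic; the p-value
#' uses the add-one estimator `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param states a [classify_copy_state()] result.
#' @param groups the two pools compared (default B vs R).
#' @param diff_threshold minimum absolute frequency difference counted
#'   (default 0.2).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return A list with one element per state type (`absent`, `amplified`):
#'   `observed`, `null_counts` (length `n_perm`), `p_value`.
#' @export
permutation_differentiation_test <- function(states, groups = c("B", "R"),
                                             diff_threshold = 0.2,
                                             n_perm = 999L, seed = 1L) {
  stopifnot(inherits(states, "copy_state_matrix"),
            diff_threshold > 0, diff_threshold <= 1, n_perm >= 1)
  gl <- states$samples$group
  sel <- which(gl %in% groups)
  if (!length(sel)) stop("no samples in the requested groups")
  lab <- gl[sel]
  n1 <- sum(lab == groups[1]); n2 <- sum(lab == groups[2])
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample(length(sel)),
                  integer(length(sel)))
  res <- list()
  for (what in c("absent", "amplified")) {
    A <- (states$state[, sel, drop = FALSE] == what) * 1
    count_stat <- function(ord) {
      f1 <- rowMeans(A[, ord[seq_len(n1)], drop = FALSE])
      f2 <- rowMeans(A[, ord[n1 + seq_len(n2)], drop = FALSE])
      as.integer(sum(abs(f1 - f2) >= diff_threshold))
    }
    obs_ord <- c(which(lab == groups[1]), which(lab == groups[2]))
    observed <- count_stat(obs_ord)
    null_counts <- apply(perms, 2, count_stat)
    res[[what]] <- list(
      observed = observed, null_counts = null_counts,
      p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1)
    )
  }
  res$diff_threshold <- diff_threshold
  res$groups <- groups
  res
}

#' Nested regression of absent-gene counts on depth and pool
#'
#' Fits, by ordinary least squares, the nested models
#' `n_absent ~ 1`, `~ median_depth`, `~ median_depth + group` (no
#' interaction) and reports the sequential F statistics, degrees of freedom,
#' p-values and R-squared, plus per-group slopes of `n_absent` on depth.
#'
#' @param per_sample `data.frame` with columns `median_depth`, `group` and
#'   `n_absent` (one row per sample), e.g. built from
#'   [classify_copy_state()] and [pav_summaries()].
#' @return A list: `anova` (`data.table` of model comparisons), `r2`
#'   (named vector per model), `group_slopes` (`data.table`), and the full
#'   model coefficients.
#' @export
depth_absence_regression <- function(per_sample) {
  ps <- as.data.table(per_sample)
  stopifnot(all(c("median_depth", "group", "n_absent") %in% names(ps)))
  if (length(unique(ps$group)) < 2) stop("need >= 2 groups")
  ps$group <- factor(ps$group)
  m0 <- lm(n_absent ~ 1, data = ps)
  m1 <- lm(n_absent ~ median_depth, data = ps)
  m2 <- lm(n_absent ~ median_depth + group, data = ps)
  constant_y <- var(ps$n_absent) == 0
  av <- anova(m0, m1, m2)
  tab <- data.table(
    term = c("median_depth", "group"),
    df = av$Df[-1], sum_sq = av$`Sum of Sq`[-1],
    f = av$F[-1], p = av$`Pr(>F)`[-1]
  )
  if (constant_y) {
    tab[, `:=`(f = NA_real_, p = NA_real_)]
    tab[, note := "response is constant; F undefined"]
  }
  r2 <- function(m) if (constant_y) 0 else
    suppressWarnings(summary(m)$r.squared)
  slopes <- ps[, {
    if (.N >= 2 && var(median_depth) > 0) {
      cf <- coef(lm(n_absent ~ median_depth, data = .SD))
      .(intercept = cf[1], slope = cf[2])
    } else .(intercept = NA_real_, slope = NA_real_)
  }, by = group]
  list(anova = tab, r2 = c(null = 0, depth = r2(m1), depth_group = r2(m2)),
       group_slopes = slopes, coefficients = coef(m2))
}

#' Gene-length bias of presence/absence variation
#'
#' Compares the length distributions of PAV genes (absent in at least one
#' sample) and non-PAV genes: class medians, a Wilcoxon rank-sum test (exact
#' for small tie-free samples, otherwise the tie-corrected normal
#' approximation without continuity correction), and length deciles per
#' class.
#'
#' @param states a [classify_copy_state()] result.
#' @param genes gene models with a `length` column; defaults to the ones in
#'   `states`.
#' @return A list: `n_pav`, `n_other`, `median_pav`, `median_other`,
#'   `statistic` (rank-sum W), `z`, `p_value`, `deciles` (`data.table`).
#' @export
pav_length_bias <- function(states, genes = states$genes) {
  stopifnot(inherits(states, "copy_state_matrix"))
  genes <- as.data.table(genes)
  pav <- rowSums(states$state == "absent") >= 1
  len_pav <- genes$length[pav]
  len_other <- genes$length[!pav]
  dq <- seq(0, 1, by = 0.1)
  res <- list(
    n_pav = length(len_pav), n_other = length(len_other),
    median_pav = median(len_pav), median_other = median(len_other),
    statistic = NA_real_, z = NA_real_, p_value = NA_real_,
    deciles = data.table(
      decile = dq,
      pav = if (length(len_pav)) quantile(len_pav, dq) else NA_real_,
      other = if (length(len_other)) quantile(len_other, dq) else NA_real_
    )
  )
  if (!length(len_pav) || !length(len_other)) {
    warning("one length class is empty; no rank-sum test")
    return(res)
  }
  ties <- anyDuplicated(c(len_pav, len_other)) > 0
  exact <- !ties && length(len_pav) < 50 && length(len_other) < 50
  wt <- suppressWarnings(
    stats::wilcox.test(len_pav, len_other, exact = exact, correct = FALSE)
  )
  res$statistic <- unname(wt$statistic)
  res$p_value <- wt$p.value
  # normal-approximation z for the reported W
  n1 <- length(len_pav); n2 <- length(len_other)
  mu <- n1 * n2 / 2
  r <- rank(c(len_pav, len_other))
  tie_tab <- table(r)
  sig <- sqrt(n1 * n2 / 12 *
                ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
                   ((n1 + n2) * (n1 + n2 - 1))))
  res$z <- if (sig > 0) (res$statistic - mu) / sig else NA_real_
  res
}

#' PCA on gene-absence indicators
#'
#' Encodes the state matrix as absence indicators (absent = 1, else 0) and
#' runs a mean-centred (not variance-standardized) PCA over genes; see
#' [panel_pca()].
#'
#' @param states a [classify_copy_state()] result.
#' @param n_components number of components.
#' @return As [panel_pca()].
#' @export
pav_pca <- function(states, n_components = 10L) {
  stopifnot(inherits(states, "copy_state_matrix"))
  ind <- (states$state == "absent") * 1
  panel_pca(ind, n_components = n_components, standardize = FALSE)
}
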