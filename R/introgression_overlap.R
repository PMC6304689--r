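#' Per-gene introgression value from a windowed ancestry track
#'
#' Each gene receives the maximum non-landrace ancestry proportion over all
#' track windows overlapping it by at least 1 bp. Genes overlapping no
#' window get value 0 and are flagged.
#'
#' @param track ancestry track (`chrom`, `start`, `end` 0-based half-open,
#'   `ancestry` in [0,1]), e.g. from [read_ancestry_track()] or
#'   [build_ancestry_track()].
#' @param genes gene models (`gene_id`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @return `data.table` with `gene_id`, `value`, `no_window`.
#' @export
gene_introgression_value <- function(track, genes) {
  track <- as.data.table(track)
  genes <- as.data.table(genes)
  if (any(track$ancestry < 0 | track$ancestry > 1))
    stop("ancestry proportions must lie in [0,1]")
  value <- numeric(nrow(genes))
  seen <- logical(nrow(genes))
  for (cn in unique(track$chrom)) {
    qi <- which(genes$chrom == cn)
    si <- which(track$chrom == cn)
    if (!length(qi) || !length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$start[qi], genes$end[qi]),
      IRanges::IRanges(track$start[si] + 1L, track$end[si])
    )
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    anc <- track$ancestry[si][S4Vectors::subjectHits(ov)]
    mx <- tapply(anc, qh, max)
    idx <- qi[as.integer(names(mx))]
    value[idx] <- pmax(value[idx], as.numeric(mx))
    seen[idx] <- TRUE
  }
  data.table(gene_id = genes$gene_id, value = value, no_window = !seen)
}

#' Classify genes as introgressed
#'
#' A gene is introgressed when its introgression value is strictly greater
#' than the threshold (default 0.1 non-landrace ancestry).
#'
#' @param values numeric vector of per-gene introgression values, or the
#'   table from [gene_introgression_value()].
#' @param threshold strict lower bound.
#' @return Logical vector.
#' @export
classify_introgressed <- function(values, threshold = 0.1) {
  v <- if (is.data.frame(values)) values$value else values
  v > threshold
}

#' Enrichment of gene absence inside introgressed regions
#'
#' Builds the 2x2 table of {absent, not absent} x {introgressed, not} for a
#' focal sample, reports the within-class absence percentages and their
#' ratio, and tests independence with a Pearson chi-squared test (1 df,
#' without continuity correction by default). A zero row or column margin
#' yields the table without a test.
#'
#' @param absent logical per gene: absent in the focal sample.
#' @param introgressed logical per gene, e.g. from
#'   [classify_introgressed()].
#' @param correct apply the Yates continuity correction.
#' @return A list: `table` (2x2), `prop_absent_in`, `prop_absent_out`,
#'   `ratio`, `chi2`, `df`, `p_value`, `note`.
#' @export
absence_enrichment <- function(absent, introgressed, correct = FALSE) {
  stopifnot(length(absent) == length(introgressed))
  absent <- as.logical(absent)
  introgressed <- as.logical(introgressed)
  tab <- matrix(c(
    sum(absent & introgressed), sum(absent & !introgressed),
    sum(!absent & introgressed), sum(!absent & !introgressed)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("absent", "present"), c("introgressed", "outside")))
  n_in <- sum(tab[, 1]); n_out <- sum(tab[, 2])
  prop_in <- if (n_in > 0) tab[1, 1] / n_in else NA_real_
  prop_out <- if (n_out > 0) tab[1, 2] / n_out else NA_real_
  res <- list(table = tab, prop_absent_in = prop_in,
              prop_absent_out = prop_out,
              ratio = prop_in / prop_out,
              chi2 = NA_real_, df = 1L, p_value = NA_real_, note = NULL)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res$note <- "degenerate margin: no test performed"
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  res$chi2 <- unname(ct$statistic)
  res$df <- unname(ct$parameter)
  res$p_value <- ct$p.value
  res
}
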