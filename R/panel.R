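#' Genotype panel container
#'
#' A `genotype_panel` bundles a multi-sample SNP panel: per-site records,
#' per-sample metadata (including the breeding-pool label), an alt-allele
#' dosage matrix and an optional per-genotype depth matrix.
#'
#' @param sites `data.table` with one row per site. Required columns:
#'   `chrom`, `pos` (1-based), `ref`, `alt` (comma-separated if multiple),
#'   `qual`, `is_snp` (logical), `n_alt` (number of ALT alleles). Optional
#'   INFO columns: `sar`, `saf`, `rpl`, `rpr`.
#' @param samples `data.table` with columns `sample_id` and `group`; group
#'   labels must be one of `"OPV"`, `"B"`, `"R"`.
#' @param geno integer matrix, sites x samples, of alt-allele dosages
#'   (0, 1, 2 or `NA` for missing / non-biallelic records).
#' @param depth optional integer matrix of per-genotype read depths, same
#'   dimensions as `geno`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, samples, geno, depth = NULL) {
  sites <- as.data.table(sites)
  samples <- as.data.table(samples)
  req <- c("chrom", "pos", "ref", "alt", "qual", "is_snp", "n_alt")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples needs columns sample_id and group")
  bad <- setdiff(unique(samples$group), c("OPV", "B", "R"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples))
    stop("geno must be n_sites x n_samples")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(geno))) stop("depth dimensions must match geno")
  }
  rng <- suppressWarnings(range(geno, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in {0,1,2} or be NA")
  # positions strictly increasing within chromosome
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
  }
  if (any(sites[, diff(pos) <= 0, by = chrom]$V1))
    stop("duplicate positions within a chromosome")
  colnames(geno) <- samples$sample_id
  if (!is.null(depth)) colnames(depth) <- samples$sample_id
  structure(
    list(sites = sites, samples = samples, geno = geno, depth = depth),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d sites x %d samples (%s)\n",
    nrow(x$sites), nrow(x$samples),
    paste(sprintf("%s=%d", names(table(x$samples$group)),
                  as.integer(table(x$samples$group))), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a panel by site index and/or sample id
#'
#' @param panel a [genotype_panel()].
#' @param sites integer or logical index over sites.
#' @param samples character vector of sample ids, or index into the sample
#'   table.
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(sites)) seq_len(nrow(panel$sites)) else sites
  pj <- if (is.null(samples)) seq_len(nrow(panel$samples)) else {
    if (is.character(samples)) match(samples, panel$samples$sample_id) else samples
  }
  if (anyNA(pj)) stop("unknown sample id(s)")
  genotype_panel(
    panel$sites[si], panel$samples[pj],
    panel$geno[si, pj, drop = FALSE],
    if (!is.null(panel$depth)) panel$depth[si, pj, drop = FALSE]
  )
}

group_columns <- function(panel, group) {
  idx <- which(panel$samples$group == group)
  if (!length(idx)) stop("no samples in group '", group, "'")
  idx
}
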