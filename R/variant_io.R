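#' Read a multi-sample VCF into a genotype panel
#'
#' Parses VCF v4.x via `VariantAnnotation::readVcf()` and converts GT calls to
#' alt-allele dosages. Multi-allelic and indel records are retained but
#' flagged so the site-filter suite can remove them; genotypes carrying an
#' allele other than 0/1 are set to missing. INFO keys SAR/SAF/RPL/RPR and
#' per-genotype DP are carried along when present.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_table `data.frame` with columns `sample_id`, `group`
#'   (levels OPV/B/R), or the path of a TSV with those columns. Every sample
#'   in the VCF must appear in the table.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, sample_table) {
  if (is.character(sample_table)) sample_table <- read_sample_table(sample_table)
  sample_table <- as.data.table(sample_table)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- colnames(vcf)
  missing_samp <- setdiff(ids, sample_table$sample_id)
  if (length(missing_samp))
    stop("sample(s) absent from the sample table: ",
         paste(missing_samp, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_l <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as.list(alt_l), function(a) paste(as.character(a), collapse = ","), "")
  n_alt <- lengths(alt_l)
  is_snp <- nchar(ref) == 1L &
    vapply(as.list(alt_l), function(a) all(nchar(as.character(a)) == 1L), TRUE)
  sites <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt_chr,
    qual = as.numeric(rr$QUAL),
    is_snp = is_snp, n_alt = as.integer(n_alt)
  )
  inf <- VariantAnnotation::info(vcf)
  for (k in c("SAR", "SAF", "RPL", "RPR")) {
    if (k %in% colnames(inf)) sites[[tolower(k)]] <- as.numeric(inf[[k]])
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  depth <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    depth <- VariantAnnotation::geno(vcf)$DP
    mode(depth) <- "integer"
  }
  st <- sample_table[match(ids, sample_id)]
  genotype_panel(sites, st, dosage, depth)
}

#' Read a sample-to-group table
#'
#' @param path TSV with columns `sample_id`, `group` and optionally
#'   `median_depth`.
#' @return `data.table`.
#' @export
read_sample_table <- function(path) {
  st <- fread(path)
  if (!all(c("sample_id", "group") %in% names(st)))
    stop("sample table needs columns sample_id and group")
  st
}

#' Read a windowed ancestry track (BED3+score, 0-based half-open)
#' @param path BED-like TSV: chrom, start, end, ancestry (no header).
#' @return `data.table` with those column names.
#' @export
read_ancestry_track <- function(path) {
  tr <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "ancestry"))
  if (any(tr$ancestry < 0 | tr$ancestry > 1))
    stop("ancestry proportions must lie in [0,1]")
  tr
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 is parsed with `rtracklayer::import()`; the `description` (or `Note`)
#' attribute is kept as the annotation keyword field. BED input (0-based
#' half-open) is converted to 1-based inclusive coordinates.
#'
#' @param path a `.gff3`/`.gff` or `.bed` file.
#' @return `data.table` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `length`, `keyword`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- fread(path, header = FALSE)
    genes <- data.table(
      gene_id = if (ncol(bed) >= 4) as.character(bed[[4]]) else
        sprintf("g%05d", seq_len(nrow(bed))),
      chrom = as.character(bed[[1]]),
      start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]),
      keyword = ""
    )
  } else {
    gr <- rtracklayer::import(path)
    mc <- as.data.frame(GenomicRanges::mcols(gr))
    kw <- if ("description" %in% names(mc)) as.character(mc$description)
      else if ("Note" %in% names(mc)) as.character(mc$Note) else ""
    id <- if ("ID" %in% names(mc)) as.character(mc$ID)
      else if ("Name" %in% names(mc)) as.character(mc$Name)
      else sprintf("g%05d", seq_along(gr))
    genes <- data.table(
      gene_id = id, chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      keyword = kw
    )
  }
  genes[, length := end - start + 1L]
  setorder(genes, chrom, start)
  genes[]
}

#' Site-filter configuration (hard-filter suite)
#'
#' Defaults reproduce the panel's published hard-filter suite verbatim:
#' QUAL > 30, site observed heterozygosity < 0.3, per-genotype depth > 1
#' (failing genotypes are set to missing, not the site removed), per-site
#' mean depth > 1 and < 16, biallelic SNPs only, no strand bias
#' (SAR > 0 and SAF > 0), read placement on both sides (RPL > 1 and
#' RPR > 1), minor allele frequency > 0.05 and missing-data fraction < 0.3.
#' All inequalities are strict, following the printed thresholds.
#'
#' @param min_qual QUAL must exceed this.
#' @param max_site_het site observed heterozygosity must be below this.
#' @param min_genotype_depth genotypes with DP at or below this are set
#'   missing before site statistics are computed.
#' @param min_site_mean_depth,max_site_mean_depth bounds (strict) on mean DP
#'   across called genotypes.
#' @param require_biallelic_snp drop indels and multi-allelic records.
#' @param min_maf panel-wide minor allele frequency must exceed this.
#' @param max_missing missing-genotype fraction must be below this.
#' @param require_strand_balance require SAR > 0 and SAF > 0.
#' @param require_read_placement require RPL > 1 and RPR > 1.
#' @param reference_sample optional sample id that must be called at the
#'   site ("genotype known in the reference genome"); `NULL` disables.
#' @return A `site_filter_config` list.
#' @export
site_filter_config <- function(min_qual = 30, max_site_het = 0.3,
                               min_genotype_depth = 1,
                               min_site_mean_depth = 1,
                               max_site_mean_depth = 16,
                               require_biallelic_snp = TRUE,
                               min_maf = 0.05, max_missing = 0.3,
                               require_strand_balance = TRUE,
                               require_read_placement = TRUE,
                               reference_sample = NULL) {
  cfg <- as.list(environment())
  stopifnot(min_qual >= 0, max_site_het >= 0, max_site_het <= 1,
            min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1,
            min_site_mean_depth <= max_site_mean_depth)
  structure(cfg, class = "site_filter_config")
}

#' Apply the site hard-filter suite
#'
#' Genotypes with DP at or below `min_genotype_depth` are first set to
#' missing; site statistics (heterozygosity, mean depth, MAF, missingness)
#' are then computed on the masked panel and sites failing any enabled rule
#' are removed. Each removed site is attributed to the first failing rule in
#' a fixed order (qual, site_het, mean_depth_min, mean_depth_max,
#' biallelic_snp, reference_called, strand_balance, read_placement, maf,
#' missing). Rules whose inputs are absent from the panel (e.g. no DP matrix
#' or no SAR/SAF INFO) are skipped with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param cfg a [site_filter_config()].
#' @return A list with `panel` (the surviving sites, with masked genotypes)
#'   and `report` (a `data.table` of per-rule removal counts, plus
#'   `n_input`/`n_passed` attributes).
#' @export
apply_site_filters <- function(panel, cfg = site_filter_config()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(cfg, "site_filter_config"))
  geno <- panel$geno
  depth <- panel$depth
  if (!is.null(depth)) {
    geno[!is.na(depth) & depth <= cfg$min_genotype_depth] <- NA_integer_
  } else if (cfg$min_genotype_depth > 0) {
    warning("no per-genotype depth in panel; genotype-depth masking skipped")
  }
  s <- panel$sites
  n <- nrow(s)
  n_samp <- ncol(geno)
  called <- rowSums(!is.na(geno))
  n_het <- rowSums(geno == 1L, na.rm = TRUE)
  het <- ifelse(called > 0, n_het / called, NA_real_)
  alt_cnt <- rowSums(geno, na.rm = TRUE)
  p <- ifelse(called > 0, alt_cnt / (2 * called), NA_real_)
  maf <- pmin(p, 1 - p)
  miss_frac <- 1 - called / n_samp
  mean_dp <- if (!is.null(depth)) {
    dp <- depth
    dp[is.na(geno)] <- NA_integer_
    rowMeans(dp, na.rm = TRUE)
  } else NULL

  rules <- list()
  rules$qual <- !is.na(s$qual) & s$qual > cfg$min_qual
  rules$site_het <- !is.na(het) & het < cfg$max_site_het
  if (!is.null(mean_dp)) {
    rules$mean_depth_min <- !is.na(mean_dp) & mean_dp > cfg$min_site_mean_depth
    rules$mean_depth_max <- !is.na(mean_dp) & mean_dp < cfg$max_site_mean_depth
  } else {
    warning("no depth matrix: mean-depth rules skipped")
  }
  if (cfg$require_biallelic_snp) rules$biallelic_snp <- s$is_snp & s$n_alt == 1L
  if (!is.null(cfg$reference_sample)) {
    j <- match(cfg$reference_sample, panel$samples$sample_id)
    if (is.na(j)) stop("reference_sample not in panel: ", cfg$reference_sample)
    rules$reference_called <- !is.na(geno[, j])
  }
  if (cfg$require_strand_balance) {
    if (all(c("sar", "saf") %in% names(s))) {
      rules$strand_balance <- !is.na(s$sar) & !is.na(s$saf) & s$sar > 0 & s$saf > 0
    } else warning("SAR/SAF absent: strand-balance rule skipped")
  }
  if (cfg$require_read_placement) {
    if (all(c("rpl", "rpr") %in% names(s))) {
      rules$read_placement <- !is.na(s$rpl) & !is.na(s$rpr) & s$rpl > 1 & s$rpr > 1
    } else warning("RPL/RPR absent: read-placement rule skipped")
  }
  rules$maf <- !is.na(maf) & maf > cfg$min_maf
  rules$missing <- miss_frac < cfg$max_missing

  keep <- rep(TRUE, n)
  removed_by <- rep(NA_character_, n)
  for (rn in names(rules)) {
    fails <- keep & !rules[[rn]]
    removed_by[fails] <- rn
    keep <- keep & rules[[rn]]
  }
  report <- data.table(
    rule = names(rules),
    n_removed = vapply(names(rules),
                       function(rn) sum(removed_by == rn, na.rm = TRUE), 0L)
  )
  out <- genotype_panel(s[keep], panel$samples,
                        geno[keep, , drop = FALSE],
                        if (!is.null(depth)) depth[keep, , drop = FALSE])
  # carry genotype masking into the depth-based masking marker so a second
  # application is a no-op on the genotype matrix
  attr(report, "n_input") <- n
  attr(report, "n_passed") <- sum(keep)
  list(panel = out, report = report)
}

#' Per-group alternate-allele frequencies
#'
#' @param panel a [genotype_panel()].
#' @param group one of `"OPV"`, `"B"`, `"R"`.
#' @param min_called sites with fewer called samples than this are flagged
#'   (frequency still reported when at least one call exists).
#' @return `data.table` with `chrom`, `pos`, `freq` (alt-allele frequency =
#'   alt count / 2 x called diploids; `NA` when no calls), `n_called`,
#'   `flagged`.
#' @export
group_allele_freq <- function(panel, group, min_called = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- group_columns(panel, group)
  g <- panel$geno[, j, drop = FALSE]
  called <- rowSums(!is.na(g))
  freq <- ifelse(called > 0, rowSums(g, na.rm = TRUE) / (2 * called), NA_real_)
  data.table(chrom = panel$sites$chrom, pos = panel$sites$pos,
             freq = freq, n_called = called, flagged = called < min_called)
}

#' Observed heterozygosity per site and per sample
#'
#' Per site: heterozygous calls / called samples. Per sample: heterozygous
#' sites / called sites.
#'
#' @param panel a [genotype_panel()].
#' @return A list with `data.table`s `site` (`chrom`, `pos`, `het`,
#'   `n_called`) and `sample` (`sample_id`, `group`, `het`, `n_called`).
#' @export
observed_heterozygosity <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  site_called <- rowSums(!is.na(g))
  site_het <- ifelse(site_called > 0,
                     rowSums(g == 1L, na.rm = TRUE) / site_called, NA_real_)
  samp_called <- colSums(!is.na(g))
  samp_het <- ifelse(samp_called > 0,
                     colSums(g == 1L, na.rm = TRUE) / samp_called, NA_real_)
  list(
    site = data.table(chrom = panel$sites$chrom, pos = panel$sites$pos,
                      het = site_het, n_called = site_called),
    sample = data.table(sample_id = panel$samples$sample_id,
                        group = panel$samples$group,
                        het = samp_het, n_called = samp_called)
  )
}
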