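#' Simulation configuration for a three-pool resequencing panel
#'
#' Describes the stated world of the synthetic generator: a panel of 9 OPV,
#' 127 maintainer (B) and 96 restorer (R) lines, sample median coverages
#' spanning roughly 1.6-19x, mostly homozygous inbred B/R genotypes, ancestral
#' OPV polymorphism sorted into the two pools with configurable
#' parallel/opposite shift fractions, introgression blocks private to R lines
#' on chromosomes 8, 10 and 13, gene deletions enriched inside those blocks,
#' and copy-number amplifications.
#'
#' Distribution arguments are lists with a `dist` element
#' (`"uniform"`, `"lognormal"`, `"beta"`, `"const"`) plus the distribution's
#' parameters and optional truncation bounds `min`/`max` (values are clipped).
#'
#' @param n_opv,n_b,n_r sample counts per group.
#' @param n_chrom,chrom_length_bp genome layout (equal-length chromosomes;
#'   scaled down from a 3.6-Gb genome for desk-scale runs).
#' @param n_sites number of SNP records to simulate.
#' @param n_genes number of gene models.
#' @param gene_length_dist gene length distribution; the lognormal default is
#'   short-gene heavy with a long right tail.
#' @param ancestral_freq_dist distribution of OPV (ancestral) alternate-allele
#'   frequencies.
#' @param p_shifted fraction of sites at which both pools shift away from the
#'   ancestral frequency.
#' @param p_opposite_given_shifted fraction of shifted sites sorting in
#'   opposite directions in B and R.
#' @param shift_magnitude_dist distribution of |delta| for shifted sites;
#'   support must be >= 0.2 so true shifts clear the classifier's threshold.
#' @param drift_f_b,drift_f_r Balding-Nichols drift parameter for the B and R
#'   pools (variance of the pool frequency around the ancestral frequency is
#'   `F p (1-p)`); 0 disables drift.
#' @param inbreeding_f_br,inbreeding_f_opv probability that a line's genotype
#'   at a site is drawn fully homozygous rather than Hardy-Weinberg.
#' @param introgression_blocks `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based inclusive bp), `carrier_group`, `ancestry_level`.
#' @param del_rate_in_block,del_rate_outside per-gene homozygous deletion
#'   probability for carrier-group samples inside blocks vs everywhere else
#'   (line-specific, independent across samples).
#' @param del_gene_frac fraction of genes segregating a pool-sorted deletion
#'   allele: for such genes the absence frequency is drawn independently for
#'   B and R from `del_pool_freq_dist`, while outbred OPV lines are absent
#'   only at the homozygous-deletion rate (mean pool frequency squared).
#'   This gives within-pool crosses more shared absent genes than
#'   between-pool crosses.
#' @param del_pool_freq_dist distribution of the per-pool absence frequency
#'   of deletion-polymorphic genes.
#' @param amp_rate per-gene, per-sample amplification probability.
#' @param amp_copy_dist amplified copy number: `base + rpois(lambda)`.
#' @param frac_diff_genes fraction of genes given pool-differentiated absence
#'   (planted signal for the permutation test).
#' @param diff_del_freq length-2 numeric: absence probability in the
#'   `diff_del_group` vs the other pool, for differentiated genes.
#' @param diff_del_group pool carrying the high absence rate.
#' @param depth_per_sample_dist distribution of sample median coverage;
#'   default lognormal with median 4.5x clipped to [1.6, 19].
#' @param read_length_bp read length used in the Poisson depth model.
#' @param frac_multiallelic,frac_indel fraction of records emitted as
#'   multi-allelic or indel (removed by the biallelic-SNP filter).
#' @param frac_fail_qual,frac_fail_strand,frac_fail_placement fraction of
#'   sites emitted with failing QUAL, SAR/SAF or RPL/RPR annotations.
#' @param ppr_frac background fraction of genes annotated with the
#'   "pentatricopeptide" keyword.
#' @param n_ppr_block_genes keyword genes planted inside the chromosome-13
#'   introgression block (Rf1-like candidates).
#' @param ancestry_window_bp window width of the emitted ancestry track.
#' @param ancestry_baseline_max non-introgressed windows get ancestry drawn
#'   uniformly on [0, this]; must stay below the 0.1 call threshold.
#' @param seed RNG seed; together with the config it fully determines output.
#'
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(
    n_opv = 9, n_b = 127, n_r = 96,
    n_chrom = 17, chrom_length_bp = 2e7,
    n_sites = 20000,
    n_genes = 2000,
    gene_length_dist = list(dist = "lognormal", meanlog = log(2000),
                            sdlog = 1.1, min = 150, max = 30000),
    ancestral_freq_dist = list(dist = "beta", shape1 = 0.8, shape2 = 0.8,
                               min = 0.05, max = 0.95),
    p_shifted = 0.25,
    p_opposite_given_shifted = 0.003,
    shift_magnitude_dist = list(dist = "uniform", min = 0.2, max = 0.5),
    drift_f_b = 0.045, drift_f_r = 0.045,
    inbreeding_f_br = 0.95, inbreeding_f_opv = 0,
    introgression_blocks = default_introgression_blocks(chrom_length_bp),
    del_rate_in_block = 0.015, del_rate_outside = 0.01,
    del_gene_frac = 0.05,
    del_pool_freq_dist = list(dist = "uniform", min = 0, max = 0.4),
    amp_rate = 0.005,
    amp_copy_dist = list(dist = "pois_plus", base = 4, lambda = 1),
    frac_diff_genes = 0, diff_del_freq = c(0.5, 0), diff_del_group = "R",
    depth_per_sample_dist = list(dist = "lognormal", meanlog = log(4.5),
                                 sdlog = 0.55, min = 1.6, max = 19),
    read_length_bp = 100,
    frac_multiallelic = 0.01, frac_indel = 0.01,
    frac_fail_qual = 0.02, frac_fail_strand = 0.02, frac_fail_placement = 0.02,
    ppr_frac = 0.01, n_ppr_block_genes = 5,
    ancestry_window_bp = 5e5, ancestry_baseline_max = 0.08,
    seed = 1L) {
  cfg <- as.list(environment())
  cfg$introgression_blocks <- as.data.table(introgression_blocks)
  probs <- c(p_shifted, p_opposite_given_shifted, drift_f_b, drift_f_r,
             inbreeding_f_br, inbreeding_f_opv, del_rate_in_block,
             del_rate_outside, del_gene_frac, amp_rate, frac_diff_genes,
             diff_del_freq,
             frac_multiallelic, frac_indel, frac_fail_qual, frac_fail_strand,
             frac_fail_placement, ppr_frac)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (n_sites < 1 || n_genes < 1 || n_chrom < 1)
    stop("n_sites, n_genes and n_chrom must be >= 1")
  if (min(n_opv, n_b, n_r) < 1) stop("each group needs >= 1 sample")
  if (nrow(cfg$introgression_blocks)) {
    blk <- cfg$introgression_blocks
    need <- c("chrom", "start", "end", "carrier_group", "ancestry_level")
    if (!all(need %in% names(blk)))
      stop("introgression_blocks needs columns: ", paste(need, collapse = ", "))
    if (any(blk$start < 1 | blk$end > chrom_length_bp | blk$start > blk$end))
      stop("introgression block intervals must lie within chromosome bounds")
    if (any(blk$ancestry_level < 0 | blk$ancestry_level > 1))
      stop("ancestry_level must lie in [0,1]")
  }
  if (shift_magnitude_dist$dist != "const" &&
      isTRUE(shift_magnitude_dist$min < 0.2))
    warning("shift magnitudes below 0.2 will be invisible to the shift classifier")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Default introgression blocks on chromosomes 8, 10 and 13
#'
#' One R-carried block per chromosome, mirroring the empirical concentration
#' of wild-relative introgression in restorer lines.
#'
#' @param chrom_length_bp chromosome length used to keep blocks in bounds.
#' @return `data.table` of block intervals.
#' @export
default_introgression_blocks <- function(chrom_length_bp = 2e7) {
  f <- chrom_length_bp / 2e7  # scale with the genome
  data.table(
    chrom = c("chr8", "chr10", "chr13"),
    start = round(c(5e6, 1e7, 2e6) * f) + 1,
    end = round(c(8e6, 1.4e7, 5e6) * f),
    carrier_group = "R",
    ancestry_level = 0.6
  )
}

# Draw n values from a distribution spec (list with $dist + params).
draw_dist <- function(spec, n) {
  x <- switch(spec$dist,
    uniform = runif(n, spec$min, spec$max),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    beta = rbeta(n, spec$shape1, spec$shape2),
    const = rep(spec$value, n),
    pois_plus = spec$base + rpois(n, spec$lambda),
    stop("unknown distribution: ", spec$dist)
  )
  if (!is.null(spec$min) && spec$dist != "uniform") x <- pmax(x, spec$min)
  if (!is.null(spec$max) && spec$dist != "uniform") x <- pmin(x, spec$max)
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d OPV + %d B + %d R samples, %d sites, %d genes on %d x %.3g bp chromosomes, seed %d\n",
    x$n_opv, x$n_b, x$n_r, x$n_sites, x$n_genes, x$n_chrom,
    x$chrom_length_bp, x$seed
  ))
  invisible(x)
}
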