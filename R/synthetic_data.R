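#' Generate a synthetic three-pool genotype panel with known truth
#'
#' Realises the stated world of a [sim_config()]: OPV lines carry ancestral
#' polymorphism at Hardy-Weinberg proportions; B and R lines are near-fully
#' homozygous inbreds whose pool frequencies equal the ancestral frequency
#' plus pool drift plus, at shifted sites, a signed shift that is parallel or
#' opposite between the pools; sites inside R-carried introgression blocks
#' get strongly divergent R frequencies. Per-genotype depths are Poisson
#' around each sample's median coverage (a zero-depth genotype is emitted as
#' missing), and QUAL / strand-balance / read-placement annotations are drawn
#' so that a configurable fraction of sites fails each hard filter.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (a `synthetic_truth`: site categories and true pool frequencies, gene
#'   models, and per-sample true median coverage).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  n_sites <- config$n_sites

  # site coordinates, unique within chromosome
  ci <- sample.int(config$n_chrom, n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (k in seq_len(config$n_chrom)) {
    idx <- which(ci == k)
    if (length(idx))
      pos[idx] <- sort(sample.int(config$chrom_length_bp, length(idx)))
  }
  chrom <- chroms[ci]
  ord <- order(chrom, pos)  # panel order (lexicographic chrom)
  chrom <- chrom[ord]; pos <- pos[ord]

  # ancestral frequencies and true shift categories
  p0 <- draw_dist(config$ancestral_freq_dist, n_sites)
  shifted <- runif(n_sites) < config$p_shifted
  opposite <- shifted & (runif(n_sites) < config$p_opposite_given_shifted)
  category <- ifelse(!shifted, "unshifted",
                     ifelse(opposite, "opposite", "parallel"))
  sgn <- sample(c(-1, 1), n_sites, replace = TRUE)
  mag_b <- draw_dist(config$shift_magnitude_dist, n_sites)
  mag_r <- draw_dist(config$shift_magnitude_dist, n_sites)
  d_b <- ifelse(shifted, sgn * mag_b, 0)
  d_r <- ifelse(shifted, ifelse(opposite, -sgn, sgn) * mag_r, 0)

  bn_draw <- function(p, f) {
    if (f <= 0) return(p)
    k <- (1 - f) / f
    rbeta(length(p), pmax(p * k, 1e-8), pmax((1 - p) * k, 1e-8))
  }
  f_b_raw <- bn_draw(p0, config$drift_f_b) + d_b
  f_r_raw <- bn_draw(p0, config$drift_f_r) + d_r
  clipped <- f_b_raw < 0 | f_b_raw > 1 | f_r_raw < 0 | f_r_raw > 1
  if (any(clipped))
    message(sum(clipped), " site(s) had shifted frequencies clipped to [0,1]")
  f_b <- pmin(pmax(f_b_raw, 0), 1)
  f_r <- pmin(pmax(f_r_raw, 0), 1)
  f_opv <- p0

  # introgression blocks: carrier pool frequency pulled toward a divergent
  # introgressed allele, proportional to the block's ancestry level
  in_block <- rep(FALSE, n_sites)
  blocks <- config$introgression_blocks
  if (nrow(blocks)) {
    intro_allele <- rbinom(n_sites, 1, 0.5)
    for (b in seq_len(nrow(blocks))) {
      hit <- chrom == blocks$chrom[b] & pos >= blocks$start[b] &
        pos <= blocks$end[b]
      in_block <- in_block | hit
      al <- blocks$ancestry_level[b]
      if (blocks$carrier_group[b] == "R") {
        f_r[hit] <- (1 - al) * f_r[hit] + al * intro_allele[hit]
      } else if (blocks$carrier_group[b] == "B") {
        f_b[hit] <- (1 - al) * f_b[hit] + al * intro_allele[hit]
      }
    }
  }

  samples <- data.table(
    sample_id = c(sprintf("OPV%02d", seq_len(config$n_opv)),
                  sprintf("B%03d", seq_len(config$n_b)),
                  sprintf("R%03d", seq_len(config$n_r))),
    group = rep(c("OPV", "B", "R"), c(config$n_opv, config$n_b, config$n_r))
  )
  n_samp <- nrow(samples)

  draw_group <- function(f, n, f_inbred) {
    hw <- matrix(rbinom(n_sites * n, 2, f), n_sites, n)
    if (f_inbred <= 0) return(hw)
    hom <- 2L * matrix(rbinom(n_sites * n, 1, f), n_sites, n)
    take <- matrix(runif(n_sites * n) < f_inbred, n_sites, n)
    ifelse(take, hom, hw)
  }
  geno <- cbind(
    draw_group(f_opv, config$n_opv, config$inbreeding_f_opv),
    draw_group(f_b, config$n_b, config$inbreeding_f_br),
    draw_group(f_r, config$n_r, config$inbreeding_f_br)
  )

  # per-genotype depth: Poisson around the sample's median coverage
  cov_s <- draw_dist(config$depth_per_sample_dist, n_samp)
  depth <- matrix(rpois(n_sites * n_samp, rep(cov_s, each = n_sites)),
                  n_sites, n_samp)
  geno[depth == 0L] <- NA_integer_

  # site annotations: QUAL / strand / placement failures at configured rates
  fail_q <- runif(n_sites) < config$frac_fail_qual
  qual <- ifelse(fail_q, runif(n_sites, 0, 30), runif(n_sites, 30.01, 2000))
  sar <- 1L + rpois(n_sites, 5); saf <- 1L + rpois(n_sites, 5)
  fail_s <- runif(n_sites) < config$frac_fail_strand
  side <- runif(n_sites) < 0.5
  sar[fail_s & side] <- 0L; saf[fail_s & !side] <- 0L
  rpl <- 2L + rpois(n_sites, 5); rpr <- 2L + rpois(n_sites, 5)
  fail_p <- runif(n_sites) < config$frac_fail_placement
  side2 <- runif(n_sites) < 0.5
  rpl[fail_p & side2] <- sample(0:1, sum(fail_p & side2), replace = TRUE)
  rpr[fail_p & !side2] <- sample(0:1, sum(fail_p & !side2), replace = TRUE)

  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4L, n_sites, replace = TRUE)
  off <- sample.int(3L, n_sites, replace = TRUE)
  ref <- bases[ri]
  alt <- bases[((ri - 1L + off) %% 4L) + 1L]
  n_alt <- rep(1L, n_sites)
  is_snp <- rep(TRUE, n_sites)
  multi <- runif(n_sites) < config$frac_multiallelic
  if (any(multi)) {
    off2 <- ((off - 1L + sample.int(2L, n_sites, replace = TRUE)) %% 3L) + 1L
    alt2 <- bases[((ri - 1L + off2) %% 4L) + 1L]
    alt[multi] <- paste(alt[multi], alt2[multi], sep = ",")
    n_alt[multi] <- 2L
  }
  indel <- !multi & runif(n_sites) < config$frac_indel
  if (any(indel)) {
    ref[indel] <- paste0(ref[indel], "A")
    is_snp[indel] <- FALSE
  }

  sites <- data.table(
    chrom = chrom, pos = pos, ref = ref, alt = alt, qual = round(qual, 2),
    is_snp = is_snp, n_alt = n_alt, sar = sar, saf = saf, rpl = rpl, rpr = rpr
  )
  panel <- genotype_panel(sites, samples, geno, depth)

  genes <- generate_gene_models(config, chroms)
  truth <- structure(list(
    sites = data.table(chrom = chrom, pos = pos, category = category,
                       f_opv = f_opv, f_b = f_b, f_r = f_r,
                       in_block = in_block, clipped = clipped,
                       is_snp = is_snp & n_alt == 1L),
    genes = genes,
    samples = data.table(samples, true_median_depth = cov_s),
    copy_number = NULL,
    seed = config$seed
  ), class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

# Gene models: random intervals with a short-gene-heavy length distribution;
# a configurable number of "pentatricopeptide" keyword genes is planted in
# the chromosome-13 block (Rf1-like candidates), plus background keyword
# genes at rate ppr_frac.
generate_gene_models <- function(config, chroms) {
  n <- config$n_genes
  len <- pmin(round(draw_dist(config$gene_length_dist, n)),
              config$chrom_length_bp)
  chrom <- chroms[sample.int(config$n_chrom, n, replace = TRUE)]
  start <- floor(runif(n, 1, config$chrom_length_bp - len + 1))
  keyword <- runif(n) < config$ppr_frac
  blocks <- config$introgression_blocks
  b13 <- if (nrow(blocks)) which(blocks$chrom == "chr13") else integer()
  n_plant <- min(config$n_ppr_block_genes, n)
  if (length(b13) && n_plant > 0) {
    ii <- sample.int(n, n_plant)
    chrom[ii] <- "chr13"
    len[ii] <- pmin(len[ii], blocks$end[b13[1]] - blocks$start[b13[1]])
    start[ii] <- floor(runif(n_plant, blocks$start[b13[1]],
                             blocks$end[b13[1]] - len[ii] + 1))
    keyword[ii] <- TRUE
  }
  genes <- data.table(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + len - 1), length = as.integer(len),
    keyword = ifelse(keyword, "pentatricopeptide repeat-containing protein",
                     "hypothetical protein")
  )
  genes$in_block <- gene_in_block(genes, blocks)
  setorder(genes, chrom, start)
  genes
}

gene_in_block <- function(genes, blocks) {
  hit <- rep(FALSE, nrow(genes))
  if (is.null(blocks) || !nrow(blocks)) return(hit)
  for (b in seq_len(nrow(blocks))) {
    hit <- hit | (genes$chrom == blocks$chrom[b] &
                    genes$start <= blocks$end[b] & genes$end >= blocks$start[b])
  }
  hit
}

#' Simulate per-gene read depths from true copy numbers
#'
#' Draws a true copy number for every gene x sample (homozygous deletions at
#' block-dependent rates, amplifications, optional pool-differentiated
#' absence), then simulates read counts as Poisson with mean
#' `coverage * length / read_length * copy` and converts them to mean
#' per-base depth. A true copy of 0 always yields depth exactly 0; short
#' genes in low-coverage samples can stochastically receive zero reads,
#' reproducing the depth-driven false-absence artifact of real panels.
#'
#' @param config a [sim_config()].
#' @param truth the `synthetic_truth` from [generate_genotypes()].
#' @return A list with `depths` (a [gene_depth_matrix()]) and `truth`
#'   (augmented with the true copy-number matrix).
#' @export
generate_gene_depths <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 1L)
  genes <- truth$genes
  samples <- truth$samples
  ng <- nrow(genes); ns <- nrow(samples)

  p_del <- matrix(config$del_rate_outside, ng, ns)
  carrier <- samples$group %in%
    unique(config$introgression_blocks$carrier_group)
  if (any(genes$in_block) && any(carrier))
    p_del[genes$in_block, carrier] <- config$del_rate_in_block
  # pool-structured deletion polymorphism: a fraction of genes segregate a
  # deletion allele whose frequency was sorted independently into B and R;
  # OPV lines are outbred, so only the homozygous-deletion class is absent
  if (config$del_gene_frac > 0) {
    poly <- runif(ng) < config$del_gene_frac
    qb <- ifelse(poly, draw_dist(config$del_pool_freq_dist, ng), 0)
    qr <- ifelse(poly, draw_dist(config$del_pool_freq_dist, ng), 0)
    qo <- ((qb + qr) / 2)^2
    qmat <- matrix(0, ng, ns)
    qmat[, samples$group == "B"] <- qb
    qmat[, samples$group == "R"] <- qr
    qmat[, samples$group == "OPV"] <- qo
    p_del <- 1 - (1 - p_del) * (1 - qmat)
  }
  n_diff <- floor(config$frac_diff_genes * ng)
  if (n_diff > 0) {
    gi <- sample.int(ng, n_diff)
    hi <- samples$group == config$diff_del_group
    lo <- samples$group == setdiff(c("B", "R"), config$diff_del_group)
    p_del[gi, hi] <- config$diff_del_freq[1]
    p_del[gi, lo] <- config$diff_del_freq[2]
  }
  copy <- matrix(1, ng, ns)
  copy[matrix(runif(ng * ns), ng, ns) < p_del] <- 0
  amp <- copy == 1 & matrix(runif(ng * ns), ng, ns) < config$amp_rate
  copy[amp] <- draw_dist(config$amp_copy_dist, sum(amp))

  lam <- outer(genes$length / config$read_length_bp,
               samples$true_median_depth) * copy
  reads <- matrix(rpois(ng * ns, lam), ng, ns)
  depth <- reads * config$read_length_bp / genes$length

  truth$copy_number <- copy
  dimnames(truth$copy_number) <- list(genes$gene_id, samples$sample_id)
  list(
    depths = gene_depth_matrix(genes, samples[, .(sample_id, group)], depth),
    truth = truth
  )
}

#' Write a simulated panel to standard file formats
#'
#' Emits VCF v4.2 (GT:DP genotypes; INFO keys SAR/SAF/RPL/RPR), GFF3 gene
#' models (1-based inclusive), a TSV gene x sample depth matrix, a BED3+score
#' windowed ancestry track (0-based half-open windows tiling each
#' chromosome), a TSV sample table and, when `truth` is given, the truth
#' ledger as TSVs.
#'
#' @param panel a [genotype_panel()].
#' @param depths a [gene_depth_matrix()] or `NULL`.
#' @param config the [sim_config()] used to generate them.
#' @param dir output directory (created if needed).
#' @param truth optional `synthetic_truth` to serialize alongside.
#' @return Invisibly, a named list of written file paths.
#' @export
write_outputs <- function(panel, depths, config, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- list()

  paths$vcf <- file.path(dir, "panel.vcf")
  write_vcf_file(panel, paths$vcf, config$chrom_length_bp)

  paths$samples <- file.path(dir, "samples.tsv")
  samp <- copy(panel$samples)
  if (!is.null(truth)) samp$median_depth <- truth$samples$true_median_depth
  fwrite(samp, paths$samples, sep = "\t")

  if (!is.null(depths)) {
    paths$genes <- file.path(dir, "genes.gff3")
    write_gene_models(depths$genes, paths$genes)
    paths$depth <- file.path(dir, "gene_depth.tsv")
    write_depth_matrix(depths, paths$depth)
  }

  paths$ancestry <- file.path(dir, "ancestry.bed")
  write_ancestry_track(build_ancestry_track(config), paths$ancestry)

  if (!is.null(truth)) {
    paths$truth_sites <- file.path(dir, "truth_sites.tsv")
    fwrite(truth$sites, paths$truth_sites, sep = "\t")
    paths$truth_genes <- file.path(dir, "truth_genes.tsv")
    fwrite(truth$genes, paths$truth_genes, sep = "\t")
    paths$truth_samples <- file.path(dir, "truth_samples.tsv")
    fwrite(truth$samples, paths$truth_samples, sep = "\t")
    if (!is.null(truth$copy_number)) {
      paths$truth_copy <- file.path(dir, "truth_copy_number.tsv")
      cn <- data.table(gene_id = rownames(truth$copy_number),
                       as.data.table(truth$copy_number))
      fwrite(cn, paths$truth_copy, sep = "\t")
    }
  }
  invisible(paths)
}

#' Build the windowed ancestry track implied by a simulation config
#'
#' Fixed-width windows tile each chromosome; windows overlapping an
#' introgression block carry the block's ancestry level, all others a
#' baseline drawn uniformly below the introgression-call threshold.
#' Coordinates are 0-based half-open.
#'
#' @param config a [sim_config()].
#' @return `data.table` with columns `chrom`, `start`, `end`, `ancestry`.
#' @export
build_ancestry_track <- function(config) {
  set.seed(config$seed + 2L)
  w <- config$ancestry_window_bp
  chroms <- paste0("chr", seq_len(config$n_chrom))
  starts <- seq(0, config$chrom_length_bp - 1, by = w)
  track <- data.table(
    chrom = rep(chroms, each = length(starts)),
    start = rep(starts, config$n_chrom)
  )
  track[, end := pmin(start + w, config$chrom_length_bp)]
  track[, ancestry := round(runif(.N, 0, config$ancestry_baseline_max), 4)]
  blocks <- config$introgression_blocks
  for (b in seq_len(nrow(blocks))) {
    hit <- track$chrom == blocks$chrom[b] &
      track$start < blocks$end[b] & track$end > blocks$start[b] - 1
    track[hit, ancestry := blocks$ancestry_level[b]]
  }
  track[]
}

# ---- writers -------------------------------------------------------------

write_vcf_file <- function(panel, path, contig_length = NA) {
  s <- panel$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=heteropool",
    sprintf("##contig=<ID=%s%s>", unique(s$chrom),
            if (is.na(contig_length)) "" else sprintf(",length=%d", as.integer(contig_length))),
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads on reverse strand\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads on forward strand\">",
    "##INFO=<ID=RPL,Number=1,Type=Integer,Description=\"Reads placed left of variant\">",
    "##INFO=<ID=RPR,Number=1,Type=Integer,Description=\"Reads placed right of variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[panel$geno + 1L],
               nrow(panel$geno), ncol(panel$geno))
  gt[is.na(panel$geno)] <- "./."
  dp <- if (is.null(panel$depth)) matrix(".", nrow(gt), ncol(gt)) else panel$depth
  cells <- matrix(paste(gt, dp, sep = ":"), nrow(gt), ncol(gt))
  info <- if (all(c("sar", "saf", "rpl", "rpr") %in% names(s))) {
    sprintf("SAR=%d;SAF=%d;RPL=%d;RPR=%d", s$sar, s$saf, s$rpl, s$rpr)
  } else rep(".", nrow(s))
  body <- do.call(paste, c(
    list(s$chrom, s$pos, ".", s$ref, s$alt, format(s$qual, trim = TRUE),
         ".", info, "GT:DP"),
    lapply(seq_len(ncol(cells)), function(j) cells[, j]),
    sep = "\t"
  ))
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    type = "gene", ID = genes$gene_id, Name = genes$gene_id,
    description = genes$keyword
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_depth_matrix <- function(depths, path) {
  dt <- data.table(gene_id = depths$genes$gene_id,
                   as.data.table(depths$depth))
  setnames(dt, c("gene_id", depths$samples$sample_id))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

write_ancestry_track <- function(track, path) {
  fwrite(track[, .(chrom, start, end, ancestry)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}
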