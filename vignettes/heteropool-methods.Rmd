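---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the statistical
models it implements, the synthetic world it validates them against, and the
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

# The analysis models

## Site filtering

`apply_site_filters()` reproduces a conservative hard-filter suite for a
FreeBayes-style multi-sample VCF: QUAL > 30, site observed heterozygosity
< 0.3, per-genotype depth > 1, per-site mean depth > 1 and < 16, biallelic
SNPs only, strand balance (SAR > 0 and SAF > 0), read placement on both
sides of the variant (RPL > 1 and RPR > 1), minor allele frequency > 0.05,
missing data < 0.3. Three readings had to be fixed:

* "depth for individual genotype > 1" is a genotype-level quantity: failing
  genotypes are set to missing *before* site statistics are computed, and
  site-level missingness then catches degraded sites. A consequence is that
  a fully masked site fails at the first statistic rule (heterozygosity
  undefined), not at the missingness rule; the filter report attributes
  each removal to the first failing rule in a fixed, documented order.
* "minimum average depth" is read as the per-site mean DP across called
  genotypes — the only site-level reading consistent with a site filter.
  Note that after masking genotypes at DP ≤ 1, a site mean ≤ 1 is only
  reachable through the masked set, so this rule is nearly vacuous under
  the defaults; it is kept for fidelity and for non-default masking.
* "genotype known in the reference genome" is ambiguous (reference-derived
  sample called, or site present in the assembly). It is implemented as an
  optional rule requiring a designated reference-derived sample to be
  called, off by default.

All inequalities are strict, following the printed thresholds (QUAL = 30
fails, QUAL = 30.01 passes). MAF at filter time is panel-wide; the
per-comparison marker rules below re-apply their own MAF.

## Weir–Cockerham F_ST

`site_fst()` implements the two-population diploid Weir & Cockerham (1984)
variance-component estimator from group sample sizes, alternate-allele
frequencies and observed heterozygote proportions, returning the
among-population component $a$ and the total $d = a+b+c$ per marker.
Negative per-site estimates are retained untruncated, because the window
estimate is the ratio of sums $\hat\theta_w = \sum a / \sum d$ — *not* the
mean of per-site ratios — and truncation would bias it. Markers entering a
comparison must be called in more than one sample per group, have MAF
> 0.05 and observed heterozygosity < 0.6; MAF and heterozygosity are
computed over the union of the two compared groups by default
(`marker_config(pool = "pair")`), with a panel-wide option, since the
source protocol does not say how they were pooled. F_ST is computed
pairwise for the three comparisons rather than as one three-population
estimate. Windows are fixed-width, anchored at position 0 of each
chromosome, 0-based half-open; this anchoring is arbitrary but must be
fixed for reproducibility.

"Top p%" flagging uses the k-th largest value with
$k = \lceil n \cdot p/100 \rceil$ as the cutoff and flags everything at or
above it, so ties at the cutoff are all flagged and the all-equal
degenerate case flags everything.

## PCA and LD pruning

`panel_pca()` mean-centres each site and scales by the binomial dosage
standard deviation $\sqrt{2p(1-p)}$ under the site's allele frequency
(EIGENSTRAT-style), mean-imputes missing dosages, drops zero-variance
sites, and eigendecomposes the sample covariance; scores are the
projections on the principal axes. For binary gene-absence indicators
(`pav_pca()`) the variance standardization is turned off — standardizing a
rare indicator would explode its weight. LD pruning is a greedy
left-to-right scan: a site is dropped if its squared Pearson correlation
with any retained site within a trailing window of sites on the same
chromosome exceeds $r^2_{max} = 0.2$. Only the $r^2$ cutoff is prescribed
by the protocol; the greedy genomic-order scan matches common practice.

## Copy-state calling

For each sample, the median gene depth $m_s$ is taken over *all* genes,
zeros included (excluding zeros would inflate $m_s$ and over-call
amplifications). States: absent iff depth is exactly 0; amplified iff
depth $> 3 m_s$ strictly (so depth $= 3 m_s$ is present); else present.
The caller only detects homozygous deletions, by construction. The
permutation test counts genes whose absence (or amplification) frequency
differs between pools by at least a threshold; the protocol never defines
"different frequencies", so the threshold defaults to 0.2 and is exposed.
Absent and amplified states are tested separately, with separate nulls.
The p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(n+1)$ to
avoid p = 0 artifacts.

## Shift classification

Sites with the OPV alternate-allele frequency in $[0.25, 0.75]$
(inclusive) where both pools shifted by at least 0.2 (inclusive) are
classified parallel or opposite by the sign concordance of
$\Delta_B = f_B - f_{OPV}$ and $\Delta_R = f_R - f_{OPV}$. "Between" and
"at least" are read inclusively; because frequencies are ratios of small
integer counts, the inclusive bounds are enforced with a $10^{-9}$
tolerance so that, e.g., $0.70 - 0.50 \ge 0.2$ holds despite floating-point
representation. Exclusions are annotated with the first failing reason in
the order: missing frequency, OPV band, B shift, R shift.

**A caveat the tests quantify:** both $\Delta$s subtract the *same*
estimated OPV frequency. With a small OPV panel (the motivating design has
9 lines, SE ≈ 0.12 at $f = 0.5$), that shared estimation error correlates
the two estimated shifts and biases classified sites toward "parallel" —
under a pure-drift simulation with 9 OPV lines the parallel fraction is far
above 1/2. The acceptance suite therefore calibrates the drift null with a
large (200-line) OPV panel, where the shared error is negligible and the
fraction is statistically compatible with 0.5. Any empirical
parallel-sorting figure obtained with a small OPV panel should be read with
this ascertainment effect in mind.

## Introgression enrichment and crosses

A gene's introgression value is the maximum ancestry over track windows
overlapping it by ≥ 1 bp (the protocol says only "overlapping"); a gene is
introgressed iff its value exceeds 0.1 strictly. Enrichment of absence in
introgressed regions uses Pearson's chi-squared (1 df) without continuity
correction by default — the protocol is silent, and at genome-scale gene
counts the correction is immaterial; it is available by flag. Degenerate
margins produce the table without a test.

`simulate_crosses()` draws unordered distinct-parent pairs with replacement
across draws (`method = "sample"`), or enumerates every pair
(`method = "all_pairs"`), and counts genes absent in both parents — the
genes an F1 would truly lack.

# The synthetic world

The generator's defaults are the stated conditions of the motivating
design, fixed once:

* **Panel**: 9 OPV + 127 B + 96 R lines; sample median coverage lognormal
  with median 4.5×, clipped to [1.6, 19] (the published depth range).
* **Genotypes**: OPV lines Hardy–Weinberg at the ancestral frequency
  ($F = 0$); B/R lines drawn with inbreeding $F = 0.95$ (single-seed
  descent leaves residual heterozygosity). Ancestral frequencies
  Beta(0.8, 0.8) truncated to [0.05, 0.95] — the source gives no spectrum;
  this puts ample mass in the analysed 0.25–0.75 band.
* **Pool frequencies**: Balding–Nichols drift around the ancestral
  frequency with $F = 0.045$ per pool, matching the published genome-wide
  between-pool differentiation in order of magnitude; plus, at a fraction
  `p_shifted = 0.25` of sites, signed shifts of magnitude Uniform(0.2, 0.5)
  that are opposite between pools with probability
  `p_opposite_given_shifted = 0.003` (the published parallel fraction is
  99.7%). Shifts that leave [0, 1] are clipped and logged.
* **Introgression**: one R-carried block each on chromosomes 8, 10 and 13
  (the empirical concentration), ancestry level 0.6; in-block R
  frequencies are pulled toward a random fixed allele proportionally to
  the ancestry level, which elevates block-window F_ST. The emitted
  ancestry track has one value per 500-kb window; non-block windows draw a
  baseline below the 0.1 call threshold.
* **Gene content**: gene lengths lognormal(meanlog = log 2000,
  sdlog = 1.1, min 150 bp) — deliberately short-gene-heavy, because the
  depth model only produces false absences when $cL/\ell$ is small; an
  earlier thinner tail produced none at all and was widened for that
  stated reason, not to meet a threshold. Deletions: line-specific
  homozygous deletions at 1.5% per gene for carrier samples inside blocks
  vs 1.0% outside (the published contrast); additionally a fraction
  (default 5%) of genes segregate a *pool-sorted* deletion allele whose
  absence frequency is drawn independently for B and R (outbred OPV lines
  are absent only at the squared mean frequency) — independent sorting is
  what makes within-pool crosses share more absent genes than B×R
  ($E[q^2] > E[q]^2$). Amplified copies are $4 + \text{Pois}(1)$, chosen
  so a true amplification reliably clears the $3 m_s$ call line.
* **Depth**: reads per gene ~ Poisson$(c_s L/\ell \cdot \text{copy})$ with
  read length $\ell = 100$; copy 0 gives depth exactly 0; the false-absence
  probability of a single-copy gene is the Poisson zero class
  $e^{-c_s L/\ell}$, which the tests check in closed form. No GC or
  mappability bias is modelled.
* **Genome**: 17 chromosomes of 20 Mb by default — a deliberate ~10×
  scale-down of the 3.6-Gb genome so that 500-kb windows retain realistic
  marker densities at desk-scale site counts.

What a green test establishes: that the estimators recover *this* world's
truth — filters remove what they should, F_ST matches the closed-form
estimator, the PAV caller is exactly calibrated to the Poisson zero class,
the permutation p-value is uniform under exchangeability, planted
structure is found. What it does not establish: robustness to alignment
and mappability artifacts, GC bias, partial deletions, heterozygous
deletions, or non-Poisson coverage — none of which the generator emulates.

# Numerical and procedural choices

* Coordinates are 1-based inclusive internally (the R/Bioconductor
  convention); BED-like inputs/outputs are converted at the boundary, and
  window tables report 0-based half-open starts.
* Dosage missingness is mean-imputed only where a method requires complete
  data (correlation for pruning, PCA); frequency and F_ST computations use
  called genotypes only.
* Permutation and cross sampling are seeded explicitly; the pipeline
  derives per-stage seeds from one global seed so stages are independently
  reproducible.
* The nested depth regression reports sequential (type-I) F tests in the
  order depth, then pool, exactly mirroring "test sequentially"; with a
  constant response the F statistics are reported as undefined rather than
  0/0.
* Rank-sum p-values are exact for small tie-free classes and otherwise use
  the tie-corrected normal approximation without continuity correction.

# Acceptance-scale analyses

Two criteria required analysis rather than implementation:

* **Shift-classifier recovery** is run in a pure-shift world (pool drift
  off): with drift on, true frequency displacements ≥ 0.2 arise in a few
  per mill of unshifted sites, and no estimator could attribute those to
  the "unshifted" mechanism label. The drift property itself is tested
  separately (drift on, shifts off, large OPV panel as discussed above).
* **Enrichment power.** At 20,000 genes with absence 1.5% inside vs 1.0%
  outside introgression, the non-central chi-squared power at α = 0.05 is
  $\approx 0.886$ even at the power-maximising 50/50 introgressed split
  (ncp $= n\varphi^2 \approx 10.1$), and lower at realistic splits. The
  stated ≥ 0.9 bar is therefore unattainable in this world; the test is
  implemented faithfully and expected to fail, and the failure is
  documented rather than papered over by inflating the gene count or the
  significance level.

# Known limitations

Homozygous deletions only; no partial-gene or breakpoint resolution; no
de-novo (non-reference) gene discovery; the ancestry track is consumed,
never inferred; no haplotype statistics, admixture modelling, or
genome-wide significance testing of F_ST; the depth model is Poisson and
cannot reproduce mapping-driven absence of long genes, which is why the
false-absence artifact is carried entirely by short genes.
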