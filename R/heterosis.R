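#' Classify sorting of ancestral variation into the two pools
#'
#' Sites where the OPV alternate-allele frequency lies in the ancestral band
#' (inclusive, default 0.25-0.75) and both pools have shifted away from it
#' by at least `min_shift` (inclusive, default 0.2) are classified as
#' `parallel` (both shifts share a sign) or `opposite`; all other sites are
#' `excluded` with an annotated reason, checked in the order missing
#' frequency, OPV band, B shift, R shift.
#'
#' @param freqs `data.table`/`data.frame` with columns `f_opv`, `f_b`, `f_r`
#'   (per-site pool alternate-allele frequencies) and optionally `chrom`,
#'   `pos`.
#' @param opv_band inclusive ancestral-frequency band.
#' @param min_shift inclusive minimum |shift| required of each pool.
#' @return `data.table` with the inputs plus `delta_b`, `delta_r`,
#'   `category` in {parallel, opposite, excluded} and `reason` in
#'   {missing_freq, opv_freq_out_of_band, insufficient_shift_B,
#'   insufficient_shift_R} (`NA` for classified sites).
#' @export
classify_shift <- function(freqs, opv_band = c(0.25, 0.75), min_shift = 0.2) {
  fx <- as.data.table(freqs)
  stopifnot(all(c("f_opv", "f_b", "f_r") %in% names(fx)),
            length(opv_band) == 2, opv_band[1] <= opv_band[2], min_shift > 0)
  fx[, delta_b := f_b - f_opv]
  fx[, delta_r := f_r - f_opv]
  n <- nrow(fx)
  category <- rep("excluded", n)
  reason <- rep(NA_character_, n)
  eps <- 1e-9  # keep the inclusive bounds inclusive under fp rounding
  missing <- is.na(fx$f_opv) | is.na(fx$f_b) | is.na(fx$f_r)
  reason[missing] <- "missing_freq"
  out_band <- !missing &
    (fx$f_opv < opv_band[1] - eps | fx$f_opv > opv_band[2] + eps)
  reason[out_band] <- "opv_freq_out_of_band"
  weak_b <- !missing & !out_band & abs(fx$delta_b) < min_shift - eps
  reason[weak_b] <- "insufficient_shift_B"
  weak_r <- !missing & !out_band & !weak_b & abs(fx$delta_r) < min_shift - eps
  reason[weak_r] <- "insufficient_shift_R"
  ok <- !missing & !out_band & !weak_b & !weak_r
  category[ok] <- ifelse(sign(fx$delta_b[ok]) == sign(fx$delta_r[ok]),
                         "parallel", "opposite")
  fx[, category := category]
  fx[, reason := reason]
  fx[]
}

#' Fraction of classified sites sorting in parallel
#'
#' @param classifications a [classify_shift()] table.
#' @return A list: `n_parallel`, `n_opposite`, `fraction_parallel`
#'   (`NA` with an explanatory `note` when no site classified), `n_sites`,
#'   `n_in_band` (OPV frequency inside the band), `n_classified`.
#' @export
parallel_fraction <- function(classifications) {
  cl <- as.data.table(classifications)
  n_par <- sum(cl$category == "parallel")
  n_opp <- sum(cl$category == "opposite")
  denom <- n_par + n_opp
  res <- list(
    n_parallel = n_par, n_opposite = n_opp,
    fraction_parallel = if (denom > 0) n_par / denom else NA_real_,
    n_sites = nrow(cl),
    n_in_band = sum(!is.na(cl$reason) &
                      !cl$reason %in% c("missing_freq", "opv_freq_out_of_band")) +
      denom,
    n_classified = denom,
    note = if (denom == 0) "no site classified parallel or opposite" else NULL
  )
  res
}

#' Windowed counts of parallel and opposite shifts
#'
#' @param classifications a [classify_shift()] table carrying `chrom` and
#'   `pos`.
#' @param window_bp window width in bp.
#' @return `data.table`: `chrom`, `start` (0-based), `end`, `n_parallel`,
#'   `n_opposite`, `opposite_rate` (`NA` for windows without classified
#'   sites).
#' @export
windowed_opposite_rate <- function(classifications, window_bp = 5e5) {
  cl <- as.data.table(classifications)
  stopifnot(all(c("chrom", "pos") %in% names(cl)))
  w <- cl[, .(
    n_parallel = sum(category == "parallel"),
    n_opposite = sum(category == "opposite"),
    n_sites = .N
  ), by = .(chrom, start = floor((pos - 1) / window_bp) * window_bp)]
  w[, end := start + window_bp]
  w[, opposite_rate := ifelse(n_parallel + n_opposite > 0,
                              n_opposite / (n_parallel + n_opposite),
                              NA_real_)]
  setorder(w, chrom, start)
  w[, .(chrom, start, end, n_sites, n_parallel, n_opposite, opposite_rate)]
}

#' Shared absent genes between two samples
#'
#' @param states a [classify_copy_state()] result.
#' @param s1,s2 sample ids.
#' @return Number of genes absent in both.
#' @export
shared_absent_count <- function(states, s1, s2) {
  stopifnot(inherits(states, "copy_state_matrix"))
  sum(states$state[, s1] == "absent" & states$state[, s2] == "absent")
}

#' Simulated crosses and complementation of absent genes
#'
#' Draws random (unordered, distinct-parent) pairs within and between pools,
#' with replacement across draws, and counts for each cross the genes absent
#' in both parents — genes a hybrid would truly lack. Fewer shared-absent
#' genes in B x R crosses than within-pool crosses indicates complementation
#' of gene content between the pools.
#'
#' @param states a [classify_copy_state()] result with pool labels.
#' @param n_per_type crosses drawn per cross type (ignored when
#'   `method = "all_pairs"`).
#' @param seed RNG seed.
#' @param types cross types as 2-column matrix or list of pairs; defaults to
#'   all unordered pool combinations present.
#' @param method `"sample"` draws random pairs with replacement across
#'   draws; `"all_pairs"` enumerates every unordered distinct-parent pair
#'   exhaustively.
#' @return A list: `crosses` (`data.table`: `type`, `parent1`, `parent2`,
#'   `shared_absent`) and `summary` (`data.table` of per-type n, mean,
#'   median and quartiles).
#' @export
simulate_crosses <- function(states, n_per_type = 100L, seed = 1L,
                             types = NULL, method = c("sample", "all_pairs")) {
  method <- match.arg(method)
  stopifnot(inherits(states, "copy_state_matrix"))
  gl <- states$samples$group
  pools <- intersect(c("OPV", "B", "R"), unique(gl))
  if (is.null(types)) {
    types <- list()
    for (i in seq_along(pools)) for (j in i:length(pools))
      types[[length(types) + 1]] <- c(pools[i], pools[j])
  }
  ab <- states$state == "absent"
  ids <- states$samples$sample_id
  set.seed(seed)
  rows <- list()
  for (tp in types) {
    i1 <- which(gl == tp[1]); i2 <- which(gl == tp[2])
    within <- tp[1] == tp[2]
    if ((within && length(i1) < 2) || (!within && (!length(i1) || !length(i2)))) {
      warning("cross type ", paste(tp, collapse = "x"),
              " skipped: not enough samples")
      next
    }
    if (method == "all_pairs") {
      if (within) {
        pr <- t(utils::combn(i1, 2))
      } else {
        pr <- as.matrix(expand.grid(i1, i2))
      }
      p1 <- pr[, 1]; p2 <- pr[, 2]
    } else {
      draw <- function(ix, n) ix[sample.int(length(ix), n, replace = TRUE)]
      p1 <- draw(i1, n_per_type)
      p2 <- draw(i2, n_per_type)
      while (any(same <- p1 == p2)) {
        p2[same] <- draw(i2, sum(same))
      }
    }
    shared <- colSums(ab[, p1, drop = FALSE] & ab[, p2, drop = FALSE])
    rows[[length(rows) + 1]] <- data.table(
      type = paste(tp, collapse = "x"),
      parent1 = ids[p1], parent2 = ids[p2], shared_absent = shared
    )
  }
  crosses <- rbindlist(rows)
  summary <- crosses[, .(
    n = .N, mean = mean(shared_absent), median = median(shared_absent),
    q25 = quantile(shared_absent, 0.25), q75 = quantile(shared_absent, 0.75)
  ), by = type]
  list(crosses = crosses, summary = summary)
}
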