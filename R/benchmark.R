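## Calibration benchmarks on synthetic data with known ground truth.

#' Fraction of called nucleotides outside planted regions
#'
#' The empirical false discovery rate of a call set against ground truth:
#' a false discovery is a called nucleotide that lies outside every planted
#' interval.
#'
#' @param calls A [pps_set()] or `GRanges` of called intervals.
#' @param truth `GRanges` of planted regions.
#' @return Fraction in `[0, 1]`; `NA` when nothing was called.
#' @export
empirical_fdr <- function(calls, truth) {
  gr <- GenomicRanges::reduce(.as_gr(calls), ignore.strand = TRUE)
  if (!length(gr)) return(NA_real_)
  called_nt <- sum(GenomicRanges::width(gr))
  inside <- GenomicRanges::intersect(
    gr, GenomicRanges::reduce(truth, ignore.strand = TRUE),
    ignore.strand = TRUE)
  1 - sum(GenomicRanges::width(inside)) / called_nt
}

#' Nucleotide-level recall of planted regions
#'
#' @param calls A [pps_set()] or `GRanges`.
#' @param truth `GRanges` of planted regions.
#' @return Fraction of planted nucleotides covered by a call.
#' @export
planted_recall <- function(calls, truth) {
  tr <- GenomicRanges::reduce(truth, ignore.strand = TRUE)
  if (!length(tr)) return(NA_real_)
  gr <- GenomicRanges::reduce(.as_gr(calls), ignore.strand = TRUE)
  inside <- GenomicRanges::intersect(gr, tr, ignore.strand = TRUE)
  sum(GenomicRanges::width(inside)) / sum(GenomicRanges::width(tr))
}

#' FDR calibration of the PPS caller on synthetic libraries
#'
#' For each seed, simulates footprint/structure-only library pairs with
#' planted footprints, calls PPSs at the permutation FDR level `q`, and
#' measures the empirical FDR of each call set against the union of planted
#' footprints of the condition. All four control pairs (2 replicates x 2
#' RNase treatments) are evaluated; the per-seed `fdr` is the mean over
#' pairs, since the FDR is a property of each call set (pooling the pairs'
#' independent false calls into one union would measure a different,
#' inflated quantity). `recall` is the nucleotide-level recall of the
#' pooled calls.
#'
#' @param cfg A [sim_config()]; its seed field is overridden per run.
#' @param seeds Integer vector of simulation seeds.
#' @param q FDR level (default 0.05).
#' @return `data.frame` with one row per seed: `seed`, `fdr`, `recall`,
#'   `n_called`.
#' @export
pps_fdr_benchmark <- function(cfg, seeds, q = 0.05) {
  rows <- lapply(seeds, function(sd) {
    cfg$seed <- as.integer(sd)
    sim <- simulate_annotation(cfg)
    libs <- simulate_libraries(sim, cfg)
    truth <- sim$truth$footprints_all$control
    calls <- list()
    fdrs <- numeric(0)
    for (rep_i in 1:2) {
      for (rnase in c("ds", "ss")) {
        fp <- libs[[sprintf("control_rep%d_%s_footprint", rep_i, rnase)]]
        so <- libs[[sprintf("control_rep%d_%s_structure_only", rep_i, rnase)]]
        gr <- call_pps_fdr(fp, so, q = q)$intervals
        calls[[length(calls) + 1L]] <- gr
        if (length(gr)) fdrs <- c(fdrs, empirical_fdr(gr, truth))
      }
    }
    all_calls <- suppressWarnings(do.call(c, calls))
    data.frame(seed = sd,
               fdr = if (length(fdrs)) mean(fdrs) else NA_real_,
               recall = planted_recall(all_calls, truth),
               n_called = length(all_calls))
  })
  do.call(rbind, rows)
}

#' Structure-score recovery of planted paired vs unpaired regions
#'
#' For each seed, simulates the structure-only libraries, computes structure
#' scores from the merged-replicate dsRNA-seq/ssRNA-seq pair and compares
#' the mean score over planted paired regions to planted unpaired regions.
#'
#' @param cfg A [sim_config()]; seed overridden per run.
#' @param seeds Integer vector of seeds.
#' @return `data.frame` per seed: `mean_paired`, `mean_unpaired`,
#'   `recovered` (paired > unpaired).
#' @export
structure_recovery_benchmark <- function(cfg, seeds) {
  rows <- lapply(seeds, function(sd) {
    cfg$seed <- as.integer(sd)
    sim <- simulate_annotation(cfg)
    libs <- simulate_libraries(sim, cfg)
    merge_tracks <- function(a, b)
      nt_track(list(chr1 = a$values$chr1 + b$values$chr1),
               condition = a$meta$condition, rnase = a$meta$rnase,
               sample_type = a$meta$sample_type)
    # dsRNA-seq = ssRNase-treated structure-only; ssRNA-seq = dsRNase-treated
    ds <- merge_tracks(libs$control_rep1_ss_structure_only,
                       libs$control_rep2_ss_structure_only)
    ss <- merge_tracks(libs$control_rep1_ds_structure_only,
                       libs$control_rep2_ds_structure_only)
    sc <- structure_score(ds, ss)
    v <- sc$score$values$chr1
    pr <- sim$truth$paired_regions
    reg_mean <- function(cls) {
      sub <- pr[pr$class == cls]
      if (!length(sub)) return(NA_real_)
      idx <- unlist(lapply(seq_along(sub), function(i)
        GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]))
      mean(v[idx], na.rm = TRUE)
    }
    mp <- reg_mean("paired"); mu <- reg_mean("unpaired")
    data.frame(seed = sd, mean_paired = mp, mean_unpaired = mu,
               recovered = isTRUE(mp > mu))
  })
  do.call(rbind, rows)
}
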