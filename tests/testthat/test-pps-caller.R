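test_that("depth equalization downsamples the larger library only", {
  set.seed(1)
  a <- random_granges(200)
  b <- random_granges(100)
  eq <- equalize_depth(a, b, seed = 3)
  expect_length(eq$a, 100L)
  expect_length(eq$b, 100L)
  # a' is a subset of a; b returned unchanged
  expect_true(all(paste(GenomicRanges::start(eq$a),
                        GenomicRanges::end(eq$a)) %in%
                    paste(GenomicRanges::start(a), GenomicRanges::end(a))))
  expect_identical(eq$b, b)
  # equal sizes: both unchanged; same seed: identical subsample
  eq2 <- equalize_depth(b, b, seed = 3)
  expect_identical(eq2$a, b)
  expect_identical(equalize_depth(a, b, seed = 3), eq)
  expect_error(equalize_depth(a[0], b), "empty")
})

test_that("Poisson enrichment matches brute-force tail summation", {
  # term-by-term pmf oracle for P(Poisson(3) >= 10)
  tail_p <- function(lambda, k) 1 - sum(dpois(0:(k - 1), lambda))
  fp <- toy_track(chr1 = c(10, 0, 5, 2))
  so <- toy_track(chr1 = c(2, 8, 5, 2))
  enr <- poisson_enrichment(fp, so, pseudocount = 1)
  v <- enr$values$chr1
  expect_equal(v[1], -log10(tail_p(3, 10)), tolerance = 1e-10)
  expect_equal(v[2], 0)  # zero footprint coverage scores 0
  expect_equal(v[3], -log10(tail_p(6, 5)), tolerance = 1e-10)
  expect_true(all(v >= 0))
  expect_error(poisson_enrichment(toy_track(chr1 = c(-1, 0)), so),
               "negative")
})

test_that("equal libraries give small, flat enrichment scores", {
  set.seed(8)
  v <- rpois(5000, 50)
  same <- poisson_enrichment(toy_track(chr1 = v), toy_track(chr1 = v))
  expect_lt(max(same$values$chr1), 2)
  expect_lt(mean(same$values$chr1), 0.5)
})

test_that("FDR threshold agrees with an exhaustive scan on toy scores", {
  obs <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  null <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  exhaustive <- function(obs, null, q) {
    cand <- sort(unique(obs))
    for (t in cand) {
      if (sum(null >= t) / sum(obs >= t) <= q) return(t)
    }
    Inf
  }
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    expect_equal(fdr_threshold(obs, null, q), exhaustive(obs, null, q),
                 info = paste("q =", q))
  }
  # all null below all observed: threshold is the minimum observed score
  expect_equal(fdr_threshold(c(5, 6, 7), c(1, 2, 3), 0.05), 5)
  # identical score sets: no threshold reaches q = 0.05
  expect_equal(fdr_threshold(obs, obs, 0.05), Inf)
  expect_error(fdr_threshold(obs, null, q = 0), "q must be")
  expect_error(fdr_threshold(obs, null, q = 1), "q must be")
})

test_that("PPS calling extracts maximal runs at an inclusive threshold", {
  tr <- toy_track(chr1 = c(0, 5, 5, 0, 5))
  ps <- call_pps(tr, threshold = 4)
  expect_length(ps, 2L)
  expect_equal(GenomicRanges::width(ps$intervals), c(2L, 1L))
  expect_equal(ps$intervals$score, c(5, 5))
  # inclusive threshold: boundary scores are kept
  expect_length(call_pps(toy_track(chr1 = c(4, 0)), 4), 1L)
  # nothing above threshold: empty set
  expect_length(call_pps(toy_track(chr1 = c(1, 2, 3)), 10), 0L)
  expect_error(call_pps(tr, Inf), "finite")
})

test_that("interval merging matches brute-force union-find on random sets", {
  set.seed(33)
  for (rep_i in 1:3) {
    gr <- random_granges(200)
    merged <- merge_overlapping(gr)
    oracle <- brute_merge(GenomicRanges::start(gr), GenomicRanges::end(gr))
    expect_equal(GenomicRanges::start(merged), as.integer(oracle[, 1]))
    expect_equal(GenomicRanges::end(merged), as.integer(oracle[, 2]))
  }
  # adjacent but non-overlapping intervals stay separate
  adj <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 11), c(10, 20)))
  expect_length(merge_overlapping(adj), 2L)
})

test_that("high-confidence intersection anchors on replicate 1", {
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50, 100),
                                                        c(10, 60, 110)))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5, 200),
                                                        c(15, 210)))
  hc <- high_confidence(r1, r2)
  expect_length(hc, 1L)
  expect_equal(GenomicRanges::start(hc$intervals), 1L)
  # identical replicates return the full set; disjoint return empty
  expect_length(high_confidence(r1, r1), 3L)
  expect_length(high_confidence(r1, GenomicRanges::shift(r1, 1000)), 0L)
  # one rep1 interval overlapping two rep2 intervals counts once
  r2b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 8), c(4, 12)))
  expect_length(high_confidence(r1[1], r2b), 1L)
})

test_that("condition classification partitions both high-confidence sets", {
  r <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(seq(1, 1000, by = 100),
                                               width = 20))
  cl <- classify_condition(r, r)
  expect_length(cl$shared, length(r))
  expect_length(cl$control_specific, 0L)
  expect_length(cl$salt_specific, 0L)

  set.seed(12)
  ctrl <- random_granges(120, max_pos = 5000)
  salt <- random_granges(80, max_pos = 5000)
  cl2 <- classify_condition(ctrl, salt)
  counts <- cl2$counts
  expect_equal(counts[["control_specific"]] + counts[["shared"]],
               counts[["control_hc"]])
  expect_equal(counts[["salt_specific"]] + counts[["salt_shared"]],
               counts[["salt_hc"]])
})

test_that("greedy feature annotation multi-labels junction intervals", {
  m <- toy_mrna()  # utr5 101-150, cds 151-300, utr3 301-400
  feats <- feature_ranges(list(tx1 = m))
  inside_cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 220))
  junction <- GenomicRanges::GRanges("chr1", IRanges::IRanges(290, 310))
  nowhere <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 920))
  ann <- annotate_features(c(inside_cds, junction, nowhere), feats)
  expect_equal(ann$labels[[1]], "cds")
  expect_equal(ann$labels[[2]], c("cds", "utr3"))
  expect_equal(ann$labels[[3]], "intergenic")
  expect_equal(ann$distribution[["cds"]], 2L)
})

test_that("feature enrichment is zero under proportional coverage", {
  m <- toy_mrna()
  feats <- feature_ranges(list(tx1 = m))
  # PPS covering the whole transcript: observed == expected in every feature
  all_tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400))
  enr <- feature_enrichment(all_tx, feats)
  expect_true(all(abs(enr) < 1e-12))
  # all PPS nucleotides in the CDS; CDS is 50% of annotation => log2 ratio 1
  m2 <- transcript_model("t", "chr1", "+", matrix(c(1L, 300L), ncol = 2),
                         cds_span = c(76L, 225L))
  in_cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 199))
  enr2 <- feature_enrichment(in_cds, feature_ranges(list(t = m2)))
  expect_equal(enr2[["cds"]], 1.0)
  expect_error(feature_enrichment(GenomicRanges::GRanges(), feats), "empty")
})

test_that("conservation comparison uses equal-length flanks and a KS test", {
  # step track: 1 inside the intervals, 0 outside
  v <- rep(0, 1000)
  ivs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(101, 301, 501),
                                                 width = 20))
  for (i in 1:3) v[(GenomicRanges::start(ivs)[i]):(GenomicRanges::end(ivs)[i])] <- 1
  cc <- conservation_compare(ivs, toy_track(chr1 = v))
  expect_equal(cc$pps_mean, rep(1, 3))
  expect_equal(cc$flank5_mean, rep(0, 3))
  expect_equal(cc$ks_stat, 1)

  # constant track: identical distributions, KS statistic 0
  cc0 <- suppressWarnings(
    conservation_compare(ivs, toy_track(chr1 = rep(0.4, 1000))))
  expect_equal(cc0$ks_stat, 0)

  # random track: statistic equals the brute-force ECDF max gap
  set.seed(19)
  rt <- toy_track(chr1 = runif(2000))
  ivr <- random_granges(20, max_pos = 1500, max_width = 25)
  ivr <- GenomicRanges::shift(ivr, 100)
  ccr <- conservation_compare(ivr, rt)
  pooled <- c(ccr$flank5_mean, ccr$flank3_mean)
  grid <- sort(unique(c(ccr$pps_mean, pooled)))
  d_oracle <- max(vapply(grid, function(g)
    abs(mean(ccr$pps_mean <= g) - mean(pooled <= g)), 0))
  expect_equal(ccr$ks_stat, d_oracle, tolerance = 1e-12)

  # intervals whose flanks leave the chromosome are dropped with a record
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 30))
  expect_message(
    cc_edge <- conservation_compare(c(edge, ivs), toy_track(chr1 = v)),
    "dropped")
  expect_equal(cc_edge$n_dropped, 1L)
})

test_that("end-to-end calling controls the empirical FDR on planted data", {
  cfg <- sim_config(n_transcripts = 100, seed = 41)
  sim <- simulate_annotation(cfg)
  libs <- simulate_libraries(sim, cfg)
  calls <- call_pps_fdr(libs$control_rep1_ds_footprint,
                        libs$control_rep1_ds_structure_only, q = 0.05)
  expect_gt(length(calls), 0L)
  expect_lt(empirical_fdr(calls, sim$truth$footprints_all$control), 0.15)
  expect_gt(planted_recall(calls, sim$truth$footprints$control[["1"]]), 0.8)
})

test_that("call sensitivity is non-decreasing in footprint enrichment", {
  recalls <- vapply(c(1.5, 3, 6), function(enr) {
    cfg <- sim_config(n_transcripts = 60, footprint_enrichment = enr,
                      seed = 55)
    sim <- simulate_annotation(cfg)
    libs <- simulate_libraries(sim, cfg)
    calls <- call_pps_fdr(libs$control_rep1_ds_footprint,
                          libs$control_rep1_ds_structure_only)
    r <- planted_recall(calls, sim$truth$footprints$control[["1"]])
    if (is.na(r)) 0 else r
  }, 0)
  expect_true(all(diff(recalls) >= -0.02))
})
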