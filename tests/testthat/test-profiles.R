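test_that("profile column statistics match brute-force computation", {
  mat <- rbind(c(1, 2, NA), c(3, NA, NA), c(5, 4, NA))
  p <- profile_matrix(mat)
  expect_equal(p$mean, c(3, 3, NA))
  expect_equal(p$n, c(3L, 2L, 0L))
  # SEM = sample SD / sqrt(n) over defined entries
  expect_equal(p$sem[1], sd(c(1, 3, 5)) / sqrt(3))
  expect_equal(p$sem[2], sd(c(2, 4)) / sqrt(2))
  expect_true(is.na(p$sem[3]))
})

test_that("max normalization scales the peak of the mean profile to 1", {
  mat <- rbind(c(0, 2, 4), c(0, 2, 4))
  p <- max_normalize(profile_matrix(mat))
  expect_equal(p$mean, c(0, 0.5, 1))
  expect_equal(max(p$matrix), 1)
  expect_equal(p$normalization, "max")
  # all-zero profile is returned unchanged
  p0 <- max_normalize(profile_matrix(matrix(0, 2, 3)))
  expect_equal(p0$mean, c(0, 0, 0))
  expect_equal(p0$normalization, "none")
})

test_that("expression filter thresholds are inclusive at the boundaries", {
  # mRNA with utr5 = 45, utr3 = 140: exactly at the minima, passes
  mk <- function(id, u5, u3, len = 400L) {
    transcript_model(id, "chr1", "+", matrix(c(1L, len), ncol = 2),
                     cds_span = c(u5 + 1L, len - u3))
  }
  models <- list(ok = mk("ok", 45L, 140L),
                 short5 = mk("short5", 44L, 140L),
                 short3 = mk("short3", 45L, 139L))
  cov50 <- toy_track(chr1 = c(rep(50 / 400, 400), rep(0, 100)))
  expect_equal(filter_expressed(models, list(cov50), "mRNA"), "ok")
  # 49 total reads in one library fails the >= 50 requirement
  cov49 <- toy_track(chr1 = c(rep(49 / 400, 400), rep(0, 100)))
  expect_equal(filter_expressed(models, list(cov50, cov49), "mRNA"),
               character(0))

  # lncRNA: >= 5 reads, no UTR requirement
  lnc <- list(l1 = transcript_model("l1", "chr1", "+",
                                    matrix(c(1L, 100L), ncol = 2),
                                    biotype = "lncRNA"))
  cov5 <- toy_track(chr1 = c(rep(0.05, 100), rep(0, 400)))
  cov4 <- toy_track(chr1 = c(rep(0.04, 100), rep(0, 400)))
  expect_equal(filter_expressed(lnc, list(cov5), "lncRNA"), "l1")
  expect_equal(filter_expressed(lnc, list(cov4), "lncRNA"), character(0))
  # biotype mismatch excludes
  expect_equal(filter_expressed(models, list(cov50), "lncRNA"),
               character(0))
})

test_that("occupancy track is the 0/1 union of intervals", {
  ivs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(10, 15, 40), c(20, 25, 45)))
  occ <- occupancy_track(ivs, c(chr1 = 50L))
  v <- occ$values$chr1
  expect_true(all(v %in% c(0, 1)))
  expect_equal(sum(v), (25 - 10 + 1) + (45 - 40 + 1))  # overlap not stacked
  expect_equal(v[9], 0); expect_equal(v[10], 1)
  expect_equal(v[25], 1); expect_equal(v[26], 0)
  expect_equal(sum(occupancy_track(GenomicRanges::GRanges(),
                                   c(chr1 = 50L))$values$chr1), 0)
})

test_that("anchored profiles align rows on the start and stop codons", {
  # toy mRNA: utr5 101-150, cds 151-300 => start codon at spliced pos 51,
  # stop codon first nt at spliced pos 50 + 150 - 2 = 198
  v <- rep(0, 500)
  v[151] <- 7   # genomic position of the start codon's first nt
  v[298] <- 9   # genomic position of the stop codon's first nt (300 - 2)
  tr <- toy_track(chr1 = v)
  models <- list(tx1 = toy_mrna())
  ps <- anchored_profile(tr, models, anchor = "start", flank = 10L)
  expect_equal(unname(ps$matrix[1, ps$positions == 0]), 7)
  expect_equal(unname(ps$mean[ps$positions == 0]), 7)
  pe <- anchored_profile(tr, models, anchor = "stop", flank = 10L)
  expect_equal(unname(pe$matrix[1, pe$positions == 0]), 9)

  # window positions outside the transcript are NA
  pw <- anchored_profile(tr, models, anchor = "start", flank = 60L)
  expect_true(all(is.na(pw$matrix[1, pw$positions < -50])))
  expect_false(anyNA(pw$matrix[1, pw$positions >= -50]))

  # brute-force column stats over a random 3-transcript profile
  set.seed(6)
  v2 <- runif(500)
  mods <- list(tx1 = toy_mrna(),
               tx2 = transcript_model("tx2", "chr1", "+",
                                      matrix(c(51L, 480L), ncol = 2),
                                      cds_span = c(121L, 400L)))
  pp <- anchored_profile(toy_track(chr1 = v2), mods, flank = 5L)
  manual <- rbind(v2[(151 - 5):(151 + 5)], v2[(121 - 5):(121 + 5)])
  expect_equal(unname(pp$matrix), unname(manual))
  expect_equal(unname(pp$mean), colMeans(manual))
})

test_that("floor-partition binning tiles the vector exactly", {
  # L = 250, 100 bins: bins have width 2 or 3 and tile 1..250
  L <- 250L; n_bins <- 100L
  x <- as.numeric(seq_len(L))
  lo <- floor((seq_len(n_bins) - 1) * L / n_bins) + 1
  hi <- floor(seq_len(n_bins) * L / n_bins)
  expect_equal(lo[1], 1); expect_equal(hi[n_bins], L)
  expect_true(all(lo[-1] == hi[-n_bins] + 1))  # no gaps, no overlaps
  manual <- vapply(seq_len(n_bins), function(b) mean(x[lo[b]:hi[b]]), 0)
  p <- binned_profile(list(t = x), scheme = "whole-100")
  expect_equal(unname(p$matrix[1, ]), manual)

  # vector shorter than the bin count: single positions repeat, never error
  p2 <- binned_profile(list(t = c(4, 8)), scheme = "whole-100")
  expect_equal(ncol(p2$matrix), 100L)
  expect_true(all(p2$matrix %in% c(4, 8)))

  # region-split scheme: 300 columns, region means preserved
  m <- toy_mrna()
  tv <- c(rep(1, 50), rep(2, 150), rep(3, 100))
  p3 <- binned_profile(list(tx1 = tv), scheme = "utr5-cds-utr3-100-each",
                       models = list(tx1 = m))
  expect_equal(ncol(p3$matrix), 300L)
  expect_equal(unname(p3$matrix[1, 1:100]), rep(1, 100))
  expect_equal(unname(p3$matrix[1, 101:200]), rep(2, 100))
  expect_equal(unname(p3$matrix[1, 201:300]), rep(3, 100))
  expect_error(binned_profile(list(tx1 = tv),
                              scheme = "utr5-cds-utr3-100-each"),
               "requires models")
})

test_that("window Z-scoring is invariant to affine transforms of the mean", {
  mat <- rbind(c(1, 5, 3, 7, 4))
  z1 <- zscore_window(profile_matrix(mat))
  z2 <- zscore_window(profile_matrix(10 + 2 * mat))
  expect_equal(z1$mean, z2$mean, tolerance = 1e-12)
  # population SD convention: a two-point {-1, +1} profile is fixed
  zf <- zscore_window(profile_matrix(rbind(c(-1, 1))))
  expect_equal(zf$mean, c(-1, 1), tolerance = 1e-12)
  # restricted window: outside entries become NA
  zw <- zscore_window(profile_matrix(mat), window = 2:4)
  expect_true(is.na(zw$mean[1]) && is.na(zw$mean[5]))
  x <- mat[1, 2:4]
  expect_equal(zw$mean[2:4], (x - mean(x)) / sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-12)
})

test_that("peak-centered profiles show the planted 0|1|0 step", {
  v <- rep(0, 1000)
  v[401:440] <- 1
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 440),
                               strand = "+")
  p <- peak_centered_profile(pk, toy_track(chr1 = v), n_bins = 20L)
  expect_equal(unname(p$mean), c(rep(0, 20), rep(1, 20), rep(0, 20)))
  # minus-strand peak is reversed; symmetric step is invariant
  pkm <- pk; GenomicRanges::strand(pkm) <- "-"
  pm <- peak_centered_profile(pkm, toy_track(chr1 = v), n_bins = 20L)
  expect_equal(pm$mean, p$mean)
  # asymmetric signal flips under strand reversal
  v2 <- rep(0, 1000); v2[361:400] <- 5
  pa <- peak_centered_profile(pk, toy_track(chr1 = v2), n_bins = 20L)
  pb <- peak_centered_profile(pkm, toy_track(chr1 = v2), n_bins = 20L)
  expect_equal(unname(pa$mean[1:20]), rep(5, 20))
  expect_equal(unname(pb$mean[41:60]), rep(5, 20))
  # peak too close to the edge is dropped with a message
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 44))
  expect_message(pd <- peak_centered_profile(c(edge, pk),
                                             toy_track(chr1 = v)),
                 "dropped")
  expect_equal(nrow(pd$matrix), 1L)
})

test_that("shuffled peaks satisfy all placement constraints", {
  set.seed(91)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, 9001, by = 1000),
                                                   width = 600))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(101, 9101, by = 1000),
                                                   width = sample(20:80, 10,
                                                                  TRUE)))
  sh <- shuffle_peaks(peaks, genes, seed = 5)
  expect_length(sh, length(peaks))
  expect_equal(GenomicRanges::width(sh), GenomicRanges::width(peaks))
  # wholly inside gene space
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(sh,
                                                       ignore.strand = TRUE),
                                 genes, ignore.strand = TRUE)
  expect_equal(sum(GenomicRanges::width(ov)),
               sum(GenomicRanges::width(GenomicRanges::reduce(sh,
                                                              ignore.strand = TRUE))))
  # pairwise non-overlapping
  expect_equal(sum(GenomicRanges::countOverlaps(sh, sh,
                                                ignore.strand = TRUE)),
               length(sh))
  # deterministic under the seed; impossible placements error
  expect_identical(shuffle_peaks(peaks, genes, seed = 5), sh)
  tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  expect_error(shuffle_peaks(peaks[1], tiny, seed = 1), "no gene space")
})

test_that("profiles over shuffled peaks are flat where real peaks are not", {
  cfg <- sim_config(n_transcripts = 120, seed = 35)
  sim <- simulate_annotation(cfg)
  m6a <- sim$truth$m6a$salt
  occ <- occupancy_track(m6a, sim$seqlengths)
  genes <- do.call(c, unname(lapply(sim$models, model_span)))
  real <- peak_centered_profile(m6a, occ, n_bins = 20L)
  shuf_pk <- shuffle_peaks(m6a, genes, seed = 77)
  shuf <- suppressMessages(peak_centered_profile(shuf_pk, occ, n_bins = 20L))
  # real peaks: center bins saturate at 1, flanks are lower
  expect_equal(unname(real$mean[21:40]), rep(1, 20))
  expect_lt(mean(real$mean[c(1:20, 41:60)]), 0.5)
  # shuffled peaks carry no systematic center enrichment:
  # center mean within 3 SE of flank mean
  center <- mean(shuf$mean[21:40])
  flank <- mean(shuf$mean[c(1:20, 41:60)])
  se <- sqrt(mean(shuf$sem[21:40]^2, na.rm = TRUE) / 20 +
               mean(shuf$sem[c(1:20, 41:60)]^2, na.rm = TRUE) / 40)
  expect_lt(abs(center - flank), 3 * se + 0.05)
})
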