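## Protein-protected site (PPS) calling.
##
## Footprint vs structure-only library pairs are compared per nucleotide with
## an upper-tail Poisson test; sites are thresholded at a permutation
## (label-swap) false discovery rate, merged, intersected across replicates
## and classified by condition.

#' Equalize sequencing depth of two read interval sets
#'
#' The larger library is randomly reduced (simple random sampling without
#' replacement, seeded) to contain the same number of reads as the smaller.
#'
#' @param lib_a,lib_b `GRanges` of read intervals.
#' @param seed Integer seed.
#' @return List with elements `a` and `b`, each a subset of the input.
#' @export
equalize_depth <- function(lib_a, lib_b, seed = 1L) {
  if (length(lib_a) == 0L || length(lib_b) == 0L)
    stop("cannot equalize an empty library")
  n <- min(length(lib_a), length(lib_b))
  set.seed(seed)
  if (length(lib_a) > n) lib_a <- lib_a[sort(sample(length(lib_a), n))]
  if (length(lib_b) > n) lib_b <- lib_b[sort(sample(length(lib_b), n))]
  list(a = lib_a, b = lib_b)
}

#' Per-nucleotide Poisson enrichment of footprint over structure-only
#'
#' At each position the enrichment score is the upper-tail Poisson p-value of
#' the footprint coverage under a rate equal to the structure-only coverage
#' plus a pseudocount, on the -log10 scale:
#' `score_i = -log10 P(Poisson(s_i + pseudocount) >= f_i)`.
#' Positions with zero footprint coverage score 0.
#'
#' @param footprint,structure_only [nt_track()]s of equal layout (depth-
#'   equalized upstream).
#' @param pseudocount Added to the structure-only rate (default 1); avoids a
#'   zero-rate degeneracy.
#' @return An [nt_track()] of enrichment scores (all >= 0).
#' @export
poisson_enrichment <- function(footprint, structure_only, pseudocount = 1) {
  track_check_coverage(footprint)
  track_check_coverage(structure_only)
  sl_f <- track_seqlengths(footprint)
  sl_s <- track_seqlengths(structure_only)
  if (!identical(sl_f[sort(names(sl_f))], sl_s[sort(names(sl_s))]))
    stop("footprint and structure-only tracks differ in layout")
  values <- lapply(names(footprint$values), function(chr) {
    f <- footprint$values[[chr]]
    s <- structure_only$values[[chr]]
    sc <- -stats::ppois(f - 1, lambda = s + pseudocount,
                        lower.tail = FALSE, log.p = TRUE) / log(10)
    sc[f == 0] <- 0
    sc
  })
  names(values) <- names(footprint$values)
  nt_track(values, condition = footprint$meta$condition,
           replicate = footprint$meta$replicate,
           rnase = footprint$meta$rnase, sample_type = "enrichment")
}

.track_scores <- function(track) {
  unlist(track$values, use.names = FALSE)
}

#' Permutation FDR threshold for enrichment scores
#'
#' The null track is the label swap of the same pair (structure-only tested
#' against footprint). The threshold is the smallest observed score `t` such
#' that `#{null >= t} / #{observed >= t} <= q`; `Inf` if no such score
#' exists.
#'
#' @param observed,null Enrichment [nt_track()]s (or numeric vectors).
#' @param q Target false discovery rate, in (0, 1). Default 0.05.
#' @return Numeric threshold (possibly `Inf`).
#' @export
fdr_threshold <- function(observed, null, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must be a single value in (0, 1)")
  o <- if (inherits(observed, "nt_track")) .track_scores(observed)
  else as.numeric(observed)
  n <- if (inherits(null, "nt_track")) .track_scores(null)
  else as.numeric(null)
  so <- sort(o)
  sn <- sort(n)
  cand <- unique(so)
  # counts >= t for each candidate, via counts < t on the sorted arrays
  o_ge <- length(so) - findInterval(cand, so, left.open = TRUE)
  n_ge <- length(sn) - findInterval(cand, sn, left.open = TRUE)
  ok <- n_ge / o_ge <= q
  if (!any(ok)) return(Inf)
  cand[which(ok)[1L]]
}

#' A set of called PPS intervals
#'
#' @param intervals `GRanges` with a `score` column (per-interval maximum
#'   enrichment score).
#' @param threshold Score threshold used.
#' @param q FDR level the threshold was derived at (or `NA`).
#' @param label One of `replicate-level`, `high-confidence`,
#'   `control-specific`, `salt-specific`, `shared`.
#' @return Object of class `pps_set`.
#' @export
pps_set <- function(intervals, threshold = NA_real_, q = NA_real_,
                    label = "replicate-level") {
  structure(list(intervals = intervals, threshold = threshold, q = q,
                 label = label),
            class = "pps_set")
}

#' @export
print.pps_set <- function(x, ...) {
  cat("pps_set [", x$label, "]: ", length(x$intervals), " intervals",
      if (!is.na(x$threshold)) sprintf(" (threshold %.3g)", x$threshold),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.pps_set <- function(x) length(x$intervals)

.as_gr <- function(x) {
  if (inherits(x, "pps_set")) x$intervals
  else if (is(x, "GRanges")) x
  else stop("expected a pps_set or GRanges")
}

#' Call PPSs from an enrichment track at a threshold
#'
#' Maximal runs of consecutive positions with score at or above the
#' (inclusive) threshold become intervals; overlapping intervals are merged;
#' adjacent but non-overlapping runs stay separate. The per-interval maximum
#' score is retained.
#'
#' @param track Enrichment [nt_track()].
#' @param threshold Inclusive score threshold (finite).
#' @return A [pps_set()] with label `replicate-level`.
#' @export
call_pps <- function(track, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  grs <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    r <- rle(v >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    gr <- GenomicRanges::GRanges(chr,
                                 IRanges::IRanges(starts[keep], ends[keep]))
    gr$score <- vapply(seq_along(gr), function(i)
      max(v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]]), 0)
    gr
  })
  grs <- Filter(Negate(is.null), grs)
  gr <- if (length(grs)) suppressWarnings(do.call(c, unname(grs)))
  else GenomicRanges::GRanges(score = numeric(0))
  gr$name <- if (length(gr)) paste0("pps", seq_along(gr)) else character(0)
  pps_set(gr, threshold = threshold)
}

#' Merge intervals overlapping by at least one nucleotide
#'
#' Strictly overlapping intervals are unioned; adjacent (gap >= 1 nt)
#' intervals stay separate. The maximum score over merged members is kept.
#'
#' @param gr `GRanges`, optionally with a `score` column.
#' @return Merged `GRanges`.
#' @export
merge_overlapping <- function(gr) {
  if (!length(gr)) return(gr)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  if (!is.null(gr$score)) {
    ov <- GenomicRanges::findOverlaps(red, gr, ignore.strand = TRUE)
    agg <- tapply(gr$score[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), max)
    red$score <- as.numeric(agg[as.character(seq_along(red))])
  }
  red
}

#' High-confidence PPSs across two replicates
#'
#' Returns the replicate-1 intervals sharing at least one nucleotide with
#' some replicate-2 interval (anchor-replicate convention: the returned
#' geometry is replicate 1's).
#'
#' @param rep1,rep2 [pps_set()]s (or `GRanges`) from the two biological
#'   replicates of one condition.
#' @return A [pps_set()] with label `high-confidence`.
#' @export
high_confidence <- function(rep1, rep2) {
  g1 <- .as_gr(rep1)
  g2 <- .as_gr(rep2)
  keep <- IRanges::overlapsAny(g1, g2, minoverlap = 1L, ignore.strand = TRUE)
  pps_set(g1[keep],
          threshold = if (inherits(rep1, "pps_set")) rep1$threshold
          else NA_real_,
          label = "high-confidence")
}

#' Classify high-confidence PPSs by condition
#'
#' `shared` PPSs are control intervals overlapping some salt interval by at
#' least one nucleotide (anchored on the control geometry); the specific
#' sets are the non-overlapping remainders on each side.
#'
#' @param control_hc,salt_hc High-confidence [pps_set()]s (or `GRanges`).
#' @return List with `control_specific`, `salt_specific`, `shared`
#'   ([pps_set()]s) and `counts` (named integer vector including the shared
#'   fraction of the salt set as a percentage).
#' @export
classify_condition <- function(control_hc, salt_hc) {
  gc_ <- .as_gr(control_hc)
  gs <- .as_gr(salt_hc)
  ov_c <- IRanges::overlapsAny(gc_, gs, minoverlap = 1L, ignore.strand = TRUE)
  ov_s <- IRanges::overlapsAny(gs, gc_, minoverlap = 1L, ignore.strand = TRUE)
  shared <- pps_set(gc_[ov_c], label = "shared")
  ctrl_sp <- pps_set(gc_[!ov_c], label = "control-specific")
  salt_sp <- pps_set(gs[!ov_s], label = "salt-specific")
  counts <- c(control_hc = length(gc_), salt_hc = length(gs),
              shared = sum(ov_c), control_specific = sum(!ov_c),
              salt_specific = sum(!ov_s), salt_shared = sum(ov_s))
  frac <- if (length(gs)) 100 * sum(ov_s) / length(gs) else NA_real_
  list(control_specific = ctrl_sp, salt_specific = salt_sp, shared = shared,
       counts = counts, shared_pct_of_salt = frac)
}

#' End-to-end PPS calling for one footprint/structure-only pair
#'
#' Computes the Poisson enrichment track, the label-swap null, the
#' permutation FDR threshold at `q`, and the merged replicate-level calls.
#'
#' @param footprint,structure_only [nt_track()]s.
#' @param q FDR level (default 0.05).
#' @param pseudocount Poisson rate pseudocount (default 1).
#' @return A [pps_set()]; the `q` field records the level and `threshold`
#'   the derived score cutoff (calls are empty when the threshold is
#'   infinite).
#' @export
call_pps_fdr <- function(footprint, structure_only, q = 0.05,
                         pseudocount = 1) {
  obs <- poisson_enrichment(footprint, structure_only, pseudocount)
  null <- poisson_enrichment(structure_only, footprint, pseudocount)
  thr <- fdr_threshold(obs, null, q)
  if (!is.finite(thr)) {
    out <- pps_set(GenomicRanges::GRanges(score = numeric(0)),
                   threshold = thr, q = q)
    return(out)
  }
  out <- call_pps(obs, thr)
  out$q <- q
  out
}

#' Greedy feature annotation of called intervals
#'
#' Each interval receives every feature label it overlaps (5'UTR, CDS,
#' 3'UTR, intron, lncRNA, ...); intervals in unannotated space are labelled
#' `intergenic`. The summary distribution counts every label occurrence with
#' equal weight.
#'
#' @param pps A [pps_set()] or `GRanges`.
#' @param models Annotation (list of [transcript_model()]) or a
#'   [feature_ranges()] `GRanges`.
#' @return List with `labels` (list of character vectors, one per interval)
#'   and `distribution` (named label-occurrence counts).
#' @export
annotate_features <- function(pps, models) {
  gr <- .as_gr(pps)
  feats <- if (is(models, "GRanges")) models else feature_ranges(models)
  ov <- GenomicRanges::findOverlaps(gr, feats, ignore.strand = TRUE)
  labels <- rep(list(character(0)), length(gr))
  if (length(ov)) {
    sp <- split(feats$feature[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    for (k in names(sp)) labels[[as.integer(k)]] <- unique(sp[[k]])
  }
  labels <- lapply(labels, function(x)
    if (length(x)) sort(x) else "intergenic")
  distribution <- sort(table(unlist(labels)), decreasing = TRUE)
  list(labels = labels, distribution = c(distribution))
}

#' Feature enrichment of PPS-covered nucleotides
#'
#' Per feature, compares the fraction of PPS-covered nucleotides falling in
#' that feature to the fraction of annotated transcriptome nucleotides the
#' feature occupies, as a log2 ratio. Features with zero annotated
#' nucleotides get `NA`.
#'
#' @param pps A [pps_set()] or `GRanges` (nonempty).
#' @param models Annotation (list of [transcript_model()]) or
#'   [feature_ranges()] output.
#' @return Named numeric vector of log2(observed/expected) per feature.
#' @export
feature_enrichment <- function(pps, models) {
  gr <- GenomicRanges::reduce(.as_gr(pps), ignore.strand = TRUE)
  if (!length(gr)) stop("empty PPS set")
  feats <- if (is(models, "GRanges")) models else feature_ranges(models)
  types <- sort(unique(feats$feature))
  ann_nt <- obs_nt <- setNames(numeric(length(types)), types)
  for (ty in types) {
    fr <- GenomicRanges::reduce(feats[feats$feature == ty],
                                ignore.strand = TRUE)
    ann_nt[ty] <- sum(GenomicRanges::width(fr))
    inter <- GenomicRanges::intersect(gr, fr, ignore.strand = TRUE)
    obs_nt[ty] <- sum(GenomicRanges::width(inter))
  }
  obs_frac <- obs_nt / sum(GenomicRanges::width(gr))
  exp_frac <- ann_nt / sum(ann_nt)
  out <- log2(obs_frac / exp_frac)
  out[ann_nt == 0] <- NA_real_
  out
}

#' Compare conservation of PPSs to equal-sized flanks
#'
#' For each interval, the mean of a conservation track over the interval is
#' compared to the means over flanking regions of exactly the interval's
#' length on the 5' and 3' side; a two-sample Kolmogorov-Smirnov test
#' compares the interval-mean distribution to the pooled flank-mean
#' distribution. Intervals whose flanks run off the chromosome are dropped.
#'
#' @param pps A [pps_set()] or `GRanges`.
#' @param cons Conservation [nt_track()].
#' @return List with `pps_mean`, `flank5_mean`, `flank3_mean` (aligned
#'   numeric vectors), `ks_stat`, `p_value`, `n_dropped`.
#' @export
conservation_compare <- function(pps, cons) {
  gr <- .as_gr(pps)
  pm <- f5 <- f3 <- numeric(0)
  dropped <- 0L
  for (i in seq_along(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    v <- cons$values[[chr]]
    s <- GenomicRanges::start(gr)[i]
    e <- GenomicRanges::end(gr)[i]
    w <- e - s + 1L
    if (is.null(v) || s - w < 1L || e + w > length(v)) {
      dropped <- dropped + 1L
      next
    }
    pm <- c(pm, mean(v[s:e], na.rm = TRUE))
    f5 <- c(f5, mean(v[(s - w):(s - 1L)], na.rm = TRUE))
    f3 <- c(f3, mean(v[(e + 1L):(e + w)], na.rm = TRUE))
  }
  if (dropped > 0L)
    message(dropped, " interval(s) dropped: flank beyond chromosome edge")
  ks <- if (length(pm) >= 1L)
    suppressWarnings(stats::ks.test(pm, c(f5, f3)))
  else list(statistic = NA_real_, p.value = NA_real_)
  list(pps_mean = pm, flank5_mean = f5, flank3_mean = f3,
       ks_stat = unname(ks$statistic), p_value = ks$p.value,
       n_dropped = dropped)
}
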