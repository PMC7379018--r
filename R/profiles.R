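## Metagene and peak-centered profiles.
##
## Profiles are transcripts-by-positions matrices of occupancy (0/1) or
## scores, aligned on the start/stop codon, binned to fixed length, or
## centered on peaks with equal-sized flanks. Undefined entries (outside the
## transcript, or zero-coverage structure positions) are NA and excluded
## from column statistics.

#' Construct a profile matrix
#'
#' @param mat Numeric matrix, rows = transcripts/peaks, columns = positions
#'   or bins (`NA` allowed).
#' @param positions Column coordinates (relative positions or bin index).
#' @param anchor Anchor description (`start`, `stop`, `binned`,
#'   `peak-centered`).
#' @param normalization Normalization record (`"none"` or `"max"`).
#' @return Object of class `profile_matrix` with per-column `mean`, `sem`
#'   and `n` computed over defined entries.
#' @export
profile_matrix <- function(mat, positions = seq_len(ncol(mat)),
                           anchor = "start", normalization = "none") {
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdc <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 0, sdc / sqrt(n), NA_real_)
  structure(list(matrix = mat, positions = positions, anchor = anchor,
                 mean = mu, sem = sem, n = n,
                 normalization = normalization),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix [", x$anchor, "]: ", nrow(x$matrix), " rows x ",
      ncol(x$matrix), " positions (normalization: ", x$normalization,
      ")\n", sep = "")
  invisible(x)
}

#' Max-normalize a profile
#'
#' Scales the mean profile (and SEM) so the highest position within the
#' window equals 1.0; applied to occupancy/density profiles. A profile with
#' no positive value is returned unchanged.
#'
#' @param profile A [profile_matrix()].
#' @return The normalized [profile_matrix()].
#' @export
max_normalize <- function(profile) {
  mx <- suppressWarnings(max(profile$mean, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) return(profile)
  profile$mean <- profile$mean / mx
  profile$sem <- profile$sem / mx
  profile$matrix <- profile$matrix / mx
  profile$normalization <- "max"
  profile
}

#' Expression filter for profile transcripts
#'
#' mRNAs pass when the summed coverage over the spliced transcript reaches
#' `min_reads` (default 50) in every supplied library and the 5'UTR is at
#' least 45 nt and the 3'UTR at least 140 nt. lncRNAs pass with at least 5
#' in every library and no UTR requirement. Thresholds are inclusive.
#'
#' @param models List of [transcript_model()].
#' @param libraries List of [nt_track()] coverage libraries (all conditions
#'   and replicates to be required).
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @param min_reads Coverage threshold; defaults to 50 for mRNA and 5 for
#'   lncRNA.
#' @param min_utr5,min_utr3 UTR length minima for mRNAs (nt).
#' @return Character vector of passing transcript ids.
#' @export
filter_expressed <- function(models, libraries,
                             biotype = c("mRNA", "lncRNA"),
                             min_reads = NULL, min_utr5 = 45L,
                             min_utr3 = 140L) {
  biotype <- match.arg(biotype)
  if (is.null(min_reads)) min_reads <- if (biotype == "mRNA") 50 else 5
  keep <- vapply(models, function(m) {
    if (m$biotype != biotype) return(FALSE)
    if (biotype == "mRNA" &&
        (m$utr5_len < min_utr5 || m$utr3_len < min_utr3)) return(FALSE)
    for (lib in libraries) {
      tot <- sum(genomic_to_transcript(m, lib), na.rm = TRUE)
      if (tot < min_reads) return(FALSE)
    }
    TRUE
  }, TRUE)
  names(models)[keep]
}

#' Binary occupancy track from an interval set
#'
#' Assigns 1 to every nucleotide covered by at least one interval and 0
#' elsewhere (overlaps do not stack).
#'
#' @param intervals `GRanges` (e.g. PPSs or m6A peaks).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return An [nt_track()] of 0/1 values.
#' @export
occupancy_track <- function(intervals, seqlengths) {
  values <- lapply(seqlengths, function(n) numeric(n))
  if (length(intervals)) {
    red <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
    for (i in seq_along(red)) {
      chr <- as.character(GenomicRanges::seqnames(red))[i]
      if (!chr %in% names(values)) next
      s <- GenomicRanges::start(red)[i]
      e <- min(GenomicRanges::end(red)[i], seqlengths[[chr]])
      values[[chr]][s:e] <- 1
    }
  }
  nt_track(values)
}

#' Start/stop-codon anchored metagene profile
#'
#' Rows are transcripts projected into spliced transcript space and aligned
#' on the first nucleotide of the start codon (or of the stop codon);
#' positions outside the transcript are undefined. Occupancy profiles are
#' typically max-normalized per window; structure profiles are
#' transcript-mean-normalized upstream.
#'
#' @param track [nt_track()] of genomic values.
#' @param models List of [transcript_model()] (mRNAs) to include.
#' @param anchor `"start"` or `"stop"`.
#' @param flank Window half-width in nt (default 100).
#' @param normalize `"none"` (default) or `"max"`.
#' @param transcript_values Optional named list of precomputed transcript-
#'   space vectors (e.g. from [normalize_by_transcript_mean()]); overrides
#'   `track`.
#' @return A [profile_matrix()] with `positions` relative to the anchor.
#' @export
anchored_profile <- function(track, models, anchor = c("start", "stop"),
                             flank = 100L, normalize = c("none", "max"),
                             transcript_values = NULL) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  width <- 2L * flank + 1L
  mat <- matrix(NA_real_, nrow = length(models), ncol = width,
                dimnames = list(names(models), NULL))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (m$biotype != "mRNA") next
    v <- if (!is.null(transcript_values)) transcript_values[[m$transcript_id]]
    else genomic_to_transcript(m, track)
    a <- if (anchor == "start") m$utr5_len + 1L
    else m$utr5_len + m$cds_len - 2L
    pos <- (a - flank):(a + flank)
    ok <- pos >= 1L & pos <= m$spliced_length
    mat[i, ok] <- v[pos[ok]]
  }
  p <- profile_matrix(mat, positions = -flank:flank, anchor = anchor)
  if (normalize == "max") p <- max_normalize(p)
  p
}

# mean over a floor-partition bin; empty partitions repeat a single position
.bin_vector <- function(x, n_bins) {
  L <- length(x)
  vapply(seq_len(n_bins) - 1L, function(b) {
    lo <- floor(b * L / n_bins) + 1L
    hi <- floor((b + 1L) * L / n_bins)
    if (hi < lo) hi <- lo
    lo <- min(lo, L); hi <- min(hi, L)
    xx <- x[lo:hi]
    if (all(is.na(xx))) NA_real_ else mean(xx, na.rm = TRUE)
  }, 0)
}

#' Binned whole-transcript or region-split profile
#'
#' With `scheme = "whole-100"` each transcript-space vector is divided into
#' 100 equal-sized bins (floor partition); with
#' `scheme = "utr5-cds-utr3-100-each"` the 5'UTR, CDS and 3'UTR are each
#' binned to 100 bins and concatenated (requires `models`). Regions shorter
#' than the bin count yield repeated single-position bins.
#'
#' @param values Named list of transcript-space numeric vectors.
#' @param scheme Binning scheme.
#' @param models List of [transcript_model()] (needed for the region-split
#'   scheme, to locate region boundaries).
#' @param n_bins Bins per region (default 100).
#' @param normalize `"none"` (default) or `"max"`.
#' @return A [profile_matrix()] with anchor `binned`.
#' @export
binned_profile <- function(values,
                           scheme = c("whole-100", "utr5-cds-utr3-100-each"),
                           models = NULL, n_bins = 100L,
                           normalize = c("none", "max")) {
  scheme <- match.arg(scheme)
  normalize <- match.arg(normalize)
  ids <- names(values)
  if (scheme == "whole-100") {
    mat <- t(vapply(values, .bin_vector, numeric(n_bins), n_bins = n_bins))
    pos <- seq_len(n_bins)
  } else {
    if (is.null(models)) stop("region-split binning requires models")
    mat <- t(vapply(ids, function(id) {
      m <- models[[id]]
      v <- values[[id]]
      u5 <- m$utr5_len; cd <- m$cds_len
      segs <- list(v[seq_len(u5)],
                   v[(u5 + 1L):(u5 + cd)],
                   v[(u5 + cd + 1L):m$spliced_length])
      unlist(lapply(segs, .bin_vector, n_bins = n_bins))
    }, numeric(3L * n_bins)))
    pos <- seq_len(3L * n_bins)
  }
  rownames(mat) <- ids
  p <- profile_matrix(mat, positions = pos, anchor = "binned")
  if (normalize == "max") p <- max_normalize(p)
  p
}

#' Z-score a profile within a window
#'
#' Replaces the mean profile by its Z-score with respect to the declared
#' window (population SD over defined entries; zero SD gives zeros).
#' Entries outside the window are set to `NA`.
#'
#' @param profile A [profile_matrix()].
#' @param window Integer column indices of the window (default: all).
#' @return The Z-scored [profile_matrix()].
#' @export
zscore_window <- function(profile, window = NULL) {
  if (is.null(window)) window <- seq_along(profile$mean)
  x <- profile$mean[window]
  def <- !is.na(x)
  out <- rep(NA_real_, length(profile$mean))
  if (any(def)) {
    m <- mean(x[def])
    s <- sqrt(mean((x[def] - m)^2))
    z <- x
    z[def] <- if (s == 0) 0 else (x[def] - m) / s
    out[window] <- z
    profile$sem[window] <- if (s == 0) 0 else profile$sem[window] / s
  }
  profile$sem[-window] <- NA_real_
  profile$mean <- out
  profile$normalization <- paste0(profile$normalization, "+zscore")
  profile
}

#' Peak-centered profile with equal-sized flanks
#'
#' Each row is `[5' flank | peak | 3' flank]` where the flanks have exactly
#' the peak's length, each third binned to `n_bins` bins. Rows are oriented
#' 5' to 3' (minus-strand peaks reversed). Peaks whose flanks run off the
#' chromosome are dropped with a message.
#'
#' @param peaks `GRanges`.
#' @param track [nt_track()] of genomic values.
#' @param n_bins Bins per third (default 20).
#' @param normalize `"none"` (default) or `"max"` (applied across the full
#'   row, for occupancy profiles).
#' @return A [profile_matrix()] with anchor `peak-centered` and
#'   `3 * n_bins` columns.
#' @export
peak_centered_profile <- function(peaks, track, n_bins = 20L,
                                  normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  rows <- list()
  dropped <- 0L
  for (i in seq_along(peaks)) {
    chr <- as.character(GenomicRanges::seqnames(peaks))[i]
    v <- track$values[[chr]]
    s <- GenomicRanges::start(peaks)[i]
    e <- GenomicRanges::end(peaks)[i]
    w <- e - s + 1L
    if (is.null(v) || s - w < 1L || e + w > length(v)) {
      dropped <- dropped + 1L
      next
    }
    thirds <- list(v[(s - w):(s - 1L)], v[s:e], v[(e + 1L):(e + w)])
    if (as.character(GenomicRanges::strand(peaks))[i] == "-")
      thirds <- lapply(rev(thirds), rev)
    rows[[length(rows) + 1L]] <-
      unlist(lapply(thirds, .bin_vector, n_bins = n_bins))
  }
  if (dropped > 0L)
    message(dropped, " peak(s) dropped: flank beyond chromosome edge")
  mat <- if (length(rows)) do.call(rbind, rows)
  else matrix(NA_real_, 0L, 3L * n_bins)
  p <- profile_matrix(mat, positions = seq_len(3L * n_bins),
                      anchor = "peak-centered")
  if (normalize == "max") p <- max_normalize(p)
  p
}

#' Shuffle peaks within genes as a positional control
#'
#' Re-places each peak uniformly at random (rejection sampling, seeded)
#' wholly inside a gene interval on its original chromosome, preserving
#' count and lengths, with shuffled peaks pairwise non-overlapping.
#'
#' @param peaks `GRanges` to shuffle.
#' @param genes `GRanges` of allowed placement regions.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per peak before failing.
#' @return `GRanges` of shuffled peaks (original order preserved).
#' @export
shuffle_peaks <- function(peaks, genes, seed = 1L, max_tries = 1000L) {
  set.seed(seed)
  genes <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  placed <- matrix(numeric(0), ncol = 2L)
  placed_chr <- character(0)
  out_s <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    chr <- as.character(GenomicRanges::seqnames(peaks))[i]
    w <- GenomicRanges::width(peaks)[i]
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == chr]
    slots <- GenomicRanges::width(g) - w + 1L
    ok <- slots > 0L
    if (!any(ok))
      stop("no gene space for a ", w, " nt peak on ", chr)
    g <- g[ok]; slots <- slots[ok]
    success <- FALSE
    for (try in seq_len(max_tries)) {
      j <- if (length(g) == 1L) 1L else sample(length(g), 1L, prob = slots)
      s <- GenomicRanges::start(g)[j] +
        sample.int(slots[j], 1L) - 1L
      e <- s + w - 1L
      same_chr <- placed_chr == chr
      if (!any(same_chr & s <= placed[, 2L] & e >= placed[, 1L])) {
        placed <- rbind(placed, c(s, e))
        placed_chr <- c(placed_chr, chr)
        out_s[i] <- s
        success <- TRUE
        break
      }
    }
    if (!success)
      stop("could not place shuffled peak without overlap on ", chr)
  }
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(peaks)),
                         IRanges::IRanges(out_s,
                                          width = GenomicRanges::width(peaks)),
                         strand = GenomicRanges::strand(peaks))
}
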