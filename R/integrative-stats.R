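## Cross-assay integration: abundance, stability (proportion uncapped),
## protein output, m6A dynamics and the stratified comparisons that link
## them to structure changes.

#' Reads per million
#'
#' `RPM = counts * 1e6 / library_total`. Zero counts are replaced by a
#' pseudocount before scaling so downstream log-ratios stay defined.
#'
#' @param counts Numeric vector of per-transcript counts.
#' @param library_total Library size (defaults to `sum(counts)`).
#' @param pseudocount Count substituted for zeros (default 0.5).
#' @return Numeric vector of RPM values.
#' @export
rpm <- function(counts, library_total = sum(counts), pseudocount = 0.5) {
  if (library_total <= 0) stop("library_total must be > 0")
  pmax(counts, pseudocount) * 1e6 / library_total
}

#' Abundance fold change between conditions
#'
#' `log2(RPM_salt / RPM_control)`.
#'
#' @param rpm_control,rpm_salt RPM vectors on matching transcripts.
#' @return Numeric vector of log2 fold changes.
#' @export
abundance_fold_change <- function(rpm_control, rpm_salt) {
  log2(rpm_salt / rpm_control)
}

#' Proportion uncapped
#'
#' The log2 ratio of degradome (GMUCT) RPM to mRNA-seq RPM for the same
#' transcript; higher values indicate a less stable transcript. Invariant
#' under common library-size rescaling.
#'
#' @param gmuct_rpm,mrna_rpm RPM vectors on matching transcripts.
#' @return Numeric vector of log2(GMUCT/mRNA) values.
#' @export
proportion_uncapped <- function(gmuct_rpm, mrna_rpm) {
  log2(gmuct_rpm / mrna_rpm)
}

#' Stability classification from proportion-uncapped change
#'
#' The fold change is the salt PU minus the control PU (a log-domain
#' difference). Positive fold change (more uncapped in salt) is
#' `destabilized-in-salt`, negative is `stabilized-in-salt`, exactly zero is
#' `unchanged`.
#'
#' @param pu_control,pu_salt Proportion-uncapped vectors.
#' @return List with `fold_change` and `class` (character vector).
#' @export
stability_class <- function(pu_control, pu_salt) {
  fc <- pu_salt - pu_control
  cls <- ifelse(is.na(fc), NA_character_,
                ifelse(fc > 0, "destabilized-in-salt",
                       ifelse(fc < 0, "stabilized-in-salt", "unchanged")))
  list(fold_change = fc, class = cls)
}

#' Per-transcript stats table from count tables
#'
#' Convenience constructor: computes per-condition RPM (replicates
#' averaged), proportion uncapped, its fold change and the stability class,
#' and the mRNA abundance fold change.
#'
#' @param mrna_counts,gmuct_counts Data frames with `transcript_id` and
#'   `<condition>_rep<r>` columns.
#' @param pseudocount Zero-count substitute (see [rpm()]).
#' @return `data.frame` keyed by `transcript_id`.
#' @export
transcript_stats <- function(mrna_counts, gmuct_counts, pseudocount = 0.5) {
  stopifnot(identical(mrna_counts$transcript_id, gmuct_counts$transcript_id))
  cond_rpm <- function(tab, cond) {
    cols <- grep(paste0("^", cond, "_rep"), names(tab), value = TRUE)
    if (!length(cols)) stop("no replicate columns for condition ", cond)
    reps <- vapply(cols, function(cl) rpm(tab[[cl]],
                                          library_total = sum(tab[[cl]]),
                                          pseudocount = pseudocount),
                   numeric(nrow(tab)))
    rowMeans(reps)
  }
  m_c <- cond_rpm(mrna_counts, "control"); m_s <- cond_rpm(mrna_counts, "salt")
  g_c <- cond_rpm(gmuct_counts, "control"); g_s <- cond_rpm(gmuct_counts, "salt")
  pu_c <- proportion_uncapped(g_c, m_c)
  pu_s <- proportion_uncapped(g_s, m_s)
  st <- stability_class(pu_c, pu_s)
  data.frame(transcript_id = mrna_counts$transcript_id,
             rpm_mrna_control = m_c, rpm_mrna_salt = m_s,
             rpm_gmuct_control = g_c, rpm_gmuct_salt = g_s,
             pu_control = pu_c, pu_salt = pu_s,
             pu_fold_change = st$fold_change,
             stability_class = st$class,
             abundance_fc = abundance_fold_change(m_c, m_s))
}

#' Protein fold change from an intensity table
#'
#' Run intensities are normalized within each run (by run total or median of
#' detected values); proteins are retained only when detected (nonzero) in
#' at least `min_reps` replicates of each condition; the fold change is the
#' log2 ratio of mean normalized intensity in salt over control (means over
#' detected runs).
#'
#' @param tab `data.frame` with `protein_id`, `control_run*` and
#'   `salt_run*` columns (iBAQ-style intensities; 0 = not detected).
#' @param normalization `"total"` (default) or `"median"`.
#' @param min_reps Minimum detected replicates per condition (default 2).
#' @return `data.frame` with `protein_id` and `protein_fc` for retained
#'   proteins; attribute `n_dropped` counts filtered proteins.
#' @export
protein_fold_change <- function(tab, normalization = c("total", "median"),
                                min_reps = 2L) {
  normalization <- match.arg(normalization)
  ctrl_cols <- grep("^control_run", names(tab), value = TRUE)
  salt_cols <- grep("^salt_run", names(tab), value = TRUE)
  if (!length(ctrl_cols) || !length(salt_cols))
    stop("expected control_run*/salt_run* columns")
  norm1 <- function(x) {
    denom <- if (normalization == "total") sum(x)
    else stats::median(x[x > 0])
    if (!is.finite(denom) || denom <= 0) denom <- 1
    x / denom
  }
  nt <- tab
  for (cl in c(ctrl_cols, salt_cols)) nt[[cl]] <- norm1(tab[[cl]])
  det_c <- rowSums(tab[ctrl_cols] > 0)
  det_s <- rowSums(tab[salt_cols] > 0)
  keep <- det_c >= min_reps & det_s >= min_reps
  mean_det <- function(row, cols) {
    x <- as.numeric(row[cols])
    mean(x[x > 0])
  }
  fc <- vapply(which(keep), function(i)
    log2(mean_det(nt[i, ], salt_cols) / mean_det(nt[i, ], ctrl_cols)),
    0)
  out <- data.frame(protein_id = tab$protein_id[keep], protein_fc = fc)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' m6A peak and transcript dynamics between conditions
#'
#' Peak-level classes use a one-nucleotide overlap rule across conditions
#' (`control-specific`, `salt-specific`, `shared`). Transcript-level classes
#' follow the three-group rule for condition-shifted methylation:
#' `control-specific` (all m6A lost in salt), `salt-specific` (m6A gained in
#' salt), `both-shifted` (m6A in both conditions but at independent,
#' non-overlapping locations), plus `both-same` (overlapping peaks in both)
#' and `none`.
#'
#' @param ctrl_peaks,salt_peaks `GRanges` of m6A peaks; a `transcript_id`
#'   column is used when present, otherwise peaks are assigned to the
#'   transcripts they overlap.
#' @param models List of [transcript_model()].
#' @return List with `peak_class` (list of per-peak label vectors for
#'   `control` and `salt`) and `transcript_class` (named character vector
#'   over all transcripts in `models`).
#' @export
m6a_dynamics <- function(ctrl_peaks, salt_peaks, models) {
  ov_c <- IRanges::overlapsAny(ctrl_peaks, salt_peaks, minoverlap = 1L,
                               ignore.strand = TRUE)
  ov_s <- IRanges::overlapsAny(salt_peaks, ctrl_peaks, minoverlap = 1L,
                               ignore.strand = TRUE)
  peak_class <- list(
    control = ifelse(ov_c, "shared", "control-specific"),
    salt = ifelse(ov_s, "shared", "salt-specific"))

  assign_tx <- function(peaks) {
    if (length(peaks) && !is.null(peaks$transcript_id))
      return(as.character(peaks$transcript_id))
    spans <- do.call(c, unname(lapply(models, model_span)))
    ov <- GenomicRanges::findOverlaps(peaks, spans, ignore.strand = TRUE)
    out <- rep(NA_character_, length(peaks))
    out[S4Vectors::queryHits(ov)] <- names(models)[S4Vectors::subjectHits(ov)]
    out
  }
  tx_c <- assign_tx(ctrl_peaks)
  tx_s <- assign_tx(salt_peaks)
  transcript_class <- setNames(rep("none", length(models)), names(models))
  for (tid in names(models)) {
    ic <- which(tx_c == tid)
    is_ <- which(tx_s == tid)
    has_c <- length(ic) > 0L
    has_s <- length(is_) > 0L
    if (has_c && !has_s) transcript_class[tid] <- "control-specific"
    else if (!has_c && has_s) transcript_class[tid] <- "salt-specific"
    else if (has_c && has_s) {
      any_shared <- any(IRanges::overlapsAny(ctrl_peaks[ic], salt_peaks[is_],
                                             ignore.strand = TRUE))
      transcript_class[tid] <- if (any_shared) "both-same" else "both-shifted"
    }
  }
  list(peak_class = peak_class, transcript_class = transcript_class)
}

#' Spearman correlation between two profiles within a window
#'
#' Rank correlation (average ranks for ties) of the per-position mean
#' profiles, with the p-value from the asymptotic t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param a,b [profile_matrix()]s or numeric vectors of equal length.
#' @param window Integer indices restricting the comparison (default: all
#'   jointly defined positions).
#' @return List with `rho`, `p_value`, `n`.
#' @export
window_correlation <- function(a, b, window = NULL) {
  va <- if (inherits(a, "profile_matrix")) a$mean else as.numeric(a)
  vb <- if (inherits(b, "profile_matrix")) b$mean else as.numeric(b)
  if (length(va) != length(vb)) stop("profiles differ in length")
  if (!is.null(window)) { va <- va[window]; vb <- vb[window] }
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  if (n < 3L) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rank(va), rank(vb))
  p <- if (abs(rho) >= 1) 0
  else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Pearson correlation of paired per-transcript scores
#'
#' @param x,y Numeric vectors of paired values (or a two-column data frame
#'   in `x`). `NA` pairs are dropped.
#' @return List with `r`, `p_value`, `n`.
#' @export
paired_score_correlation <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[[2L]]; x <- x[[1L]] }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wilcoxon comparison of two groups
#'
#' Unpaired Mann-Whitney rank-sum (normal approximation with tie
#' correction); a paired mode is available for aligned per-position
#' comparisons.
#'
#' @param values_a,values_b Numeric vectors.
#' @param paired Paired test (requires equal lengths). Default `FALSE`.
#' @return List with `statistic` and `p_value`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Stratified report of a per-transcript metric
#'
#' Splits transcripts into the 2x2 strata (condition-specific m6A yes/no by
#' stabilized/destabilized), summarizes the metric per stratum and tests
#' each stratum against the pooled remainder plus all pairwise contrasts
#' (Wilcoxon). Empty strata are reported with `n = 0` and their tests
#' skipped.
#'
#' @param stats `data.frame` with columns `stability_class`, a logical m6A
#'   column (`m6a_col`) and the metric column (`value_col`).
#' @param value_col Metric column name (default `"protein_fc"`).
#' @param m6a_col Logical column flagging condition-specific m6A (default
#'   `"has_salt_m6a"`).
#' @return List with `strata` (n, mean, median, p_vs_rest per stratum) and
#'   `pairwise` (data.frame of stratum pairs with Wilcoxon statistics).
#' @export
strata_report <- function(stats, value_col = "protein_fc",
                          m6a_col = "has_salt_m6a") {
  stopifnot(all(c("stability_class", m6a_col, value_col) %in% names(stats)))
  keep <- stats$stability_class %in% c("stabilized-in-salt",
                                       "destabilized-in-salt") &
    !is.na(stats[[value_col]]) & !is.na(stats[[m6a_col]])
  df <- stats[keep, ]
  grid <- expand.grid(m6a = c(TRUE, FALSE),
                      stability = c("stabilized-in-salt",
                                    "destabilized-in-salt"),
                      stringsAsFactors = FALSE)
  vals <- lapply(seq_len(nrow(grid)), function(i)
    df[[value_col]][df[[m6a_col]] == grid$m6a[i] &
                      df$stability_class == grid$stability[i]])
  nm <- paste0(ifelse(grid$m6a, "m6a+", "m6a-"), "/",
               ifelse(grid$stability == "stabilized-in-salt",
                      "stabilized", "destabilized"))
  strata <- data.frame(
    stratum = nm,
    n = vapply(vals, length, 0L),
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0),
    median = vapply(vals, function(v)
      if (length(v)) stats::median(v) else NA_real_, 0))
  strata$p_vs_rest <- vapply(seq_along(vals), function(i) {
    rest <- unlist(vals[-i])
    if (length(vals[[i]]) < 2L || length(rest) < 2L) return(NA_real_)
    group_compare(vals[[i]], rest)$p_value
  }, 0)
  pairs <- utils::combn(seq_along(vals), 2L)
  pairwise <- data.frame(
    a = nm[pairs[1L, ]], b = nm[pairs[2L, ]],
    statistic = NA_real_, p_value = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    va <- vals[[pairs[1L, k]]]; vb <- vals[[pairs[2L, k]]]
    if (length(va) >= 2L && length(vb) >= 2L) {
      gc <- group_compare(va, vb)
      pairwise$statistic[k] <- gc$statistic
      pairwise$p_value[k] <- gc$p_value
    }
  }
  list(strata = strata, pairwise = pairwise)
}
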