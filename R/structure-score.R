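## Per-nucleotide RNA secondary-structure scores.
##
## The structure score at a nucleotide is the generalized-log ratio of
## coverage in the dsRNA-seq library (ssRNase-treated; reports paired
## regions) to the ssRNA-seq library (dsRNase-treated; reports unpaired
## regions), after scaling each library by its total covered length.
## Positive scores indicate a likely double-stranded nucleotide.

#' Generalized log
#'
#' `glog(x) = log2(x + sqrt(1 + x^2))`; defined at 0 (`glog(0) = 0`) and
#' approaching `log2(2x)` for large `x`.
#'
#' @param x Numeric.
#' @return Numeric of the same length.
#' @export
glog <- function(x) log2(x + sqrt(1 + x^2))

#' Per-nucleotide structure scores from a dsRNA-seq/ssRNA-seq pair
#'
#' Coverage in each library is scaled by total covered length:
#' `ds_i = n_ds,i * max(L_ds, L_ss) / L_ds` (and symmetrically for ss),
#' where `L` counts genome-wide positions with coverage > 0 in that library.
#' The score is `S_i = glog(ds_i) - glog(ss_i)`, defined only where
#' `n_ds,i + n_ss,i > 0` (elsewhere `NA`).
#'
#' @param ds [nt_track()] of dsRNA-seq coverage (the ssRNase-treated
#'   library).
#' @param ss [nt_track()] of ssRNA-seq coverage (the dsRNase-treated
#'   library).
#' @return List of class `structure_scores`: `score` ([nt_track()] with
#'   `NA` at uncovered positions), `L_ds`, `L_ss`.
#' @export
structure_score <- function(ds, ss) {
  track_check_coverage(ds)
  track_check_coverage(ss)
  sl_d <- track_seqlengths(ds)
  sl_s <- track_seqlengths(ss)
  if (!identical(sl_d[sort(names(sl_d))], sl_s[sort(names(sl_s))]))
    stop("ds and ss tracks differ in layout")
  L_ds <- sum(vapply(ds$values, function(v) sum(v > 0), 0L))
  L_ss <- sum(vapply(ss$values, function(v) sum(v > 0), 0L))
  if (L_ds == 0 && L_ss == 0) stop("both libraries are empty")
  Lmax <- max(L_ds, L_ss)
  values <- lapply(names(ds$values), function(chr) {
    nd <- ds$values[[chr]]
    ns <- ss$values[[chr]]
    s <- glog(nd * Lmax / L_ds) - glog(ns * Lmax / L_ss)
    s[nd + ns == 0] <- NA_real_
    s
  })
  names(values) <- names(ds$values)
  structure(list(score = nt_track(values, condition = ds$meta$condition),
                 L_ds = L_ds, L_ss = L_ss),
            class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  n_def <- sum(vapply(x$score$values, function(v) sum(!is.na(v)), 0L))
  cat("structure_scores:", n_def, "defined positions; L_ds =", x$L_ds,
      ", L_ss =", x$L_ss, "\n")
  invisible(x)
}

.score_track <- function(scores) {
  if (inherits(scores, "structure_scores")) scores$score
  else if (inherits(scores, "nt_track")) scores
  else stop("expected structure_scores or nt_track")
}

#' Standardize structure scores
#'
#' Z-scores the raw structure scores to normalize for read coverage. With
#' `scope = "transcript"` each transcript's defined exonic positions are
#' centred and scaled by their own (population) mean and SD; positions
#' outside any transcript stay `NA`. With `scope = "global"` all defined
#' positions are standardized jointly. A zero SD yields all-zero scores.
#'
#' @param scores A `structure_scores` or score [nt_track()].
#' @param models Annotation (list of [transcript_model()]); required for
#'   transcript scope.
#' @param scope `"transcript"` (default) or `"global"`.
#' @return Score [nt_track()] of standardized values.
#' @export
standardize_scores <- function(scores, models = NULL,
                               scope = c("transcript", "global")) {
  scope <- match.arg(scope)
  tr <- .score_track(scores)
  zf <- function(x) {
    def <- !is.na(x)
    if (!any(def)) return(x)
    m <- mean(x[def])
    s <- sqrt(mean((x[def] - m)^2))
    x[def] <- if (s == 0) 0 else (x[def] - m) / s
    x
  }
  if (scope == "global") {
    all_v <- unlist(tr$values, use.names = FALSE)
    def <- !is.na(all_v)
    m <- mean(all_v[def])
    s <- sqrt(mean((all_v[def] - m)^2))
    values <- lapply(tr$values, function(v) {
      d <- !is.na(v)
      v[d] <- if (s == 0) 0 else (v[d] - m) / s
      v
    })
    names(values) <- names(tr$values)
    return(nt_track(values, condition = tr$meta$condition))
  }
  if (is.null(models)) stop("transcript scope requires an annotation")
  values <- lapply(tr$values, function(v) rep(NA_real_, length(v)))
  names(values) <- names(tr$values)
  for (mdl in models) {
    v <- tr$values[[mdl$chrom]]
    idx <- unlist(lapply(seq_len(nrow(mdl$exons)), function(i)
      mdl$exons[i, 1L]:mdl$exons[i, 2L]), use.names = FALSE)
    values[[mdl$chrom]][idx] <- zf(v[idx])
  }
  nt_track(values, condition = tr$meta$condition)
}

#' Transcript-mean-normalized per-nucleotide profile values
#'
#' Projects scores into transcript space and normalizes each nucleotide by
#' the average score across the entire spliced transcript. Because structure
#' scores are log-scale, the default normalization is subtraction of the
#' transcript mean; division is available by flag.
#'
#' @param scores A `structure_scores` or score [nt_track()].
#' @param model A [transcript_model()].
#' @param method `"subtract"` (default) or `"divide"`.
#' @return Numeric vector of length `model$spliced_length` (`NA` at
#'   undefined positions).
#' @export
normalize_by_transcript_mean <- function(scores, model,
                                         method = c("subtract", "divide")) {
  method <- match.arg(method)
  v <- genomic_to_transcript(model, .score_track(scores))
  m <- mean(v, na.rm = TRUE)
  if (is.nan(m)) return(v)
  if (method == "subtract") v - m else v / m
}

#' Region-average structure scores for one transcript
#'
#' Means of (standardized) scores over the 5'UTR, CDS, 3'UTR and the whole
#' spliced transcript; undefined positions are excluded, and a region with
#' no defined positions yields `NA`.
#'
#' @param scores A `structure_scores` or score [nt_track()].
#' @param model A [transcript_model()].
#' @return Named numeric vector `c(utr5, cds, utr3, whole)`.
#' @export
region_average <- function(scores, model) {
  v <- genomic_to_transcript(model, .score_track(scores))
  seg_mean <- function(idx) {
    if (!length(idx)) return(NA_real_)
    x <- v[idx]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  u5 <- model$utr5_len
  cd <- model$cds_len
  c(utr5 = seg_mean(seq_len(u5)),
    cds = seg_mean(if (cd) (u5 + 1L):(u5 + cd) else integer(0)),
    utr3 = seg_mean(if (model$utr3_len)
      (u5 + cd + 1L):model$spliced_length else integer(0)),
    whole = seg_mean(seq_len(model$spliced_length)))
}

#' Region-average table across an annotation
#'
#' @param scores A `structure_scores` or score [nt_track()].
#' @param models List of [transcript_model()].
#' @return `data.frame` with `transcript_id`, `utr5`, `cds`, `utr3`,
#'   `whole`.
#' @export
region_average_table <- function(scores, models) {
  rows <- t(vapply(models, function(m) region_average(scores, m),
                   numeric(4)))
  data.frame(transcript_id = names(models), rows, row.names = NULL)
}

#' Structure fold change between conditions
#'
#' Region-wise fold change is the salt mean minus the control mean of the
#' log-scale scores (equal to log2 of the ratio of linear-scale values).
#' Transcripts with fold change > 0 are classed `greater-in-salt`, < 0
#' `lower-in-salt`, exactly 0 `unchanged`; `NA` regions propagate.
#'
#' @param control,salt [region_average_table()] outputs on matching
#'   transcripts.
#' @param class_region Region whose fold change drives the class label
#'   (default `"whole"`).
#' @return `data.frame` with per-region `fc_*` columns and `class`.
#' @export
structure_fold_change <- function(control, salt, class_region = "whole") {
  ids <- intersect(control$transcript_id, salt$transcript_id)
  ctl <- control[match(ids, control$transcript_id), ]
  slt <- salt[match(ids, salt$transcript_id), ]
  out <- data.frame(transcript_id = ids)
  for (r in c("utr5", "cds", "utr3", "whole"))
    out[[paste0("fc_", r)]] <- slt[[r]] - ctl[[r]]
  fc <- out[[paste0("fc_", class_region)]]
  out$class <- ifelse(is.na(fc), NA_character_,
                      ifelse(fc > 0, "greater-in-salt",
                             ifelse(fc < 0, "lower-in-salt", "unchanged")))
  out
}

#' Folding-constraint string from structure scores
#'
#' Nucleotides with score strictly greater than 2.0 are constrained paired
#' (`|`), strictly below -0.5 constrained unpaired (`x`), anything else
#' (including `NA`) unconstrained (`.`). The dialect matches RNAfold
#' constraint strings.
#'
#' @param scores Numeric vector of structure scores over an interval.
#' @param paired_above Paired threshold (default 2.0, strict).
#' @param unpaired_below Unpaired threshold (default -0.5, strict).
#' @return Single constraint string of the same length as `scores`.
#' @export
fold_constraints <- function(scores, paired_above = 2.0,
                             unpaired_below = -0.5) {
  sym <- rep(".", length(scores))
  sym[!is.na(scores) & scores > paired_above] <- "|"
  sym[!is.na(scores) & scores < unpaired_below] <- "x"
  paste(sym, collapse = "")
}
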