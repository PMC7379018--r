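#' @import GenomicRanges IRanges S4Vectors
#' @importFrom methods is
#' @importFrom stats rpois rnbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# Internal coordinate convention: 1-based closed (GRanges/IRanges native).
# BED and bedGraph are shifted at the format boundary by rtracklayer.

## ---- per-nucleotide tracks -------------------------------------------------

#' Create a per-nucleotide track
#'
#' A track holds one dense numeric vector per chromosome. Library tracks carry
#' non-negative integer read coverage; score tracks carry reals with `NA`
#' marking positions where the quantity is undefined (e.g. structure score at
#' zero coverage).
#'
#' @param values Named list of numeric vectors, one per chromosome. Vector
#'   length defines the chromosome length.
#' @param condition,replicate,rnase,sample_type Library metadata. `rnase` is
#'   `"ds"` (dsRNase-treated, i.e. the ssRNA-seq library) or `"ss"`
#'   (ssRNase-treated, i.e. the dsRNA-seq library); `sample_type` is
#'   `"footprint"` or `"structure_only"`.
#' @return An object of class `nt_track`.
#' @export
nt_track <- function(values, condition = NA_character_, replicate = NA_integer_,
                     rnase = NA_character_, sample_type = NA_character_) {
  stopifnot(is.list(values), length(values) == 0L || !is.null(names(values)))
  structure(
    list(values = values,
         meta = list(condition = condition, replicate = as.integer(replicate),
                     rnase = rnase, sample_type = sample_type)),
    class = "nt_track")
}

#' @export
print.nt_track <- function(x, ...) {
  cat("nt_track:", length(x$values), "chromosome(s),",
      sum(vapply(x$values, length, 0L)), "nt\n")
  m <- x$meta
  if (!is.na(m$condition))
    cat("  ", m$condition, "rep", m$replicate, m$rnase, m$sample_type, "\n")
  invisible(x)
}

#' Chromosome lengths of a track
#' @param track An `nt_track`.
#' @return Named integer vector.
#' @export
track_seqlengths <- function(track) {
  vapply(track$values, length, 0L)
}

track_check_coverage <- function(track) {
  for (v in track$values) {
    if (anyNA(v) || any(v < 0))
      stop("library track has negative or missing coverage")
  }
  invisible(TRUE)
}

## ---- transcript models -----------------------------------------------------

#' Construct a transcript model
#'
#' A spliced gene model with optional CDS. Exons are genomic, 1-based closed,
#' non-overlapping. Derived fields give the 5'UTR/CDS/3'UTR split in both
#' genomic and transcript space.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of genomic (start, end), 1-based closed.
#' @param cds_span Genomic `c(start, end)` of the CDS, or `NULL` for
#'   non-coding models.
#' @param biotype `"mRNA"` or `"lncRNA"`. Araport-style long non-coding types
#'   (lncRNA, antisense_lncRNA, antisense_RNA, ncRNA) are all collapsed to
#'   `"lncRNA"` on ingest.
#' @return Object of class `transcript_model` with derived fields
#'   `spliced_length`, `utr5_len`, `cds_len`, `utr3_len`, `introns`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             cds_span = NULL, biotype = c("mRNA", "lncRNA")) {
  biotype <- match.arg(biotype)
  exons <- matrix(as.integer(exons), ncol = 2L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) stop("exon end < start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("exons overlap or touch out of order")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  spliced_length <- sum(exons[, 2L] - exons[, 1L] + 1L)

  utr5_len <- cds_len <- utr3_len <- 0L
  if (is.null(cds_span)) {
    if (biotype == "mRNA") stop("mRNA model requires a cds_span")
  } else {
    cds_span <- as.integer(cds_span)
    # CDS boundaries must fall inside exons
    inside <- function(p) any(p >= exons[, 1L] & p <= exons[, 2L])
    if (!inside(cds_span[1L]) || !inside(cds_span[2L]))
      stop("CDS boundary outside exons for ", transcript_id)
    cds_len <- .exonic_width(exons, cds_span[1L], cds_span[2L])
    up_len <- .exonic_width(exons, min(exons), cds_span[1L] - 1L)
    down_len <- .exonic_width(exons, cds_span[2L] + 1L, max(exons))
    if (strand == "+") { utr5_len <- up_len; utr3_len <- down_len }
    else { utr5_len <- down_len; utr3_len <- up_len }
  }

  introns <- if (nrow(exons) > 1L)
    cbind(exons[-nrow(exons), 2L] + 1L, exons[-1L, 1L] - 1L)
  else matrix(integer(0), ncol = 2L)

  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exons = exons, cds_span = cds_span, biotype = biotype,
         spliced_length = spliced_length, utr5_len = utr5_len,
         cds_len = cds_len, utr3_len = utr3_len, introns = introns),
    class = "transcript_model")
}

# exonic nucleotides of [a, b] clipped to the exon set
.exonic_width <- function(exons, a, b) {
  if (b < a) return(0L)
  s <- pmax(exons[, 1L], a); e <- pmin(exons[, 2L], b)
  sum(pmax(e - s + 1L, 0L))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, sprintf("(%s)", x$biotype),
      sprintf("%s:%d-%d(%s)", x$chrom, min(x$exons), max(x$exons), x$strand),
      "\n  spliced", x$spliced_length, "nt; UTR5/CDS/UTR3 =",
      x$utr5_len, "/", x$cds_len, "/", x$utr3_len, "\n")
  invisible(x)
}

#' Genomic span of a transcript model
#' @param model A `transcript_model`.
#' @return `GRanges` of length 1.
#' @export
model_span <- function(model) {
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(min(model$exons), max(model$exons)),
                         strand = model$strand)
}

#' Project a genomic track onto transcript coordinates
#'
#' Extracts the exonic values of `track` for `model` and returns them spliced,
#' 5' to 3' in transcript orientation (minus-strand arrays are reversed;
#' intronic positions are dropped).
#'
#' @param model A `transcript_model`.
#' @param track An `nt_track` covering the model's chromosome.
#' @return Numeric vector of length `model$spliced_length`.
#' @export
genomic_to_transcript <- function(model, track) {
  v <- track$values[[model$chrom]]
  if (is.null(v)) stop("track lacks chromosome ", model$chrom)
  if (max(model$exons) > length(v)) stop("model extends beyond track")
  idx <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    model$exons[i, 1L]:model$exons[i, 2L]), use.names = FALSE)
  out <- v[idx]
  if (model$strand == "-") out <- rev(out)
  out
}

#' Genomic feature ranges for an annotation
#'
#' Decomposes transcript models into labelled genomic segments: `utr5`,
#' `cds`, `utr3` and `intron` for mRNAs, `lncRNA` exons for non-coding
#' models. Used by the greedy feature annotation and enrichment of called
#' sites.
#'
#' @param models List of `transcript_model`.
#' @return `GRanges` with metadata column `feature`.
#' @export
feature_ranges <- function(models) {
  pieces <- lapply(models, function(m) {
    rngs <- list()
    if (m$biotype == "lncRNA") {
      rngs$lncRNA <- m$exons
    } else {
      cs <- m$cds_span
      ex <- m$exons
      cds <- cbind(pmax(ex[, 1L], cs[1L]), pmin(ex[, 2L], cs[2L]))
      cds <- cds[cds[, 2L] >= cds[, 1L], , drop = FALSE]
      up <- cbind(ex[, 1L], pmin(ex[, 2L], cs[1L] - 1L))
      up <- up[up[, 2L] >= up[, 1L], , drop = FALSE]
      dn <- cbind(pmax(ex[, 1L], cs[2L] + 1L), ex[, 2L])
      dn <- dn[dn[, 2L] >= dn[, 1L], , drop = FALSE]
      if (m$strand == "+") { rngs$utr5 <- up; rngs$utr3 <- dn }
      else { rngs$utr5 <- dn; rngs$utr3 <- up }
      rngs$cds <- cds
      if (nrow(m$introns)) rngs$intron <- m$introns
    }
    rngs <- Filter(function(x) nrow(x) > 0L, rngs)
    if (!length(rngs)) return(NULL)
    feat <- rep(names(rngs), vapply(rngs, nrow, 0L))
    mat <- do.call(rbind, rngs)
    gr <- GenomicRanges::GRanges(m$chrom,
                                 IRanges::IRanges(mat[, 1L], mat[, 2L]),
                                 strand = m$strand)
    gr$feature <- feat
    gr$transcript_id <- m$transcript_id
    gr
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(GenomicRanges::GRanges(feature = character(0)))
  suppressWarnings(do.call(c, unname(pieces)))
}

## ---- annotation I/O --------------------------------------------------------

LNCRNA_TYPES <- c("lncRNA", "lnc_RNA", "antisense_lncRNA", "antisense_RNA",
                  "ncRNA")

#' Read a GFF3/GTF annotation into transcript models
#'
#' Transcript-level features typed as any long non-coding class (lncRNA,
#' antisense_lncRNA, antisense_RNA, ncRNA) are collapsed to a single
#' `lncRNA` biotype; mRNA features must contain nested exon and CDS features.
#'
#' @param path GFF3 or GTF file (gzip transparently supported).
#' @return Named list of `transcript_model`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  tx_idx <- which(type %in% c("mRNA", "transcript", LNCRNA_TYPES))
  models <- list()
  ids <- as.character(gr$ID)
  parent <- gr$Parent
  parent1 <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  for (i in tx_idx) {
    tid <- ids[i]
    kids <- which(!is.na(parent1) & parent1 == tid)
    ex <- kids[type[kids] == "exon"]
    cds <- kids[type[kids] == "CDS"]
    exons <- if (length(ex))
      cbind(GenomicRanges::start(gr)[ex], GenomicRanges::end(gr)[ex])
    else
      cbind(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    cds_span <- if (length(cds))
      c(min(GenomicRanges::start(gr)[cds]), max(GenomicRanges::end(gr)[cds]))
    else NULL
    biotype <- if (type[i] %in% LNCRNA_TYPES || is.null(cds_span)) "lncRNA"
    else "mRNA"
    models[[tid]] <- transcript_model(
      tid, as.character(GenomicRanges::seqnames(gr))[i],
      as.character(GenomicRanges::strand(gr))[i],
      exons, cds_span = cds_span, biotype = biotype)
  }
  models
}

#' Write transcript models to GFF3
#'
#' Emits gene/transcript/exon/CDS records; output is deterministic for a
#' given model list.
#'
#' @param models List of `transcript_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  rows <- lapply(models, function(m) {
    span <- c(min(m$exons), max(m$exons))
    tx_type <- if (m$biotype == "lncRNA") "lncRNA" else "mRNA"
    df <- data.frame(
      seqid = m$chrom, source = "pipseqr",
      type = c("gene", tx_type,
               rep("exon", nrow(m$exons)),
               if (!is.null(m$cds_span)) "CDS"),
      start = c(span[1L], span[1L], m$exons[, 1L],
                if (!is.null(m$cds_span)) m$cds_span[1L]),
      end = c(span[2L], span[2L], m$exons[, 2L],
              if (!is.null(m$cds_span)) m$cds_span[2L]),
      score = ".", strand = m$strand, phase = ".",
      stringsAsFactors = FALSE)
    gid <- paste0("gene:", m$transcript_id)
    n_ex <- nrow(m$exons)
    attrs <- c(paste0("ID=", gid),
               paste0("ID=", m$transcript_id, ";Parent=", gid),
               paste0("ID=", m$transcript_id, ".exon", seq_len(n_ex),
                      ";Parent=", m$transcript_id),
               if (!is.null(m$cds_span))
                 paste0("ID=", m$transcript_id, ".cds;Parent=",
                        m$transcript_id))
    df$attributes <- attrs
    df
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- interval and track I/O ------------------------------------------------

#' Read / write BED6 interval sets
#'
#' Intervals are `GRanges`; BED is 0-based half-open on disk and 1-based
#' closed in memory (shift handled by rtracklayer).
#'
#' @param path BED file.
#' @return `GRanges` with `name` and `score` columns.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) gr$name <- rep(NA_character_, length(gr))
  if (is.null(gr$score)) gr$score <- rep(0, length(gr))
  gr
}

#' @rdname read_intervals
#' @param gr `GRanges` to write; `name` and `score` columns used if present.
#' @export
write_intervals <- function(gr, path) {
  if (is.null(gr$name)) gr$name <- paste0("iv", seq_along(gr))
  if (is.null(gr$score)) gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write per-nucleotide coverage as bedGraph
#'
#' @param path bedGraph file.
#' @param seqlengths Named integer vector of chromosome lengths (positions
#'   not covered by a record are 0).
#' @param ... Metadata passed to [nt_track()].
#' @return `nt_track`.
#' @export
read_bedgraph <- function(path, seqlengths, ...) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(seqlengths, function(n) numeric(n))
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    if (!chr %in% names(values)) stop("unexpected chromosome ", chr)
    sub <- gr[GenomicRanges::seqnames(gr) == chr]
    if (any(GenomicRanges::end(sub) > seqlengths[[chr]]))
      stop("bedGraph record beyond chromosome end on ", chr)
    for (i in seq_along(sub)) {
      values[[chr]][GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
        sub$score[i]
    }
  }
  nt_track(values, ...)
}

#' @rdname read_bedgraph
#' @param track `nt_track` to write; zero runs are omitted, `NA` written as
#'   omitted positions.
#' @export
write_bedgraph <- function(track, path) {
  grs <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    v[is.na(v)] <- 0
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts[keep], ends[keep]),
                           score = r$values[keep])
  })
  grs <- Filter(Negate(is.null), grs)
  gr <- if (length(grs)) suppressWarnings(do.call(c, unname(grs)))
  else GenomicRanges::GRanges(score = numeric(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a tab-separated table
#'
#' Thin wrapper for count and intensity tables (header row expected).
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_table_tsv
#' @param x `data.frame` to write.
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
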