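## Synthetic PIP-seq experiment with planted ground truth.
##
## The generator emulates the data model of a nuclear PIP-seq study:
## a virtual genome tiled with spliced transcripts, 16 coverage libraries
## (2 conditions x 2 replicates x {footprint, structure-only} x {dsRNase,
## ssRNase}), condition-specific m6A peak sets, mRNA-seq/GMUCT count pairs
## and label-free protein intensities -- each with planted, recoverable
## effects.

#' Simulation configuration
#'
#' Defaults describe a small but realistic nuclear PIP-seq experiment:
#' 200 transcripts of 0.8-1.5 kb at 30x mean coverage, protein footprints of
#' 20-50 nt planted at 1 per kb with 4-fold protection, double-/single-
#' stranded regions planted at 1 per kb with a 3-fold dsRNase/ssRNase
#' coverage asymmetry, and 60% replicate concordance of planted footprints.
#'
#' @param n_transcripts Number of transcripts.
#' @param transcript_length_range Spliced length range (nt).
#' @param utr5_length_range,utr3_length_range UTR length ranges (nt). The
#'   defaults straddle the metagene expression-filter minima (45 nt 5'UTR,
#'   140 nt 3'UTR) so only a fraction of mRNAs passes the filter.
#' @param n_introns_range Range of intron counts per transcript.
#' @param intron_length_range Intron length range (nt).
#' @param frac_lncrna Fraction of transcripts emitted as lncRNA-like (no CDS).
#' @param mean_depth Mean read coverage per transcribed nucleotide.
#' @param footprint_density Expected planted protein-protected regions per kb.
#' @param footprint_length_range Footprint length range (nt).
#' @param footprint_enrichment Coverage multiplier of footprint libraries
#'   inside planted footprints (> 1).
#' @param replicate_concordance Fraction of planted footprints shared by both
#'   replicates of a condition.
#' @param paired_region_density Expected planted structure regions per kb
#'   (each planted as paired or unpaired with equal probability).
#' @param paired_region_length_range Structure region length range (nt).
#' @param ds_ss_contrast dsRNA-seq/ssRNA-seq coverage asymmetry factor (> 1)
#'   over planted paired regions (reversed over unpaired regions).
#' @param m6a_peak_rate_by_condition Named vector `c(control=, salt=)` of
#'   expected m6A peaks per mRNA.
#' @param m6a_length_range m6A peak length range (nt).
#' @param nb_dispersion Negative-binomial dispersion of count tables.
#' @param mean_counts Mean mRNA-seq counts per transcript.
#' @param base_pu Baseline log2 proportion uncapped (GMUCT/mRNA ratio).
#' @param stability_shift_sd SD of planted per-transcript log2 proportion-
#'   uncapped shifts in salt.
#' @param protein_log2fc_sd SD of planted per-protein log2 fold changes.
#' @param protein_noise_sd SD (log scale) of run-to-run protein noise.
#' @param frac_protein_undetected Fraction of proteins planted to fail the
#'   two-replicate detection filter.
#' @param seed Integer seed; identical configuration implies bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200,
                       transcript_length_range = c(800L, 1500L),
                       utr5_length_range = c(20L, 150L),
                       utr3_length_range = c(80L, 400L),
                       n_introns_range = c(0L, 2L),
                       intron_length_range = c(60L, 200L),
                       frac_lncrna = 0.1,
                       mean_depth = 30,
                       footprint_density = 1,
                       footprint_length_range = c(20L, 50L),
                       footprint_enrichment = 4,
                       replicate_concordance = 0.6,
                       paired_region_density = 1,
                       paired_region_length_range = c(30L, 80L),
                       ds_ss_contrast = 3,
                       m6a_peak_rate_by_condition = c(control = 0.5, salt = 0.8),
                       m6a_length_range = c(50L, 150L),
                       nb_dispersion = 0.1,
                       mean_counts = 500,
                       base_pu = -2,
                       stability_shift_sd = 0.5,
                       protein_log2fc_sd = 0.5,
                       protein_noise_sd = 0.2,
                       frac_protein_undetected = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  rng <- function(x) length(x) == 2L && x[1L] <= x[2L] && x[1L] >= 0
  if (cfg$n_transcripts < 0) stop("n_transcripts must be >= 0")
  for (f in c("transcript_length_range", "utr5_length_range",
              "utr3_length_range", "n_introns_range", "intron_length_range",
              "footprint_length_range", "paired_region_length_range",
              "m6a_length_range"))
    if (!rng(cfg[[f]])) stop("invalid range: ", f)
  if (cfg$frac_lncrna < 0 || cfg$frac_lncrna > 1)
    stop("frac_lncrna must be in [0,1]")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (cfg$footprint_enrichment < 1) stop("footprint_enrichment must be >= 1")
  if (cfg$ds_ss_contrast < 1) stop("ds_ss_contrast must be >= 1")
  if (any(c(cfg$footprint_density, cfg$paired_region_density,
            cfg$m6a_peak_rate_by_condition) < 0))
    stop("rates must be >= 0")
  min_len <- cfg$utr5_length_range[1L] + cfg$utr3_length_range[1L] + 30L
  if (cfg$transcript_length_range[1L] < min_len)
    stop("transcript_length_range too short for the UTR ranges plus a ",
         "minimal CDS")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
  else as.integer(floor(runif(n, range[1L], range[2L] + 1)))
}

# map transcript-space position (1-based, 5'->3') to genomic position
.tx2gen <- function(exons, strand, p) {
  widths <- exons[, 2L] - exons[, 1L] + 1L
  if (strand == "-") {
    csum <- cumsum(rev(widths))
    i <- findInterval(p - 1L, c(0L, csum), rightmost.closed = FALSE)
    off <- p - c(0L, csum)[i] - 1L
    ri <- nrow(exons) - i + 1L
    exons[ri, 2L] - off
  } else {
    csum <- cumsum(widths)
    i <- findInterval(p - 1L, c(0L, csum), rightmost.closed = FALSE)
    off <- p - c(0L, csum)[i] - 1L
    exons[i, 1L] + off
  }
}

# place n intervals of the given lengths inside random exons of a model,
# non-overlapping among themselves; returns GRanges (possibly shorter than n
# if placement repeatedly fails)
.place_in_exons <- function(model, lens, max_tries = 50L) {
  out <- matrix(integer(0), ncol = 2L)
  ex <- model$exons
  w <- ex[, 2L] - ex[, 1L] + 1L
  for (len in lens) {
    ok_ex <- which(w >= len)
    if (!length(ok_ex)) next
    for (try in seq_len(max_tries)) {
      e <- if (length(ok_ex) == 1L) ok_ex else
        sample(ok_ex, 1L, prob = w[ok_ex])
      s <- ex[e, 1L] + .runif_int(1L, c(0L, w[e] - len))
      iv <- c(s, s + len - 1L)
      if (!nrow(out) || all(iv[2L] < out[, 1L] | iv[1L] > out[, 2L])) {
        out <- rbind(out, iv)
        break
      }
    }
  }
  if (!nrow(out)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(out[, 1L], out[, 2L]),
                         strand = model$strand)
}

.empty_gr <- function() GenomicRanges::GRanges()

#' Simulate a transcript annotation with planted ground truth
#'
#' Lays non-overlapping transcripts along a virtual chromosome and plants:
#' protein footprints (per condition, assigned to one or both replicates
#' according to `replicate_concordance`), paired/unpaired structure regions,
#' condition-specific m6A peaks, per-transcript stability shifts and
#' per-protein fold changes.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (named list of [transcript_model()]),
#'   `seqlengths` (named integer), and `truth` -- a list with elements
#'   `footprints` (nested list `[[condition]][[replicate]]` of `GRanges`),
#'   `footprints_all` (union per condition), `paired_regions` (`GRanges` with
#'   `class` column `paired`/`unpaired`), `m6a` (list per condition of
#'   `GRanges` with `transcript_id`), `stability_shift` and `protein_log2fc`
#'   (named numeric vectors).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  models <- list()
  gap <- 100L
  pos <- 1L + gap
  conditions <- c("control", "salt")
  fp <- list(control = list(`1` = list(), `2` = list()),
             salt = list(`1` = list(), `2` = list()))
  paired <- list()
  m6a <- list(control = list(), salt = list())

  n <- cfg$n_transcripts
  if (n > 0) {
    for (k in seq_len(n)) {
      tid <- sprintf("TX%04d", k)
      is_lnc <- runif(1) < cfg$frac_lncrna
      L <- .runif_int(1L, cfg$transcript_length_range)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (is_lnc) {
        utr5 <- utr3 <- 0L
        cds_len <- 0L
      } else {
        utr5 <- .runif_int(1L, cfg$utr5_length_range)
        utr3 <- .runif_int(1L, cfg$utr3_length_range)
        cds_len <- L - utr5 - utr3
        cds_len <- cds_len - cds_len %% 3L
        if (cds_len < 30L) { cds_len <- 30L }
        L <- utr5 + cds_len + utr3
      }
      n_introns <- .runif_int(1L, cfg$n_introns_range)
      brk <- if (n_introns > 0 && L > 2L)
        sort(sample(2:L, min(n_introns, L - 2L))) else integer(0)
      ilens <- .runif_int(length(brk), cfg$intron_length_range)
      # genomic exons from spliced breakpoints
      seg_start <- c(1L, brk)
      seg_end <- c(brk - 1L, L)
      g <- pos
      exons <- matrix(integer(0), ncol = 2L)
      for (i in seq_along(seg_start)) {
        wseg <- seg_end[i] - seg_start[i] + 1L
        exons <- rbind(exons, c(g, g + wseg - 1L))
        g <- g + wseg + if (i <= length(ilens)) ilens[i] else 0L
      }
      span_end <- max(exons)
      cds_span <- NULL
      if (!is_lnc) {
        p1 <- utr5 + 1L
        p2 <- utr5 + cds_len
        g1 <- .tx2gen(exons, strand, p1)
        g2 <- .tx2gen(exons, strand, p2)
        cds_span <- c(min(g1, g2), max(g1, g2))
      }
      m <- transcript_model(tid, "chr1", strand, exons, cds_span,
                            biotype = if (is_lnc) "lncRNA" else "mRNA")
      models[[tid]] <- m
      kb <- m$spliced_length / 1000

      # footprints per condition, split across replicates
      for (cond in conditions) {
        n_fp <- rpois(1L, cfg$footprint_density * kb)
        if (n_fp > 0) {
          gr <- .place_in_exons(m, .runif_int(n_fp, cfg$footprint_length_range))
          if (length(gr)) {
            u <- runif(length(gr))
            both <- u < cfg$replicate_concordance
            r1 <- both | (runif(length(gr)) < 0.5 & !both)
            r2 <- both | (!r1)
            if (any(r1)) fp[[cond]][["1"]][[tid]] <- gr[r1]
            if (any(r2)) fp[[cond]][["2"]][[tid]] <- gr[r2]
          }
        }
      }

      # paired / unpaired structure regions
      n_pr <- rpois(1L, cfg$paired_region_density * kb)
      if (n_pr > 0) {
        gr <- .place_in_exons(m, .runif_int(n_pr,
                                            cfg$paired_region_length_range))
        if (length(gr)) {
          gr$class <- ifelse(runif(length(gr)) < 0.5, "paired", "unpaired")
          paired[[tid]] <- gr
        }
      }

      # condition-specific m6A peaks (mRNAs only)
      if (!is_lnc) {
        for (cond in conditions) {
          n_m6a <- rpois(1L, cfg$m6a_peak_rate_by_condition[[cond]])
          if (n_m6a > 0) {
            gr <- .place_in_exons(m, .runif_int(n_m6a, cfg$m6a_length_range))
            if (length(gr)) {
              gr$transcript_id <- tid
              m6a[[cond]][[tid]] <- gr
            }
          }
        }
      }
      pos <- span_end + gap + .runif_int(1L, c(0L, 100L))
    }
  }

  seqlengths <- c(chr1 = as.integer(pos + gap))
  cat_gr <- function(lst) {
    lst <- Filter(function(x) length(x) > 0, lst)
    if (!length(lst)) .empty_gr()
    else suppressWarnings(do.call(c, unname(lst)))
  }
  truth <- list(
    footprints = lapply(fp, function(bycond) lapply(bycond, cat_gr)),
    paired_regions = cat_gr(paired),
    m6a = lapply(m6a, cat_gr))
  truth$footprints_all <- lapply(truth$footprints, function(reps)
    GenomicRanges::reduce(c(reps[["1"]], reps[["2"]]), ignore.strand = TRUE))

  mids <- names(models)
  coding <- vapply(models, function(m) m$biotype == "mRNA", TRUE)
  truth$stability_shift <- setNames(
    rnorm(length(mids), 0, cfg$stability_shift_sd), mids)
  truth$protein_log2fc <- setNames(
    rnorm(sum(coding), 0, cfg$protein_log2fc_sd), mids[coding])

  list(models = models, seqlengths = seqlengths, truth = truth)
}

# multiplier track for the ds/ss structure contrast of one RNase treatment
.contrast_values <- function(sim, cfg, rnase) {
  v <- rep(1, sim$seqlengths[["chr1"]])
  pr <- sim$truth$paired_regions
  if (!length(pr)) return(v)
  c_fac <- cfg$ds_ss_contrast
  for (i in seq_along(pr)) {
    idx <- GenomicRanges::start(pr)[i]:GenomicRanges::end(pr)[i]
    up <- (pr$class[i] == "paired") == (rnase == "ss")
    v[idx] <- if (up) c_fac else 1 / c_fac
  }
  v
}

#' Simulate the 16 PIP-seq coverage libraries
#'
#' Per-nucleotide coverage is Poisson around `mean_depth` within transcribed
#' regions and zero elsewhere. Inside planted paired regions the dsRNA-seq
#' (ssRNase-treated) mean is multiplied by `ds_ss_contrast` and the ssRNA-seq
#' (dsRNase-treated) mean divided by it; the reverse holds in unpaired
#' regions. Inside planted footprints both footprint libraries are multiplied
#' by `footprint_enrichment` relative to the matched structure-only library.
#' Replicates are independent draws.
#'
#' @param sim Result of [simulate_annotation()].
#' @param cfg The same [sim_config()].
#' @return Named list of 16 [nt_track()] objects, names
#'   `<condition>_rep<r>_<rnase>_<sample_type>`.
#' @export
simulate_libraries <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(sim$models)) stop("annotation is empty")
  set.seed(cfg$seed + 1000L)
  G <- sim$seqlengths[["chr1"]]
  base <- rep(0, G)
  for (m in sim$models) base[min(m$exons):max(m$exons)] <- cfg$mean_depth
  contrast <- list(ds = .contrast_values(sim, cfg, "ds"),
                   ss = .contrast_values(sim, cfg, "ss"))
  out <- list()
  for (cond in c("control", "salt")) {
    for (rep_i in 1:2) {
      fp_gr <- sim$truth$footprints[[cond]][[as.character(rep_i)]]
      fp_mask <- rep(1, G)
      if (length(fp_gr)) {
        for (i in seq_along(fp_gr)) {
          fp_mask[GenomicRanges::start(fp_gr)[i]:GenomicRanges::end(fp_gr)[i]] <-
            cfg$footprint_enrichment
        }
      }
      for (rnase in c("ds", "ss")) {
        for (stype in c("footprint", "structure_only")) {
          lam <- base * contrast[[rnase]]
          if (stype == "footprint") lam <- lam * fp_mask
          nm <- sprintf("%s_rep%d_%s_%s", cond, rep_i, rnase, stype)
          out[[nm]] <- nt_track(list(chr1 = rpois(G, lam)),
                                condition = cond, replicate = rep_i,
                                rnase = rnase, sample_type = stype)
        }
      }
    }
  }
  out
}

#' Simulate mRNA-seq/GMUCT counts and protein intensities
#'
#' Counts are negative binomial per transcript, condition and replicate;
#' GMUCT means are constructed so the expected log2 proportion-uncapped
#' difference (salt minus control) equals the planted stability shift.
#' Protein intensities have three runs per condition with log-normal noise
#' around the planted log2 fold change; a configurable fraction of proteins
#' is planted to be detected in fewer than two replicates of one condition,
#' to exercise the downstream detection filter.
#'
#' @param sim Result of [simulate_annotation()].
#' @param cfg The same [sim_config()].
#' @return List with `mrna_counts` and `gmuct_counts` (data.frames:
#'   `transcript_id` + `<condition>_rep<r>` columns) and
#'   `protein_intensity` (data.frame: `protein_id` + `<condition>_run<r>`).
#' @export
simulate_counts_and_proteins <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(sim$models)) stop("annotation is empty")
  set.seed(cfg$seed + 2000L)
  ids <- names(sim$models)
  ntx <- length(ids)
  mu <- rlnorm(ntx, log(cfg$mean_counts), 0.7)
  shift <- sim$truth$stability_shift[ids]
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu_vec) rnbinom(ntx, mu = mu_vec, size = size)
  mrna <- data.frame(transcript_id = ids,
                     control_rep1 = draw(mu), control_rep2 = draw(mu),
                     salt_rep1 = draw(mu), salt_rep2 = draw(mu))
  mu_g_ctrl <- mu * 2^cfg$base_pu
  mu_g_salt <- mu * 2^(cfg$base_pu + shift)
  gmuct <- data.frame(transcript_id = ids,
                      control_rep1 = draw(mu_g_ctrl),
                      control_rep2 = draw(mu_g_ctrl),
                      salt_rep1 = draw(mu_g_salt),
                      salt_rep2 = draw(mu_g_salt))

  pfc <- sim$truth$protein_log2fc
  pids <- names(pfc)
  np <- length(pids)
  intensity <- NULL
  if (np > 0) {
    base <- rlnorm(np, log(1e6), 1)
    noise <- function() rlnorm(np, 0, cfg$protein_noise_sd)
    tab <- data.frame(protein_id = pids,
                      control_run1 = base * noise(),
                      control_run2 = base * noise(),
                      control_run3 = base * noise(),
                      salt_run1 = base * 2^pfc * noise(),
                      salt_run2 = base * 2^pfc * noise(),
                      salt_run3 = base * 2^pfc * noise())
    n_drop <- round(cfg$frac_protein_undetected * np)
    if (n_drop > 0) {
      drop_idx <- sample(np, n_drop)
      for (i in drop_idx) {
        cond_cols <- if (runif(1) < 0.5) 2:4 else 5:7
        zero_cols <- sample(cond_cols, 2L)
        tab[i, zero_cols] <- 0
      }
    }
    intensity <- tab
  }
  list(mrna_counts = mrna, gmuct_counts = gmuct,
       protein_intensity = intensity)
}

#' Emit uniform-length read intervals for a library track
#'
#' A thin read-interval emitter (uniform 50-nt reads) for exercising the
#' depth-equalization path; read start positions are sampled proportionally
#' to coverage.
#'
#' @param track An [nt_track()].
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in nt (default 50).
#' @param seed Integer seed.
#' @return `GRanges` of read intervals.
#' @export
simulate_reads <- function(track, n_reads, read_length = 50L, seed = 1L) {
  set.seed(seed)
  grs <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    G <- length(v)
    w <- v[seq_len(max(G - read_length + 1L, 1L))]
    if (sum(w) == 0) return(NULL)
    n_chr <- n_reads  # single-chromosome genomes in practice
    starts <- sample.int(length(w), n_chr, replace = TRUE, prob = w)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts,
                                                 starts + read_length - 1L))
  })
  grs <- Filter(Negate(is.null), grs)
  if (!length(grs)) return(.empty_gr())
  suppressWarnings(do.call(c, unname(grs)))
}

#' Write a full simulated experiment to disk
#'
#' Emits GFF3 annotation, one bedGraph per library, BED6 ground-truth
#' interval sets, TSV count/intensity tables and a JSON ground-truth summary.
#' Deterministic given the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotation(cfg)
  write_annotation(sim$models, file.path(dir, "annotation.gff3"))
  libs <- simulate_libraries(sim, cfg)
  for (nm in names(libs))
    write_bedgraph(libs[[nm]], file.path(dir, paste0(nm, ".bedGraph")))
  for (cond in names(sim$truth$footprints_all)) {
    gr <- sim$truth$footprints_all[[cond]]
    if (length(gr))
      write_intervals(gr, file.path(dir, paste0("footprints_", cond, ".bed")))
    m <- sim$truth$m6a[[cond]]
    if (length(m))
      write_intervals(m, file.path(dir, paste0("m6a_", cond, ".bed")))
  }
  if (length(sim$truth$paired_regions))
    write_intervals(sim$truth$paired_regions,
                    file.path(dir, "paired_regions.bed"))
  tabs <- simulate_counts_and_proteins(sim, cfg)
  write_table_tsv(tabs$mrna_counts, file.path(dir, "mrna_counts.tsv"))
  write_table_tsv(tabs$gmuct_counts, file.path(dir, "gmuct_counts.tsv"))
  if (!is.null(tabs$protein_intensity))
    write_table_tsv(tabs$protein_intensity,
                    file.path(dir, "protein_intensity.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      n_transcripts = length(sim$models),
      seqlengths = as.list(sim$seqlengths),
      n_footprints = lapply(sim$truth$footprints_all, length),
      n_paired_regions = length(sim$truth$paired_regions),
      n_m6a = lapply(sim$truth$m6a, length),
      seed = cfg$seed)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}
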