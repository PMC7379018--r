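---
title: "Methods: nuclear PIP-seq analysis with pipseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear PIP-seq analysis with pipseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipseqr)
```

# Overview

Protein interaction profile sequencing (PIP-seq) digests nuclear RNA with a
double-strand-specific or single-strand-specific RNase, either with proteins
bound (*footprint* sample) or after proteinase K treatment (*structure-only*
sample). Comparing the two samples maps protein-protected sites (PPSs);
comparing the two RNase treatments of the structure-only sample maps
intrinsic RNA secondary structure. `pipseqr` implements the downstream
analysis: structure scoring, PPS calling with a permutation false discovery
rate, metagene and peak-centered profiling, and the integrative statistics
that relate structure change to m6A methylation, transcript stability
(degradome "proportion uncapped"), abundance and protein output — plus a
deterministic synthetic-data generator with planted ground truth so every
stage is testable without sequencing data.

A note on naming that recurs throughout: the **dsRNA-seq** library is the
one *treated with the ssRNase* (double-stranded regions survive), and the
**ssRNA-seq** library is the one *treated with the dsRNase*. The
`rnase` field of a library records the *treatment*, so the track named
`..._ss_structure_only` is the dsRNA-seq library.

# Coordinates and formats

Internally all coordinates are **1-based, fully closed**, the native
convention of `GenomicRanges`/`IRanges`; conversion to and from 0-based
half-open BED/bedGraph happens only in the I/O layer
(`read_intervals()`, `write_bedgraph()`, ...). GFF3 is read through
`rtracklayer` with `Parent`-based nesting and written by a small
deterministic writer so identical inputs produce byte-identical files.
Araport-style long non-coding types (`lncRNA`, `antisense_lncRNA`,
`ncRNA`, ...) collapse to a single `lncRNA` biotype.

# Structure score

For a nucleotide $i$ with dsRNA-seq coverage $n_{ds,i}$ and ssRNA-seq
coverage $n_{ss,i}$, each library is first scaled by its *covered length*
$L$ — the genome-wide number of positions with coverage $> 0$:

$$ds_i = n_{ds,i}\,\frac{\max(L_{ds}, L_{ss})}{L_{ds}},
\qquad
ss_i = n_{ss,i}\,\frac{\max(L_{ds}, L_{ss})}{L_{ss}}.$$

The score is a difference of generalized logs,

$$S_i = \mathrm{glog}(ds_i) - \mathrm{glog}(ss_i),
\qquad
\mathrm{glog}(x) = \log_2\!\left(x + \sqrt{1 + x^2}\right),$$

which behaves like $\log_2(2x)$ for large coverage but is defined at zero
(`glog(0) = 0`), so a position covered in only one library still gets a
finite score. $S_i$ is `NA` where $n_{ds,i} + n_{ss,i} = 0$. Positive
scores indicate likely base-paired nucleotides.

```{r structure-example}
ds <- nt_track(list(chr1 = c(3, 1)))
ss <- nt_track(list(chr1 = c(1, 3)))
structure_score(ds, ss)$score$values$chr1  # c(+1.352, -1.352)
```

To remove per-transcript coverage effects, `standardize_scores()` z-scores
the defined exonic positions of each transcript using the **population**
standard deviation (divide by $n$, not $n-1$), so a two-position transcript
with scores $\{-1, +1\}$ standardizes to itself. The same convention is
used by `zscore_window()` for profile windows. `fold_constraints()` maps
scores to an RNAfold-style constraint string with *strict* thresholds:
score $> 2.0$ becomes `|` (paired), score $< -0.5$ becomes `x` (unpaired),
anything else — including the boundary values and `NA` — stays `.`.

# PPS calling

At each position the footprint coverage $f_i$ is tested against the
structure-only coverage $s_i$ under a Poisson upper tail with a pseudocount
of 1 (avoiding a zero-rate degeneracy):

$$\mathrm{score}_i = -\log_{10} P\!\left(\mathrm{Poisson}(s_i + 1) \ge f_i\right),$$

with positions of zero footprint coverage scored 0. The null distribution
is the **label swap** of the same pair (structure-only tested against
footprint); the FDR threshold at level $q$ is the smallest observed score
$t$ with

$$\frac{\#\{\text{null} \ge t\}}{\#\{\text{observed} \ge t\}} \le q,$$

an inclusive threshold ($\ge$ on both sides). Maximal runs of positions at
or above the threshold become intervals (`call_pps()`); intervals sharing
at least one nucleotide are merged, while merely adjacent intervals stay
separate. `high_confidence()` keeps replicate-1 intervals that overlap a
replicate-2 interval by at least one nucleotide (the returned geometry is
replicate 1's), and `classify_condition()` splits the two conditions'
high-confidence sets into control-specific / salt-specific / shared with
the same one-nucleotide rule, anchored on the control geometry for the
shared set. `equalize_depth()` downsamples the larger of two read sets
before coverage comparison.

Calibration is measured, not assumed: `pps_fdr_benchmark()` plants
footprints in synthetic libraries and reports the fraction of called
nucleotides outside every planted region. At the default operating point
(4-fold enrichment, mean depth 30, $q = 0.05$) the mean empirical FDR over
20 seeds sits at about 5%.

# Profiles

`anchored_profile()` builds transcripts-by-positions matrices aligned on
the first nucleotide of the start codon (spliced position `utr5_len + 1`)
or of the stop codon (`utr5_len + cds_len - 2`); positions outside a
transcript are `NA` and excluded from the per-column mean/SEM.
`binned_profile()` compresses transcript-space vectors with a floor
partition — bin $b$ of $n$ over length $L$ covers positions
$\lfloor bL/n\rfloor + 1$ through $\lfloor (b+1)L/n\rfloor$ — which tiles
the vector exactly, with no gaps or overlaps; regions shorter than the bin
count repeat single positions rather than failing.
`peak_centered_profile()` rows are `[5' flank | peak | 3' flank]` with
flanks of exactly the peak's length, each third binned, minus-strand peaks
reversed, and edge peaks dropped. `shuffle_peaks()` provides the
positional control: peaks are re-placed uniformly (seeded rejection
sampling, gene-slot-weighted) wholly inside gene space, preserving count
and lengths and avoiding mutual overlaps.

Expression filters for profile inclusion follow the inclusive thresholds
`filter_expressed()` documents: mRNAs need at least 50 summed reads in
*every* supplied library plus a 5'UTR of at least 45 nt and a 3'UTR of at
least 140 nt (so UTR windows are actually informative); lncRNAs need at
least 5 reads and no UTR minimum.

# Integrative statistics

*Stability.* Proportion uncapped is
$PU = \log_2(\mathrm{RPM}_{GMUCT} / \mathrm{RPM}_{mRNA})$; its change under
salt is the log-domain **difference** $PU_{salt} - PU_{control}$ (not a
ratio of the two logs, which would not be scale-invariant). Positive change
means more uncapped ends per transcript copy, i.e. *destabilized-in-salt*.
RPM substitutes a pseudocount of 0.5 for zero counts so the logs stay
defined.

*Protein output.* `protein_fold_change()` normalizes each run by its total
(or median of detected values), requires detection (nonzero intensity) in
at least two replicates of each condition, and takes the log2 ratio of
mean normalized intensity over detected runs only.

*m6A dynamics.* Peaks are compared across conditions by the one-nucleotide
overlap rule; transcripts are classed `control-specific`, `salt-specific`,
`both-shifted` (peaks in both conditions, none overlapping), `both-same`,
or `none`.

*Tests.* Spearman correlations use rank-Pearson with the asymptotic
$t$ approximation; two-group comparisons use the normal-approximation
Wilcoxon (`exact = FALSE`); distribution comparisons (e.g. conservation of
PPSs versus equal-length flanks) use the two-sample Kolmogorov–Smirnov
test. These are deliberately *bought* from `stats` rather than
reimplemented; the tests in `tests/testthat/` pin them against independent
oracles (rank-Pearson, exhaustive ECDF gap).

# The synthetic-data generator

`sim_config()` / `simulate_annotation()` / `simulate_libraries()` /
`simulate_counts_and_proteins()` produce a complete experiment on one
synthetic chromosome with planted, recorded ground truth
(`$truth`): per-replicate footprints, paired/unpaired structure regions,
per-condition m6A peaks, per-transcript stability shifts and per-protein
fold changes. Determinism is strict — one seed governs the annotation,
`seed + 1000` the libraries, `seed + 2000` the count/protein tables — and
identical configurations produce byte-identical output files.

Key defaults and why:

* `n_transcripts = 200`, `transcript_length_range = c(800, 1500)`:
  a ~1 kb-transcript problem large enough for stable FDR estimates yet
  fast enough that a 20-seed benchmark runs in minutes.
* `mean_depth = 30`, `footprint_enrichment = 4`: moderate coverage and a
  realistic enrichment at which the caller is neither saturated nor
  powerless, so calibration is actually exercised.
* `replicate_concordance = 0.6`: fraction of a condition's footprints
  shared between replicates, so the replicate-intersection step has real
  work to do.
* `ds_ss_contrast = 3`: coverage asymmetry over planted paired regions
  (reversed over unpaired regions), giving structure scores a planted sign
  to recover.
* `nb_dispersion = 0.1`, `mean_counts = 500`: overdispersed counts typical
  of RNA-seq; `base_pu = -2` puts degradome coverage at a quarter of mRNA
  coverage.
* `frac_protein_undetected = 0.1`: plants proteins that fail the
  two-replicate detection filter, exercising the filter path.

With every effect parameter at its neutral value (enrichment 1, contrast
1, zero shift SDs) the generator emits exchangeable Poisson noise, which
is what the null-calibration tests rely on.

What the generator *emulates*: coverage-level consequences of protection,
structure contrast, methylation, stability and protein effects, replicate
noise and partial replicate concordance. What it does *not* emulate:
sequences (there are none), ligation/PCR biases, fragment-length effects,
multi-mapping, isoform complexity beyond one model per gene, or chromatin
context. Conclusions about those require real libraries.

# Design decisions

* **1-based closed coordinates internally** — matches the idiom of the
  underlying Bioconductor containers; BED conversion is confined to I/O.
* **Population SD in all standardizations** — keeps tiny windows
  well-defined and makes two-point examples exact.
* **Strict inequalities for constraint thresholds and fold-change
  classes** — boundary values are deliberately unconstrained/`unchanged`.
* **PU change as a difference of logs** — scale-invariant and equal to the
  log of the linear-scale ratio.
* **Anchor-replicate convention** — high-confidence and shared sets report
  replicate-1/control geometry rather than fragmented intersections, so
  interval counts match interval-level bookkeeping.
* **Permutation FDR with an inclusive threshold** — the smallest observed
  score whose swap-null exceedance ratio drops to `q`; `Inf` (no calls)
  when no score qualifies, rather than silently falling back.

# Limitations

The Poisson enrichment model ignores overdispersion between biological
replicates (the replicate-intersection step is the practical guard); the
label-swap null assumes the two samples are exchangeable under no
protection; covered-length normalization of structure scores assumes
comparable breadth of the two libraries; and the synthetic benchmark
measures calibration under its own generative model, not under real
library artifacts.
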