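# Small in-code fixtures shared across test files.

toy_track <- function(..., meta = list()) {
  vals <- list(...)
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("chr", seq_along(vals))
  do.call(nt_track, c(list(values = vals), meta))
}

# single-exon plus-strand mRNA on chr1:101-400 with CDS 151-300
toy_mrna <- function() {
  transcript_model("tx1", "chr1", "+", matrix(c(101L, 400L), ncol = 2),
                   cds_span = c(151L, 300L), biotype = "mRNA")
}

random_granges <- function(n, chrom = "chr1", max_pos = 1000L,
                           max_width = 30L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1L),
                         name = paste0("iv", seq_len(n)),
                         score = round(runif(n), 3))
}

# brute-force merge of >=1 nt overlapping intervals via pairwise union-find
brute_merge <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && starts[i] <= ends[j] && starts[j] <= ends[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- t(vapply(unique(roots), function(r)
    c(min(starts[roots == r]), max(ends[roots == r])), numeric(2)))
  out[order(out[, 1L]), , drop = FALSE]
}
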