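# Independent oracles used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n*m) brute-force pairwise overlap: for each interval in x, is there any
# half-open overlap in y?
brute_overlaps_any <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    any(x$chrom[i] == y$chrom & x$start[i] < y$end & y$start < x$end[i])
  }, logical(1))
}

# Exhaustive 6-mer enumeration: every position whose substring equals the
# motif (or its reverse complement).
brute_scan <- function(seq, motif = "CACGTG") {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  L <- nchar(seq)
  w <- nchar(motif)
  if (L < w) return(integer(0))
  subs <- substring(seq, 1:(L - w + 1), w:L)
  sort(unique(which(subs == motif | subs == rc) - 1L))
}

# Random candidate-row flag matrix for funnel property tests.
random_candidate_rows <- function(n, seed) {
  withr::with_seed(seed, {
    bound <- runif(n) < 0.6
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n)),
      array_log_fc = runif(n, 1, 3),
      array_adj_p = runif(n, 0, 0.05),
      rnaseq_log_fc = runif(n, 1, 3),
      rnaseq_adj_p = runif(n, 0, 0.05),
      tm_list = TRUE,
      ebox_near_tss = runif(n) < 0.7,
      mycn_bound_near_tss = bound,
      ebox_occupied = bound & runif(n) < 0.7,
      limited_normal_expression = runif(n) < 0.4,
      not_secreted = runif(n) < 0.8
    )
  })
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"), span = 10000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    tibble::tibble(
      chrom = sample(chroms, n, replace = TRUE),
      start = start,
      end = start + sample.int(200, n, replace = TRUE)
    )
  })
}
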