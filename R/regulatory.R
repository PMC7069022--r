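# Promoter-window geometry, E-box motif scanning, peak filtering against a
# q-value threshold and a genomic blacklist, and per-cell-line occupancy
# calls. All genomic coordinates are 0-based half-open (BED convention).

#' Do two genomic intervals overlap?
#'
#' Half-open convention: `[a.start, a.end)` overlaps `[b.start, b.end)` iff
#' they share a chromosome and `a.start < b.end` and `b.start < a.end`.
#' Adjacent intervals do not overlap. Vectorised with recycling.
#'
#' @param a,b Data frames (or lists) with `chrom`, `start`, `end`.
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# For each row of x, is there any overlapping row in y? Uses the
# interval-tree machinery in GenomicRanges (intervals are shifted to 1-based
# closed on the way in).
overlaps_any <- function(x, y) {
  if (is.null(y) || nrow(y) == 0) {
    return(rep(FALSE, nrow(x)))
  }
  if (nrow(x) == 0) {
    return(logical(0))
  }
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
  GenomicRanges::countOverlaps(gx, gy) > 0
}

#' Build strand-oriented promoter windows around TSSs
#'
#' For a plus-strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a minus-strand gene upstream extends to the right, giving
#' `[tss - downstream + 1, tss + upstream + 1)`. Windows are clipped at
#' chromosome start (coordinate 0).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss` (0-based position of
#'   the transcription start site) and `strand` (`+` or `-`).
#' @param upstream,downstream Window extents in bp (>= 0). The default of
#'   1 kb on each side is the package's operational definition of
#'   "TSS-proximal".
#' @return Tibble with `gene_id`, `chrom`, `win_start`, `win_end`, `strand`,
#'   `tss`.
#' @export
promoter_windows <- function(genes, upstream = 1000, downstream = 1000) {
  if (upstream < 0 || downstream < 0) {
    abort_config("`upstream` and `downstream` must be >= 0.")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_data("Gene strands must be '+' or '-'.")
  }
  mutate(genes,
    win_start = pmax(0L, as.integer(ifelse(.data$strand == "+",
                                           .data$tss - upstream,
                                           .data$tss - downstream + 1L))),
    win_end = as.integer(ifelse(.data$strand == "+",
                                .data$tss + downstream,
                                .data$tss + upstream + 1L))
  )[, c("gene_id", "chrom", "win_start", "win_end", "strand", "tss")]
}

#' Scan promoter sequences for E-box motifs
#'
#' Reports every (possibly overlapping) occurrence of each configured motif
#' in each promoter sequence. Sequences are expected strand-oriented (5' to
#' 3' along the gene) with the TSS at index `upstream` (0-based), so the
#' reported `offset_from_tss` is negative upstream of the TSS. The canonical
#' E-box CACGTG is its own reverse complement, so scanning it forward is
#' strand-agnostic; for non-palindromic motifs the reverse complement is
#' scanned too and duplicate positions are collapsed.
#'
#' @param promoters Named [Biostrings::DNAStringSet] or named character
#'   vector of promoter sequences over A/C/G/T/N.
#' @param upstream Number of bp upstream of the TSS included in each
#'   sequence (the TSS sits at this 0-based index).
#' @param motifs Character vector of motifs; default the canonical CACGTG
#'   only. Degenerate E-box variants (e.g. CATGTG) may be added explicitly.
#' @return Tibble with `gene_id`, `motif`, `start_in_promoter` (0-based) and
#'   `offset_from_tss`.
#' @export
scan_eboxes <- function(promoters, upstream = 1000, motifs = "CACGTG") {
  if (length(motifs) == 0) abort_config("`motifs` must be non-empty.")
  if (is.character(promoters)) {
    bad <- grepl("[^ACGTNacgtn]", promoters)
    if (any(bad)) {
      abort_data(sprintf("Sequence '%s' contains non-IUPAC characters.",
                         names(promoters)[which(bad)[1]] %||% which(bad)[1]))
    }
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  }
  if (is.null(names(promoters))) {
    abort_data("Promoter sequences must be named by gene identifier.")
  }
  hits <- map_dfr(motifs, function(m) {
    pats <- unique(c(m, as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))))
    map_dfr(pats, function(p) {
      mm <- Biostrings::vmatchPattern(p, promoters)
      starts <- setNames(Biostrings::startIndex(mm), names(promoters))
      imap_dfr(starts, function(s, gene) {
        if (is.null(s) || length(s) == 0) return(NULL)
        tibble(gene_id = gene, motif = m, start_in_promoter = as.integer(s) - 1L)
      })
    })
  })
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), motif = character(),
                  start_in_promoter = integer(), offset_from_tss = integer()))
  }
  hits <- distinct(hits, .data$gene_id, .data$motif, .data$start_in_promoter)
  hits <- mutate(hits, offset_from_tss = .data$start_in_promoter - as.integer(upstream))
  arrange(hits, .data$gene_id, .data$start_in_promoter)
}

#' Map promoter-coordinate motif hits to genomic intervals
#'
#' @param hits Output of [scan_eboxes()].
#' @param windows Output of [promoter_windows()] for the same genes and the
#'   same `upstream` geometry the sequences were extracted with.
#' @return `hits` with genomic `chrom`, `start`, `end` columns (0-based
#'   half-open).
#' @export
motif_hits_genomic <- function(hits, windows) {
  missing <- setdiff(unique(hits$gene_id), windows$gene_id)
  if (length(missing) > 0) {
    abort_data(sprintf("No promoter window for gene(s): %s",
                       paste(missing, collapse = ", ")))
  }
  width <- nchar(hits$motif)
  out <- left_join(hits, windows, by = "gene_id")
  mutate(out,
    start = as.integer(ifelse(.data$strand == "+",
                              .data$win_start + .data$start_in_promoter,
                              .data$win_end - .data$start_in_promoter - width)),
    end = .data$start + width
  )[, c("gene_id", "motif", "start_in_promoter", "offset_from_tss",
        "chrom", "start", "end")]
}

#' Filter ChIP peaks on q-value and blacklist
#'
#' Retains peaks with `q_value <= q_threshold` (inclusive at the boundary,
#' matching the usual peak-calling convention) that have zero overlap with
#' every blacklist interval: any 1-bp overlap removes the peak. The
#' operation is idempotent and a `NULL` blacklist is equivalent to an empty
#' one.
#'
#' @param peaks Peak tibble (see [read_narrowpeak()]).
#' @param q_threshold q-value cutoff in (0, 1); default 0.05.
#' @param blacklist Optional tibble of intervals (`chrom`, `start`, `end`).
#' @return Filtered peak tibble, input order preserved.
#' @export
filter_peaks <- function(peaks, q_threshold = 0.05, blacklist = NULL) {
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort_config("`q_threshold` must lie strictly in (0, 1).")
  }
  keep <- peaks$q_value <= q_threshold
  keep <- keep & !overlaps_any(peaks, blacklist)
  peaks[keep, , drop = FALSE]
}

#' Call per-gene MYCN occupancy from filtered peaks
#'
#' Per cell line and gene: `mycn_bound_near_tss` is true iff some filtered
#' peak overlaps the gene's promoter window; `ebox_occupied` is true iff
#' some filtered peak overlaps (by at least 1 bp) a motif-hit interval in
#' that promoter. Occupancy at an E-box implies binding near the TSS. The
#' consensus requires each call in at least `min_lines` cell lines
#' (default 1: any line).
#'
#' @param peaks_by_line Named list of filtered peak tibbles, one per cell
#'   line.
#' @param windows Output of [promoter_windows()].
#' @param motif_hits Output of [motif_hits_genomic()]; every gene carrying a
#'   motif hit must have a promoter window.
#' @param min_lines Minimum number of cell lines supporting a consensus call.
#' @return A list with `calls` (tibble: `gene_id`, `cell_line`,
#'   `mycn_bound_near_tss`, `ebox_occupied`, `n_supporting_peaks`) and
#'   `consensus` (tibble: `gene_id`, `mycn_bound_near_tss`, `ebox_occupied`,
#'   `n_lines_bound`, `n_lines_occupied`).
#' @export
call_occupancy <- function(peaks_by_line, windows, motif_hits, min_lines = 1) {
  if (is.null(names(peaks_by_line)) || any(names(peaks_by_line) == "")) {
    abort_config("`peaks_by_line` must be a named list (one peak set per cell line).")
  }
  missing <- setdiff(unique(motif_hits$gene_id), windows$gene_id)
  if (length(missing) > 0) {
    abort_data(sprintf("Gene(s) without a promoter window: %s",
                       paste(missing, collapse = ", ")))
  }
  win_iv <- tibble(gene_id = windows$gene_id, chrom = windows$chrom,
                   start = windows$win_start, end = windows$win_end)
  calls <- imap_dfr(peaks_by_line, function(pk, cl) {
    bound <- overlaps_any(win_iv, pk)
    occ_hits <- if (nrow(motif_hits) > 0) {
      motif_hits$gene_id[overlaps_any(motif_hits, pk)]
    } else {
      character(0)
    }
    occupied <- win_iv$gene_id %in% occ_hits
    n_sup <- if (nrow(pk) > 0) {
      gw <- GenomicRanges::GRanges(win_iv$chrom,
                                   IRanges::IRanges(win_iv$start + 1L, win_iv$end))
      gp <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
      GenomicRanges::countOverlaps(gw, gp)
    } else {
      rep(0L, nrow(win_iv))
    }
    tibble(
      gene_id = win_iv$gene_id,
      cell_line = cl,
      mycn_bound_near_tss = bound,
      ebox_occupied = occupied & bound,
      n_supporting_peaks = as.integer(n_sup)
    )
  })
  consensus <- calls |>
    group_by(.data$gene_id) |>
    summarise(
      n_lines_bound = sum(.data$mycn_bound_near_tss),
      n_lines_occupied = sum(.data$ebox_occupied),
      .groups = "drop"
    ) |>
    mutate(
      mycn_bound_near_tss = .data$n_lines_bound >= min_lines,
      ebox_occupied = .data$n_lines_occupied >= min_lines
    ) |>
    select("gene_id", "mycn_bound_near_tss", "ebox_occupied",
           "n_lines_bound", "n_lines_occupied")
  list(calls = calls, consensus = consensus)
}

#' Toy local-Poisson peak caller
#'
#' A desk-scale enrichment caller used to generate peak fixtures from
#' coverage vectors: per position, the background rate is the maximum of the
#' control's local means over the supplied window sizes and its global mean;
#' the upper Poisson tail gives a p-value, Benjamini-Hochberg adjusts across
#' positions, and contiguous significant runs (bridging gaps up to
#' `merge_gap`) are merged into peaks whose q-value is the run's minimum
#' adjusted p and whose signal is the run's mean coverage scaled per million.
#'
#' @param coverage,control Equal-length non-negative integer vectors of
#'   per-position read coverage.
#' @param window_sizes Local-background window widths in bp.
#' @param alpha Significance level on the adjusted p-values.
#' @param merge_gap Maximum gap (bp) bridged when merging significant runs.
#' @return Peak tibble with `start`, `end` (0-based half-open positions in
#'   the vector), `q_value` and `signal`.
#' @export
toy_local_poisson_caller <- function(coverage, control,
                                     window_sizes = c(200, 1000),
                                     alpha = 0.05, merge_gap = 10) {
  if (length(coverage) != length(control)) {
    abort_data("`coverage` and `control` must have the same length.")
  }
  if (any(coverage < 0) || any(control < 0)) {
    abort_data("Coverage vectors must be non-negative.")
  }
  n <- length(coverage)
  lambda <- rep(mean(control), n)
  for (w in window_sizes) {
    half <- max(1L, as.integer(w) %/% 2L)
    cs <- cumsum(c(0, control))
    lo <- pmax(0L, seq_len(n) - 1L - half)
    hi <- pmin(n, seq_len(n) + half)
    local_mean <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
    lambda <- pmax(lambda, local_mean)
  }
  p <- ppois(coverage - 1, lambda, lower.tail = FALSE)
  adj <- benjamini_hochberg(p)
  sig <- adj <= alpha & coverage > lambda
  if (!any(sig)) {
    return(tibble(start = integer(), end = integer(),
                  q_value = double(), signal = double()))
  }
  # bridge short gaps, then take runs
  pos <- which(sig)
  run_id <- cumsum(c(1L, diff(pos) > merge_gap + 1L))
  total <- sum(coverage)
  map_dfr(split(pos, run_id), function(ps) {
    s <- min(ps) - 1L
    e <- max(ps)
    tibble(
      start = s,
      end = e,
      q_value = min(adj[seq(s + 1L, e)]),
      signal = mean(coverage[seq(s + 1L, e)]) * 1e6 / max(total, 1)
    )
  })
}
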