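#' Run the complete target-nomination pipeline
#'
#' Orchestrates the whole funnel on in-memory inputs: the status-stratified
#' screen on the count platform, the quantile-stratified screen on the
#' intensity platform (derived from the counts by [log_cpm()] when no
#' separate array matrix is supplied), promoter-window construction, E-box
#' scanning, peak filtering, occupancy calling, annotation filtering,
#' candidate assembly and the attrition funnel.
#'
#' @param counts Count [expression_matrix()] (genes x samples).
#' @param sample_annotation Tibble with `sample_id`, `mycn_status`.
#' @param array Optional intensity expression matrix for the second
#'   platform; defaults to `log_cpm(counts)`.
#' @param array_annotation Sample annotation for `array` (defaults to
#'   `sample_annotation`).
#' @param driver_gene_id Driver gene used for quantile stratification.
#' @param quantile_fraction Tail fraction for the quantile screen.
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param promoters Strand-oriented promoter sequences (named
#'   [Biostrings::DNAStringSet]).
#' @param upstream,downstream Promoter-window extents in bp.
#' @param motifs E-box motif set for [scan_eboxes()].
#' @param peaks_by_line Named list of peak tibbles, one per ChIP cell line.
#' @param blacklist Optional blacklist interval tibble.
#' @param q_threshold Peak q-value cutoff.
#' @param min_lines Cell-line quorum for consensus occupancy.
#' @param localization,tissues,cns_tissues,expr_threshold Annotation-filter
#'   inputs, see [filter_verdicts()].
#' @param min_log_fc,max_adj_p Screen thresholds.
#' @param rank_by Final ranking key, see [apply_funnel()].
#' @return A list with the `funnel_report` (`$report`), the candidate matrix
#'   (`$rows`), both screens (`$screen_rnaseq`, `$screen_array`), the
#'   occupancy calls (`$occupancy`) and the filter verdicts (`$verdicts`).
#' @export
run_funnel_pipeline <- function(counts, sample_annotation,
                                array = NULL, array_annotation = NULL,
                                driver_gene_id = "MYCN",
                                quantile_fraction = 0.15,
                                genes, promoters,
                                upstream = 1000, downstream = 1000,
                                motifs = "CACGTG",
                                peaks_by_line, blacklist = NULL,
                                q_threshold = 0.05, min_lines = 1,
                                localization, tissues, cns_tissues,
                                expr_threshold = 1,
                                min_log_fc = 1, max_adj_p = 0.05,
                                rank_by = c("adj_p", "log_fc")) {
  rank_by <- match.arg(rank_by)

  groups_status <- stratify(counts, sample_annotation, mode = "by_status")
  screen_rnaseq <- differential_screen(counts, groups_status,
                                       min_log_fc = min_log_fc,
                                       max_adj_p = max_adj_p)

  if (is.null(array)) array <- log_cpm(counts)
  if (is.null(array_annotation)) array_annotation <- sample_annotation
  groups_quant <- stratify(array, array_annotation, mode = "by_quantile",
                           driver_gene_id = driver_gene_id,
                           quantile_fraction = quantile_fraction)
  screen_array <- differential_screen(array, groups_quant,
                                      min_log_fc = min_log_fc,
                                      max_adj_p = max_adj_p)

  windows <- promoter_windows(genes, upstream = upstream, downstream = downstream)
  hits <- scan_eboxes(promoters, upstream = upstream, motifs = motifs)
  hits_g <- motif_hits_genomic(hits, windows)
  filtered <- lapply(peaks_by_line, filter_peaks,
                     q_threshold = q_threshold, blacklist = blacklist)
  occupancy <- call_occupancy(filtered, windows, hits_g, min_lines = min_lines)

  verdicts <- filter_verdicts(localization, tissues, cns_tissues,
                              expr_threshold = expr_threshold)

  rows <- assemble_candidates(screen_rnaseq, screen_array, verdicts,
                              motif_genes = unique(hits_g$gene_id),
                              occupancy = occupancy$consensus,
                              min_log_fc = min_log_fc, max_adj_p = max_adj_p)
  report <- apply_funnel(rows, rank_by = rank_by)
  list(report = report, rows = rows,
       screen_rnaseq = screen_rnaseq, screen_array = screen_array,
       occupancy = occupancy, verdicts = verdicts)
}
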