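#' Bundled neuroblastoma candidate-matrix example
#'
#' A curated 14-gene candidate matrix from a published screen for
#' differentially overexpressed plasma-membrane genes in MYCN-amplified
#' neuroblastoma, encoded exactly as reported: per-gene log fold changes and
#' adjusted p-values on the microarray and RNA-seq platforms, plus the six
#' Boolean evidence flags the funnel consumes. NME1's microarray log fold
#' change was not reported and is carried as `NA`; the gene is retained
#' because its adjusted p-value qualifies. The matrix serves as a worked
#' example and as a regression fixture: [apply_funnel()] on it attrites
#' 14 -> 11 -> 10 -> 8 -> 3 -> 2.
#'
#' @return A candidate-row tibble in the shape produced by
#'   [assemble_candidates()].
#' @examples
#' tidy(apply_funnel(nb_candidate_matrix()))
#' @export
nb_candidate_matrix <- function() {
  rows <- tibble::tribble(
    ~gene_id,   ~array_log_fc, ~array_adj_p, ~rnaseq_log_fc, ~rnaseq_adj_p, ~ebox_near_tss, ~mycn_bound_near_tss, ~ebox_occupied, ~limited_normal_expression, ~not_secreted,
    "CAMKV",    1.47,          1.04e-06,     1.73,           2.02e-06,      TRUE,           TRUE,                 TRUE,           TRUE,                       TRUE,
    "CPNE7",    1.38,          1.32e-09,     2.75,           1.33e-07,      TRUE,           TRUE,                 TRUE,           FALSE,                      FALSE,
    "GLRA2",    1.52,          1.3487e-03,   2.80,           1.27e-05,      TRUE,           FALSE,                FALSE,          FALSE,                      FALSE,
    "HHIP",     1.38,          1.52e-05,     1.89,           2.05e-06,      TRUE,           TRUE,                 TRUE,           FALSE,                      FALSE,
    "KCNH5",    1.45,          1.737e-04,    2.11,           5.154e-03,     TRUE,           TRUE,                 FALSE,          FALSE,                      FALSE,
    "LGR5",     1.26,          3.63e-04,     2.38,           1.43e-06,      FALSE,          FALSE,                FALSE,          FALSE,                      FALSE,
    "TMEM131L", 1.06,          3.31e-06,     1.05,           4.23e-11,      TRUE,           TRUE,                 TRUE,           FALSE,                      FALSE,
    "LRRC7",    1.29,          1.7533e-03,   2.02,           2.54e-05,      TRUE,           TRUE,                 TRUE,           TRUE,                       FALSE,
    "NME1",     NA,            2.00e-08,     1.00,           1.17e-06,      TRUE,           TRUE,                 TRUE,           TRUE,                       TRUE,
    "SLC30A3",  1.10,          6.26e-08,     4.06,           2.64e-10,      FALSE,          FALSE,                FALSE,          FALSE,                      FALSE,
    "SLC16A1",  1.37,          1.06e-07,     1.08,           9.40e-10,      TRUE,           TRUE,                 TRUE,           FALSE,                      FALSE,
    "SLCO5A1",  1.84,          8.96e-13,     2.08,           3.93e-10,      TRUE,           TRUE,                 TRUE,           FALSE,                      FALSE,
    "TMEM97",   1.89,          3.49e-11,     1.56,           9.48e-14,      TRUE,           TRUE,                 FALSE,          FALSE,                      FALSE,
    "SLC44A5",  1.42,          1.01e-05,     1.33,           2.541e-03,     FALSE,          FALSE,                FALSE,          FALSE,                      FALSE
  )
  dplyr::mutate(rows, tm_list = TRUE, .after = "rnaseq_adj_p")
}
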