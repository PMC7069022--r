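# Candidate-matrix assembly, the ordered attrition funnel, candidate
# ranking, and driver-candidate co-expression.

funnel_stage_names <- function() {
  c("candidate_matrix", "ebox_near_tss", "mycn_bound_near_tss",
    "ebox_occupied", "limited_normal_expression", "not_secreted")
}

#' Assemble the per-gene candidate matrix
#'
#' One row per gene that passes the differential-expression screen on *both*
#' platforms and carries the plasma-membrane designation; the remaining
#' evidence (E-box near TSS, occupancy, tissue restriction, secretion) is
#' attached as Boolean flags, with genes absent from a source getting
#' `FALSE`. A gene whose array log fold change is missing (`NA`) is admitted
#' on its array adjusted p-value alone.
#'
#' @param de_rnaseq,de_array Per-gene DE tables (tibbles with `gene_id`,
#'   `log_fc`, `adj_p` and optionally a precomputed `pass` column;
#'   [tidy()] of a [differential_screen()] result works directly).
#' @param verdicts Annotation filter verdicts from [filter_verdicts()].
#' @param motif_genes Character vector (or tibble with `gene_id`) of genes
#'   with at least one TSS-proximal E-box.
#' @param occupancy Consensus occupancy tibble from [call_occupancy()]
#'   (`$consensus`), or `NULL` for no occupancy evidence.
#' @param min_log_fc,max_adj_p Screen thresholds used when a `pass` column
#'   is not supplied.
#' @return Tibble of candidate rows: `gene_id`, the four platform
#'   statistics, and the six Boolean flags.
#' @export
assemble_candidates <- function(de_rnaseq, de_array, verdicts, motif_genes,
                                occupancy = NULL,
                                min_log_fc = 1, max_adj_p = 0.05) {
  de_rnaseq <- as_de_table(de_rnaseq, min_log_fc, max_adj_p, allow_na_lfc = FALSE)
  de_array <- as_de_table(de_array, min_log_fc, max_adj_p, allow_na_lfc = TRUE)
  if (anyDuplicated(de_rnaseq$gene_id) || anyDuplicated(de_array$gene_id)) {
    abort_data("Duplicate gene identifiers in a differential-expression table.")
  }
  if (is.data.frame(motif_genes)) motif_genes <- motif_genes$gene_id
  motif_genes <- unique(motif_genes)
  keep <- intersect(de_rnaseq$gene_id[de_rnaseq$pass],
                    de_array$gene_id[de_array$pass])
  keep <- intersect(keep, verdicts$gene_id[verdicts$membrane])
  rows <- tibble(gene_id = keep) |>
    left_join(rename(de_array[, c("gene_id", "log_fc", "adj_p")],
                     array_log_fc = "log_fc", array_adj_p = "adj_p"),
              by = "gene_id") |>
    left_join(rename(de_rnaseq[, c("gene_id", "log_fc", "adj_p")],
                     rnaseq_log_fc = "log_fc", rnaseq_adj_p = "adj_p"),
              by = "gene_id") |>
    mutate(
      tm_list = TRUE,
      ebox_near_tss = .data$gene_id %in% motif_genes
    )
  if (is.null(occupancy) || nrow(occupancy) == 0) {
    rows$mycn_bound_near_tss <- FALSE
    rows$ebox_occupied <- FALSE
  } else {
    occ <- occupancy[, c("gene_id", "mycn_bound_near_tss", "ebox_occupied")]
    rows <- left_join(rows, occ, by = "gene_id") |>
      mutate(
        mycn_bound_near_tss = !is.na(.data$mycn_bound_near_tss) & .data$mycn_bound_near_tss,
        ebox_occupied = !is.na(.data$ebox_occupied) & .data$ebox_occupied
      )
  }
  rows <- left_join(rows,
                    verdicts[, c("gene_id", "limited_normal_expression", "not_secreted")],
                    by = "gene_id") |>
    mutate(
      ebox_occupied = .data$ebox_occupied & .data$mycn_bound_near_tss,
      limited_normal_expression = !is.na(.data$limited_normal_expression) &
        .data$limited_normal_expression,
      not_secreted = !is.na(.data$not_secreted) & .data$not_secreted
    )
  arrange(rows, .data$gene_id)
}

as_de_table <- function(de, min_log_fc, max_adj_p, allow_na_lfc) {
  if (inherits(de, "de_screen")) de <- de$table
  de <- as_tibble(de)
  if (!"pass" %in% names(de)) {
    if (allow_na_lfc) {
      de$pass <- (is.na(de$log_fc) | de$log_fc > min_log_fc) & de$adj_p < max_adj_p
    } else {
      de$pass <- screen_pass(de$log_fc, de$adj_p, min_log_fc, max_adj_p)
    }
  }
  de
}

#' Apply the ordered attrition funnel
#'
#' Stages are applied conjunctively in a fixed order: (1) membership in the
#' candidate matrix, (2) E-box near the TSS, (3) MYCN bound near the TSS,
#' (4) E-box occupied by MYCN, (5) normal-tissue expression limited to the
#' CNS, (6) not secreted. Survivor sets are nested by construction; because
#' the stages are conjunctive the final set does not depend on their order,
#' only the intermediate counts do.
#'
#' @param rows Candidate rows from [assemble_candidates()] (or any tibble
#'   with `gene_id` and the six Boolean flag columns).
#' @param rank_by Primary ranking key for the final candidates:
#'   `"adj_p"` (ascending RNA-seq adjusted p, the default) or `"log_fc"`
#'   (descending RNA-seq log fold change). The other statistic is the
#'   tie-break, with `gene_id` as the final deterministic tie-break.
#' @return An object of class `funnel_report`; use [tidy()] for per-stage
#'   survivor counts, [glance()] for a one-row summary, `$stages` for the
#'   survivor sets and `$final_ranked` for the ranked nominations.
#' @export
apply_funnel <- function(rows, rank_by = c("adj_p", "log_fc")) {
  rank_by <- match.arg(rank_by)
  flags <- funnel_stage_names()[-1]
  for (f in flags) {
    if (!f %in% names(rows)) abort_data(sprintf("Missing flag column '%s'.", f))
    if (anyNA(rows[[f]])) abort_data(sprintf("Flag column '%s' contains NA.", f))
  }
  if (anyDuplicated(rows$gene_id)) {
    abort_data("Duplicate gene identifiers in the candidate matrix.")
  }
  if (any(rows$ebox_occupied & !rows$mycn_bound_near_tss)) {
    abort_data("Invariant violation: ebox_occupied implies mycn_bound_near_tss.")
  }
  alive <- rep(TRUE, nrow(rows))
  survivors <- list(rows$gene_id)
  for (f in flags) {
    alive <- alive & rows[[f]]
    survivors <- c(survivors, list(rows$gene_id[alive]))
  }
  stages <- tibble(
    stage = funnel_stage_names(),
    n_survivors = vapply(survivors, length, integer(1)),
    survivors = survivors
  )
  final <- rank_candidates(rows, survivors[[length(survivors)]], rank_by = rank_by)
  structure(
    list(stages = stages, final_ranked = final, rows = rows, rank_by = rank_by),
    class = "funnel_report"
  )
}

#' Rank the final candidates
#'
#' Default ordering is by ascending RNA-seq adjusted p-value, ties broken by
#' descending RNA-seq log fold change, then by gene identifier. With
#' `rank_by = "log_fc"` the fold change becomes the primary key. (On real
#' candidate tables the two keys can disagree; the report carries both
#' statistics so the choice is visible.)
#'
#' @param rows Candidate rows (must contain `rnaseq_adj_p` and
#'   `rnaseq_log_fc`).
#' @param survivors Character vector of surviving gene identifiers.
#' @inheritParams apply_funnel
#' @return Tibble `gene_id`, `rnaseq_adj_p`, `rnaseq_log_fc` in rank order.
#' @export
rank_candidates <- function(rows, survivors, rank_by = c("adj_p", "log_fc")) {
  rank_by <- match.arg(rank_by)
  out <- rows[rows$gene_id %in% survivors,
              c("gene_id", "rnaseq_adj_p", "rnaseq_log_fc")]
  if (rank_by == "adj_p") {
    out <- arrange(out, .data$rnaseq_adj_p, dplyr::desc(.data$rnaseq_log_fc),
                   .data$gene_id)
  } else {
    out <- arrange(out, dplyr::desc(.data$rnaseq_log_fc), .data$rnaseq_adj_p,
                   .data$gene_id)
  }
  out
}

#' Driver-candidate co-expression
#'
#' Pearson correlation between two genes' expression vectors across samples,
#' with a two-sided p-value from the t transform on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x An expression matrix.
#' @param gene_a,gene_b Gene identifiers present in `x`.
#' @return One-row tibble: `gene_a`, `gene_b`, `r`, `p`, `n`.
#' @export
correlate <- function(x, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% x$gene_id) abort_data(sprintf("Gene '%s' is not in the matrix.", g))
  }
  va <- as.numeric(x[x$gene_id == gene_a, -1])
  vb <- as.numeric(x[x$gene_id == gene_b, -1])
  n <- length(va)
  if (n < 3) abort_data("Correlation needs at least 3 samples.")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort_data("Correlation is undefined for a zero-variance expression vector.")
  }
  ct <- cor.test(va, vb, method = "pearson")
  tibble(gene_a = gene_a, gene_b = gene_b,
         r = unname(ct$estimate), p = ct$p.value, n = n)
}
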