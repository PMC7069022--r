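# Annotation-based filters: plasma-membrane designation from per-category
# localization confidence scores, restriction of normal-tissue expression to
# the CNS, and exclusion of secreted products. Each filter is a pure
# predicate over a per-gene record.

default_membrane_categories <- function() c("Plasma membrane", "Cell surface")

#' Plasma-membrane designation from localization confidence scores
#'
#' A gene is designated plasma-membrane when the maximum confidence score
#' across all its GO cellular-component categories is attained by a membrane
#' category ("Plasma membrane" or "Cell surface", matched
#' case-insensitively) and that maximum is at least 3 (scores run 0-5). A
#' membrane category sharing the maximum with a non-membrane category still
#' passes: the rule constrains only which category attains the max.
#'
#' @param localization Long tibble with `gene_id`, `category`, `score`
#'   (integer 0-5).
#' @param membrane_categories Synonyms counted as membrane categories.
#' @param min_score Minimum qualifying maximum score (default 3).
#' @return Tibble with `gene_id` and logical `membrane`.
#' @export
membrane_designation <- function(localization,
                                 membrane_categories = default_membrane_categories(),
                                 min_score = 3) {
  if (nrow(localization) == 0 || anyNA(localization$score)) {
    abort_data("Localization scores must be non-empty and complete.")
  }
  if (any(localization$score < 0 | localization$score > 5)) {
    abort_data("Localization confidence scores must lie in [0, 5].")
  }
  mem <- tolower(membrane_categories)
  localization |>
    group_by(.data$gene_id) |>
    summarise(
      membrane = max(.data$score) >= min_score &
        any(tolower(.data$category[.data$score == max(.data$score)]) %in% mem),
      .groups = "drop"
    )
}

#' Normal-tissue expression restricted to the CNS?
#'
#' True for a gene iff its expression is at or below `expr_threshold` in
#' every tissue *not* declared as CNS; CNS tissues are unconstrained (the
#' intended therapeutic is a biologic that does not cross the blood-brain
#' barrier, so brain expression is tolerated).
#'
#' @param tissues Wide tibble: `gene_id` plus one numeric column per tissue.
#' @param cns_tissues Character vector naming the CNS columns; must be a
#'   subset of the tissue columns.
#' @param expr_threshold Expression cutoff (TPM-like units), default 1.
#' @return Tibble with `gene_id` and logical `limited_normal_expression`.
#' @export
normal_tissue_filter <- function(tissues, cns_tissues, expr_threshold = 1) {
  tissue_cols <- setdiff(names(tissues), "gene_id")
  if (length(tissue_cols) == 0) {
    abort_data("The tissue table has no tissue columns.")
  }
  if (!all(cns_tissues %in% tissue_cols)) {
    abort_data(sprintf("CNS tissue(s) not in the table: %s",
                       paste(setdiff(cns_tissues, tissue_cols), collapse = ", ")))
  }
  if (expr_threshold < 0) abort_config("`expr_threshold` must be >= 0.")
  non_cns <- setdiff(tissue_cols, cns_tissues)
  m <- as.matrix(tissues[, non_cns, drop = FALSE])
  tibble(
    gene_id = tissues$gene_id,
    limited_normal_expression = if (length(non_cns) == 0) {
      rep(TRUE, nrow(tissues))
    } else {
      apply(m <= expr_threshold, 1, all)
    }
  )
}

#' Exclude genes with secreted products
#'
#' @param secretion Tibble with `gene_id` and logical `secreted` (one row
#'   per gene; the long localization table from [simulate_annotations()] is
#'   accepted and de-duplicated).
#' @return Tibble with `gene_id` and logical `not_secreted`.
#' @export
secretion_filter <- function(secretion) {
  rec <- distinct(secretion[, c("gene_id", "secreted")])
  if (anyDuplicated(rec$gene_id)) {
    abort_data("Conflicting secreted flags for the same gene.")
  }
  tibble(gene_id = rec$gene_id, not_secreted = !rec$secreted)
}

#' Combined annotation filter verdicts
#'
#' Joins the three annotation filters into one verdict per gene. Genes
#' missing from a source fail that filter (no tri-state: every flag is
#' populated).
#'
#' @inheritParams membrane_designation
#' @inheritParams normal_tissue_filter
#' @param secretion See [secretion_filter()]; defaults to the `secreted`
#'   column of `localization` when present.
#' @return Tibble with `gene_id`, `membrane`, `limited_normal_expression`,
#'   `not_secreted`.
#' @export
filter_verdicts <- function(localization, tissues, cns_tissues,
                            expr_threshold = 1, secretion = NULL,
                            membrane_categories = default_membrane_categories()) {
  if (is.null(secretion)) {
    if (!"secreted" %in% names(localization)) {
      abort_data("Supply `secretion` or include a `secreted` column in `localization`.")
    }
    secretion <- localization
  }
  mem <- membrane_designation(localization, membrane_categories)
  ltd <- normal_tissue_filter(tissues, cns_tissues, expr_threshold)
  sec <- secretion_filter(secretion)
  genes <- unique(c(mem$gene_id, ltd$gene_id, sec$gene_id))
  tibble(gene_id = genes) |>
    left_join(mem, by = "gene_id") |>
    left_join(ltd, by = "gene_id") |>
    left_join(sec, by = "gene_id") |>
    mutate(across(c("membrane", "limited_normal_expression", "not_secreted"),
                  ~ !is.na(.x) & .x))
}
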