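# tidy()/glance()/autoplot()/print() methods for the two fitted result
# types: differential-expression screens and funnel reports.

#' @export
print.de_screen <- function(x, ...) {
  cat(sprintf(
    "Differential-expression screen: %d genes, %d pass (log_fc > %g, adj_p < %g)\n",
    nrow(x$table), length(x$survivors),
    x$thresholds$min_log_fc, x$thresholds$max_adj_p
  ))
  cat(sprintf("Prior df %.2f, prior variance %.4f\n", x$df_prior, x$s2_prior))
  invisible(x)
}

#' Tidy a differential-expression screen
#' @param x A `de_screen` object from [differential_screen()].
#' @param ... Unused.
#' @return The per-gene tibble: `gene_id`, `log_fc`, `mean_expression`,
#'   `moderated_t`, `raw_p`, `adj_p`, `pass`.
#' @export
tidy.de_screen <- function(x, ...) x$table

#' One-row summary of a differential-expression screen
#' @inheritParams tidy.de_screen
#' @return Tibble with gene counts, thresholds and the estimated prior.
#' @export
glance.de_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_pass = length(x$survivors),
    min_log_fc = x$thresholds$min_log_fc,
    max_adj_p = x$thresholds$max_adj_p,
    df_prior = x$df_prior,
    s2_prior = x$s2_prior
  )
}

#' Volcano plot of a differential-expression screen
#' @inheritParams tidy.de_screen
#' @param object A `de_screen` object.
#' @return A ggplot: log fold change against -log10 adjusted p, screen
#'   survivors highlighted and thresholds drawn.
#' @export
autoplot.de_screen <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log_fc,
                                    y = -log10(.data$adj_p),
                                    colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$thresholds$min_log_fc,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$max_adj_p),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (high vs low)",
                  y = "-log10 adjusted p", colour = "passes screen") +
    ggplot2::theme_minimal()
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Target-nomination funnel\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-28s %d\n", x$stages$stage[i], x$stages$n_survivors[i]))
  }
  if (nrow(x$final_ranked) > 0) {
    cat(sprintf("Final nominations (ranked by %s): %s\n", x$rank_by,
                paste(x$final_ranked$gene_id, collapse = ", ")))
  } else {
    cat("No final nominations.\n")
  }
  invisible(x)
}

#' Tidy a funnel report
#' @param x A `funnel_report` from [apply_funnel()].
#' @param ... Unused.
#' @return Tibble with `stage` and `n_survivors`, in funnel order.
#' @export
tidy.funnel_report <- function(x, ...) {
  x$stages[, c("stage", "n_survivors")]
}

#' One-row summary of a funnel report
#' @inheritParams tidy.funnel_report
#' @return Tibble with initial/final sizes and the top-ranked gene.
#' @export
glance.funnel_report <- function(x, ...) {
  tibble(
    n_stages = nrow(x$stages),
    n_initial = x$stages$n_survivors[1],
    n_final = x$stages$n_survivors[nrow(x$stages)],
    top_candidate = if (nrow(x$final_ranked) > 0) x$final_ranked$gene_id[1] else NA_character_,
    rank_by = x$rank_by
  )
}

#' Attrition plot of a funnel report
#' @param object A `funnel_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of survivor counts per stage.
#' @export
autoplot.funnel_report <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_survivors)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_survivors), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "surviving genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
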