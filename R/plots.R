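# ggplot2 views of the main result types.

#' Survivor funnel of a cascade report
#'
#' Bar chart of compounds surviving each filtering stage.
#'
#' @param object A `cascade_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cascade_report
#' @export
autoplot.cascade_report <- function(object, ...) {
  lg <- object$ledger
  lg$stage <- factor(lg$stage, levels = lg$stage)
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "compounds surviving",
                  title = "Screening cascade survivor ledger") +
    ggplot2::theme_minimal()
}

#' Specificity gap versus energy level
#'
#' MA-style view of the screen: each multi-region compound's gap
#' `delta_e = E2 - E1` against its energy level `A = (E1 + E2) / 2`,
#' colored by significance at `alpha`.
#'
#' @param records Output of [specificity_significance()].
#' @param alpha Highlight threshold on q (default 0.05).
#' @return A ggplot.
#' @export
plot_specificity <- function(records, alpha = 0.05) {
  df <- filter(as_tibble(records), !.data$single_cluster)
  df$significant <- !is.na(df$q) & df$q <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$delta_e,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "A = (E1 + E2) / 2 (kcal/mol)",
                  y = expression(Delta * E[r] == E[2] - E[1] ~ "(kcal/mol)"),
                  color = paste0("q <= ", alpha)) +
    ggplot2::theme_minimal()
}

#' Stage expression profile of one gene
#'
#' Boxplots of (log2) expression by stage, faceted by group — the classic
#' stage-profile view used to inspect a stage-associated gene.
#'
#' @param dataset An `expr_dataset`.
#' @param gene Gene id.
#' @return A ggplot.
#' @export
plot_stage_profile <- function(dataset, gene) {
  stopifnot(inherits(dataset, "expr_dataset"))
  df <- tidy(dataset) |> filter(.data$gene_id == gene)
  if (nrow(df) == 0) abort(paste0("unknown gene `", gene, "`"))
  stages <- unique(dataset$meta$stage)
  df$stage <- factor(df$stage, levels = stages)
  ylab <- if (dataset$transform == "log2") "log2 expression" else "expression (RPKM-like)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "lightsteelblue") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(title = gene, x = "stage", y = ylab) +
    ggplot2::theme_minimal()
}
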