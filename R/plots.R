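#' Volcano plot of a differential-test result
#'
#' @param fit A result tibble from [nb_stage_test()],
#'   [two_factor_interaction()] or [diff_mirna()]'s table.
#' @param lfc_cutoff,alpha Cutoffs drawn and used for colouring.
#' @return A ggplot object.
#' @export
plot_volcano <- function(fit, lfc_cutoff = 0.5, alpha = 0.05) {
  d <- fit |>
    dplyr::filter(!is.na(.data$padj)) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$padj < alpha & .data$log2FC > lfc_cutoff ~ "up",
        .data$padj < alpha & .data$log2FC < -lfc_cutoff ~ "down",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2FC, -log10(.data$padj),
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b5651d", down = "#2e6f40", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted P",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of post-transcriptional classification labels
#'
#' @param classification A [classify_pt()] result.
#' @return A ggplot object.
#' @export
plot_pt_summary <- function(classification) {
  counts <- summarize_transition(classification)
  ggplot2::ggplot(counts, ggplot2::aes(.data$label, .data$n)) +
    ggplot2::geom_col(fill = "#4878a8") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Enrichment plot for a target-site Monte-Carlo result
#'
#' Observed targeting score against the null mean (+/- 2 null SD), with
#' miRNAs ordered by empirical p.
#'
#' @param object A [monte_carlo_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirhub_result <- function(object, ...) {
  d <- object |>
    dplyr::arrange(.data$empirical_p) |>
    dplyr::mutate(mirna = factor(.data$mirna, levels = rev(.data$mirna)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$mirna)) +
    ggplot2::geom_linerange(
      ggplot2::aes(xmin = pmax(.data$null_mean - 2 * .data$null_sd, 0),
                   xmax = .data$null_mean + 2 * .data$null_sd),
      colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$null_mean), colour = "grey40",
                        shape = 3) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$observed_score,
                   colour = .data$empirical_p < 0.05), size = 2
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(x = "targeting score", y = NULL,
                  colour = "empirical P < 0.05") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
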