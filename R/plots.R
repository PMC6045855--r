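#' Plot a gene's cleavage pattern in normal versus tumor
#'
#' Grouped bar chart of each cleavage-site cluster's usage frequency in the
#' normal and tumor groups of one cancer type, ordered by genomic
#' coordinate. Significantly shifted sites (at the alpha used for the
#' shifts) are labelled with their direction.
#'
#' @param result An `apa_result`.
#' @param gene Gene name or gene ID.
#' @param cancer_type Cancer type to show.
#' @return A ggplot object.
#' @export
plot_cleavage_pattern <- function(result, gene, cancer_type) {
  stopifnot(inherits(result, "apa_result"))
  gid <- result$genes$gene_id[
    result$genes$gene_name == gene | result$genes$gene_id == gene
  ]
  if (length(gid) != 1) {
    abort(paste0("Gene ", gene, " not found in the result."))
  }
  dat <- result$shifts |>
    filter(.data$gene_id == gid, .data$cancer_type == !!cancer_type) |>
    tidyr::pivot_longer(
      c("freq_n", "freq_t"),
      names_to = "condition", values_to = "freq"
    ) |>
    mutate(condition = ifelse(.data$condition == "freq_n", "normal", "tumor"))
  if (nrow(dat) == 0) {
    abort("No frequency shifts for this gene and cancer type.")
  }
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$cs_label, y = .data$freq, fill = .data$condition)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_text(
      data = dat |> filter(.data$direction != "none", .data$condition == "tumor"),
      mapping = ggplot2::aes(
        x = .data$cs_label,
        y = pmax(.data$freq_n, .data$freq_t) + 0.05,
        label = ifelse(.data$direction == "up", "up", "down")
      ),
      inherit.aes = FALSE
    ) +
    ggplot2::scale_fill_manual(values = c(normal = "#4477AA", tumor = "#CC6677")) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(
      x = "cleavage-site cluster (by genomic coordinate)",
      y = "usage frequency (s/g)",
      title = paste0(gene, " in ", cancer_type)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.apa_result <- function(object, ...) {
  if (nrow(object$events) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no APA events detected") +
        ggplot2::theme_void()
    )
  }
  dat <- object$events |>
    count(.data$cancer_type, .data$trend)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$cancer_type, y = .data$n, fill = .data$trend)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      shortening = "#CC6677", lengthening = "#4477AA", complex = "#AAAAAA"
    )) +
    ggplot2::labs(
      x = "cancer type", y = "APA events",
      title = "Tumor-specific APA events by 3' UTR trend"
    ) +
    ggplot2::theme_minimal()
}
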