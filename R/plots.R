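#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity-of-response result
#'
#' Bar chart of the percentage of effectors reversed, per motif, with the
#' overall bar highlighted.
#'
#' @param object An `intensity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$motif <- factor(df$motif, levels = unique(df$motif))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$motif, y = .data$percent,
    fill = .data$motif == "overall"
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#a6bddb")) +
    ggplot2::labs(
      x = NULL, y = "% effectors reversed",
      title = "Intensity of response"
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the accuracy distribution of a model ensemble
#'
#' @param object A `model_ensemble`.
#' @param ... Unused.
#' @return A ggplot histogram of per-solution accuracies.
#' @export
autoplot.model_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "#2c7fb8", colour = "white") +
    ggplot2::geom_vline(
      xintercept = mean(df$accuracy),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "solution accuracy", y = "count",
      title = sprintf(
        "Ensemble of %d solutions (mean accuracy %.2f)",
        nrow(df), mean(df$accuracy)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-target contributions as a drug-ablation heat map
#'
#' @param object A `target_contribution` or `moa_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot tile map of percent reversal by motif.
#' @export
autoplot.target_contribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$motif <- factor(df$motif, levels = unique(df$motif))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$motif, y = .data$target, fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$percent)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#2c7fb8",
      limits = c(0, 100), name = "% reversed"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Single-target contributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.target_contribution
#' @export
autoplot.moa_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$status == "ok", ]
  df$motif <- factor(df$motif, levels = unique(df$motif))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$motif, y = .data$drug, fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$percent)),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#2c7fb8",
      limits = c(0, 100), name = "% reversed"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Drug efficacy benchmark") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `dex_result`.
#' @param ... Unused.
#' @return A ggplot of mean difference against -log10 FDR.
#' @export
autoplot.dex_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$diff <- df$mean_case - df$mean_control
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$diff, y = -log10(.data$fdr), colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#d7301f", `FALSE` = "grey60"),
      name = "FDR < 0.05"
    ) +
    ggplot2::labs(
      x = "mean difference (case - control)",
      y = expression(-log[10] ~ FDR),
      title = "Differential expression"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mechanism-of-action subnetwork
#'
#' Nodes are laid out with a deterministic Sugiyama (layered) layout;
#' green edges are activations, red are inhibitions, edge width encodes
#' ensemble support, and node shape encodes role (target, intermediate,
#' effector).
#'
#' @param object A `moa_subnetwork`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moa_subnetwork <- function(object, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() +
      ggplot2::labs(title = "Empty mechanism subnetwork") +
      ggplot2::theme_void())
  }
  g <- moa_igraph(object)
  xy <- igraph::layout_with_sugiyama(g)$layout
  pos <- tibble::tibble(
    protein = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
  ) |>
    dplyr::left_join(object$nodes, by = "protein")
  seg <- object$edges |>
    dplyr::left_join(dplyr::select(pos, "protein", "x", "y"),
      by = c("from" = "protein")
    ) |>
    dplyr::left_join(dplyr::select(pos, "protein", xend = "x", yend = "y"),
      by = c("to" = "protein")
    ) |>
    dplyr::mutate(interaction = ifelse(.data$sign > 0, "activation", "inhibition"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$interaction, linewidth = .data$support
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), alpha = 0.8
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$role),
      size = 4, fill = "white"
    ) +
    ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$protein),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(activation = "#1a9850", inhibition = "#d73027")
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), limits = c(0, 1)) +
    ggplot2::labs(title = "Mechanism-of-action subnetwork") +
    ggplot2::theme_void()
}

#' Plot bioflag delta changes
#'
#' @param object A `panel_summary` from [summarize_panel()].
#' @param ... Unused.
#' @return A ggplot bar chart of percent delta change per analyte.
#' @export
autoplot.panel_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$analyte, y = .data$delta_percent,
    fill = .data$delta_percent < 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f")) +
    ggplot2::labs(
      x = NULL, y = "delta change of cohort mean (%)",
      title = "Bioflag kinetics under treatment"
    ) +
    ggplot2::theme_minimal()
}
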