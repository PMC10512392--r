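# ggplot2 views of the result objects: checkerboard heatmaps, HIP/HOP
# scatterplots and the combination-by-set enrichment heatmap.

#' @describeIn dose_matrix Checkerboard heatmap of relative growth W.
#' @param object A `dose_matrix`.
#' @export
autoplot.dose_matrix <- function(object, ...) {
  df <- tidy.dose_matrix(object) |>
    mutate(dose_a = factor(.data$dose_a), dose_b = factor(.data$dose_b))
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_b, .data$dose_a,
                                   fill = .data$w)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), name = "W") +
    ggplot2::labs(x = paste(object$drug_b, "dose"),
                  y = paste(object$drug_a, "dose"),
                  title = "Relative growth across the dose matrix") +
    ggplot2::theme_minimal()
}

#' @describeIn epsilon_matrix Heatmap of the Bliss deviation per cell:
#'   yellow = synergy (negative), black = independence, blue = antagonism.
#' @param object An `epsilon_matrix`.
#' @export
autoplot.epsilon_matrix <- function(object, ...) {
  df <- tidy.epsilon_matrix(object) |>
    mutate(dose_a = factor(.data$dose_a), dose_b = factor(.data$dose_b))
  lim <- max(abs(df$eps), 0.05)
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_b, .data$dose_a,
                                   fill = .data$eps)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "yellow", mid = "black",
                                  high = "blue", midpoint = 0,
                                  limits = c(-lim, lim), name = "epsilon") +
    ggplot2::labs(x = paste(object$drug_b, "dose"),
                  y = paste(object$drug_a, "dose"),
                  title = sprintf("%s x %s  (AvgS = %.3f)",
                                  object$drug_a, object$drug_b,
                                  object$avg_s)) +
    ggplot2::theme_minimal()
}

#' HIP/HOP scatterplot of a combination screen
#'
#' Two-panel fitness-defect view of a combination report: heterozygous
#' essential strains (HIP) and homozygous non-essential strains (HOP) side
#' by side, combination-specific strains in red, other significantly
#' sensitive strains in green, the rest in violet.
#'
#' @param report Output of [combination_report()] or
#'   [combination_specific()].
#' @param threshold Significance threshold on the combination Z
#'   (default 2).
#' @return A ggplot object.
#' @export
plot_hiphop_scatter <- function(report, threshold = 2.0) {
  df <- report |>
    mutate(
      class = dplyr::case_when(
        .data$specific ~ "combination-specific",
        .data$z_combo >= threshold ~ "significant",
        TRUE ~ "not significant"),
      panel = if_else(.data$essentiality == "het-essential",
                      "HIP (essential heterozygotes)",
                      "HOP (non-essential homozygotes)")) |>
    group_by(.data$panel) |>
    mutate(idx = rank(.data$strain, ties.method = "first")) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$z_combo,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(
      "combination-specific" = "red", "significant" = "green4",
      "not significant" = "violet"), name = NULL) +
    ggplot2::facet_wrap(~panel, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "strain", y = "fitness defect (robust Z)") +
    ggplot2::theme_minimal()
}

#' @describeIn enrichment_matrix Clustered NES heatmap (combinations x
#'   sets); rows/columns follow the average-linkage Pearson ordering, and
#'   the synergy annotation, when present, is appended to the x labels.
#' @param object An `enrichment_matrix`.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  m <- object$matrix
  row_ord <- if (!is.null(object$combinations)) {
    rownames(m)[object$combinations$order]
  } else rownames(m)
  col_ord <- if (!is.null(object$sets)) {
    colnames(m)[object$sets$order]
  } else colnames(m)
  df <- tidy.enrichment_matrix(object) |>
    mutate(combination = factor(.data$combination, levels = row_ord),
           set = factor(.data$set, levels = col_ord))
  if (!is.null(object$annotation)) {
    df <- left_join(df, object$annotation, by = "combination") |>
      mutate(combination = factor(
        paste0(.data$combination,
               if_else(.data$synergistic, " *", "")),
        levels = paste0(row_ord,
                        if_else(object$annotation$synergistic[
                          match(row_ord, object$annotation$combination)],
                          " *", ""))))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$combination, .data$set,
                                   fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey85",
                                  high = "red", midpoint = 0,
                                  name = "NES") +
    ggplot2::labs(x = "combination (* = synergistic)", y = "gene set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
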