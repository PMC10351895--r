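# ggplot2 displays for the main result types.

#' Heatmap of a 5'SS-anchored coverage matrix
#'
#' Rows are splice sites (in their current order, e.g. after
#' [order_rows()]), columns are offsets relative to the donor.
#'
#' @param object A `coverage_matrix`.
#' @param trans Transformation for the fill scale (default `"sqrt"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_matrix <- function(object, trans = "sqrt", ...) {
  df <- as_tibble(unclass(object), .name_repair = "minimal")
  names(df) <- colnames(object)
  df$site <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -"site",
    names_to = "offset", values_to = "cpm"
  ) |>
    mutate(offset = as.integer(.data$offset))
  ggplot2::ggplot(long, ggplot2::aes(
    .data$offset, .data$site,
    fill = .data$cpm
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "offset from 5'SS (nt)", y = "splice sites", fill = "cpm"
    ) +
    ggplot2::theme_minimal()
}

#' Metaprofile line plot with the peak offset marked
#'
#' @param object An `ss_metaplot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ss_metaplot <- function(object, ...) {
  peak <- attr(object, "peak_offset", exact = TRUE)
  ggplot2::ggplot(
    tidy(object), ggplot2::aes(.data$offset, .data$signal)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = peak, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = "offset from 5'SS (nt)", y = "mean cpm",
      title = sprintf("peak at %+d nt", peak)
    ) +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential analysis
#'
#' @param object An `nb_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_de <- function(object, ...) {
  df <- object$results |> filter(!.data$excluded)
  df$call <- ifelse(df$up, "up", ifelse(df$down, "down", "ns"))
  ggplot2::ggplot(df, ggplot2::aes(
    .data$base_mean, .data$log2fc,
    colour = .data$call
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60")
    ) +
    ggplot2::labs(
      x = "mean normalized count", y = sprintf(
        "log2FC (%s vs %s)", object$contrast, object$reference
      )
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of per-donor spliced/unspliced log2 ratios
#'
#' @param junction_table A [junction_ratio_table()] result.
#' @return A ggplot of the kept donors' log2(spliced/unspliced).
#' @export
plot_junction_ratios <- function(junction_table) {
  df <- junction_table |> filter(.data$kept, !is.na(.data$log2fc))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "log2(spliced / unspliced)", y = "5' splice sites"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of snRNA read shares
#'
#' @param profile A [snrna_profile()] result.
#' @return A ggplot of per-snRNA shares of ms-snRNA reads.
#' @export
plot_snrna_shares <- function(profile) {
  ggplot2::ggplot(profile$counts, ggplot2::aes(
    .data$snrna, .data$share
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of ms-snRNA reads") +
    ggplot2::theme_minimal()
}
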