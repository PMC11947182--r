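# ggplot2 views of the main result types.

#' Ion image of one feature
#'
#' @param fm A [feature_matrix()].
#' @param mz Feature to display (nearest bin center is used).
#' @return A ggplot raster of per-pixel intensity.
#' @export
plot_ion_image <- function(fm, mz) {
  j <- which.min(abs(fm$mz - mz))
  df <- fm$pixels
  df$intensity <- fm$values[, j]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s  m/z %.4f", fm$sample_id, fm$mz[j]),
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Cluster raster of a segmentation
#'
#' @param object An `msi_segmentation`.
#' @param ... Unused.
#' @return A ggplot raster of cluster labels.
#' @method autoplot msi_segmentation
#' @export
autoplot.msi_segmentation <- function(object, ...) {
  df <- tidy.msi_segmentation(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$sample_id, fill = "cluster") +
    ggplot2::theme_minimal()
}

#' TIC drift scatterplot
#'
#' Per-pixel total ion current against acquisition index, the diagnostic view
#' of within-run signal drift.
#'
#' @param fm A [feature_matrix()] (or list of them).
#' @return A ggplot.
#' @export
plot_tic_drift <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm <- list(fm)
  df <- dplyr::bind_rows(purrr::map(fm, tic_series))
  df <- df[df$tic > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$acquisition_index, .data$tic)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~sample_id, scales = "free") +
    ggplot2::labs(x = "acquisition index", y = "TIC") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential table
#'
#' @param object An `msi_differential` (run through [classify_volcano()] or
#'   classified on the fly with the default cuts).
#' @param p_col Which p value to plot, default `"tukey_adjusted_p"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msi_differential
#' @export
autoplot.msi_differential <- function(object, p_col = "tukey_adjusted_p",
                                      ...) {
  df <- tibble::as_tibble(object)
  if (!"hit" %in% names(df)) df <- classify_volcano(df, p_col = p_col)
  df$status <- dplyr::case_when(
    df$hit ~ "significant, high effect",
    df$significant ~ "significant",
    TRUE ~ "ns")
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc,
                                   -log10(.data[[p_col]]),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-0.5, 0.5), linetype = 3) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 3) +
    ggplot2::facet_grid(region ~ contrast) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Dot size encodes set size, shade the FDR q value, rows the lipid class and
#' saturation split, split by direction of change.
#'
#' @param object An `msi_enrichment`.
#' @param q_cut Only sets with `fdr_q` below this are drawn; default 1 (all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msi_enrichment
#' @export
autoplot.msi_enrichment <- function(object, q_cut = 1, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$fdr_q <= q_cut, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$set_id,
                                   size = .data$n_set,
                                   colour = .data$fdr_q)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::facet_grid(region ~ contrast) +
    ggplot2::labs(x = NULL, y = NULL, size = "set size", colour = "FDR q") +
    ggplot2::theme_minimal()
}
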