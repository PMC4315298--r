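# ggplot2 displays for the main result types. These are deliberately
# plain: heat map of a matrix region, track plots for the strip index
# and DI, and state-profile heat maps.

#' Heat map of a contact-matrix region
#'
#' @param mat A `contact_matrix`.
#' @param from_bin,to_bin 0-based bin range to display (defaults to the
#'   whole chromosome).
#' @param trim Winsorize values at this quantile of the displayed cells
#'   (default 0.98) so a few extreme cells do not flatten the palette.
#' @return A ggplot object.
#' @export
plot_contact_map <- function(mat, from_bin = 0L,
                             to_bin = nrow(mat$values) - 1L,
                             trim = 0.98) {
  tb <- as_tibble(mat, upper_only = FALSE, drop_zero = FALSE) |>
    filter(.data$bin1 >= from_bin, .data$bin1 <= to_bin,
           .data$bin2 >= from_bin, .data$bin2 <= to_bin)
  cap <- quantile(abs(tb$value), trim, na.rm = TRUE)
  tb$value <- pmax(pmin(tb$value, cap), -cap)
  ggplot2::ggplot(tb, ggplot2::aes(.data$bin1, .data$bin2,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin", fill = mat$kind,
                  title = mat$chrom) +
    ggplot2::theme_minimal()
}

#' Strip-index track with calling cutoffs
#'
#' @param track Index tibble from [strip_index()].
#' @param cutoff Cutoff drawn as dashed guides (default 45).
#' @return A ggplot object.
#' @export
plot_strip_index <- function(track, cutoff = 45) {
  ggplot2::ggplot(filter(track, .data$defined),
                  ggplot2::aes(.data$bin, .data$index)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "bin", y = "strip index") +
    ggplot2::theme_minimal()
}

#' Directionality-index track coloured by HMM state
#'
#' @param states State tibble from [fit_hmm()].
#' @return A ggplot object.
#' @export
plot_di_track <- function(states) {
  df <- filter(states, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$di,
                                   fill = .data$state)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(U = "seagreen", D = "darkorange",
                                          N = "grey60")) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "bin", y = "directionality index") +
    ggplot2::theme_minimal()
}

#' Heat map of chromatin-state centroids
#'
#' @param centroids k x marks centroid matrix from [classify_states()],
#'   optionally renamed with [name_states()].
#' @return A ggplot object.
#' @export
plot_state_profiles <- function(centroids) {
  df <- as_tibble(centroids, rownames = "state") |>
    tidyr::pivot_longer(-"state", names_to = "mark", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(.data$mark, .data$state,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
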