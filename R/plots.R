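# ggplot2 visualisations for the main result types.

#' Plot rarefaction curves
#'
#' Four-panel view of a rarefaction: core genes, pan genes and new genes
#' against the number of genomes added, plus the new-gene curve on log10
#' axes (whose slope gives the Heaps openness exponent). Per-permutation
#' counts are drawn as translucent points under the medians.
#'
#' @param object A `rarefaction` object.
#' @param max_points Cap on per-permutation points drawn per panel
#'   (default 5000), to keep plots light.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @method autoplot rarefaction
#' @export
autoplot.rarefaction <- function(object, max_points = 5000, ...) {
  long_counts <- object$counts |>
    tidyr::pivot_longer(c("core", "pan", "new"), names_to = "curve",
                        values_to = "count")
  if (nrow(long_counts) > max_points) {
    long_counts <- long_counts[sample.int(nrow(long_counts), max_points), ]
  }
  long_med <- tidy(object)
  log_med <- long_med |>
    dplyr::filter(.data$curve == "new", .data$k >= 2, .data$median > 0) |>
    dplyr::mutate(curve = "log10(new)", k = .data$k,
                  median = .data$median)
  ggplot2::ggplot(long_med, ggplot2::aes(x = .data$k, y = .data$median)) +
    ggplot2::geom_point(data = long_counts,
                        ggplot2::aes(y = .data$count),
                        colour = "red", alpha = 0.15, size = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "genomes added", y = "gene families",
                  title = sprintf("Rarefaction over %d permutations",
                                  object$n_permutations)) +
    ggplot2::theme_minimal()
}

#' Plot a Heaps-law fit
#'
#' The fitted new-gene medians on log10-log10 axes with the regression
#' line; the slope's negation is the openness exponent alpha.
#'
#' @param object A `heaps_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heaps_fit
#' @export
autoplot.heaps_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = log10(.data$k),
                                            y = log10(.data$new))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = log10(object$kappa),
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "log10 genomes added", y = "log10 new gene families",
      title = sprintf("Heaps fit: alpha = %.2f (%s pan-genome)",
                      object$alpha, if (object$open) "open" else "closed")
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise metric matrix
#'
#' Strains ordered by complete-linkage clustering of the matrix rows
#' (see [cluster_metric_matrix()]).
#'
#' @param matrix Symmetric strain-by-strain metric matrix (e.g. from
#'   [metric_matrix()]).
#' @param name Label for the fill scale (defaults to the matrix's
#'   `metric` attribute or "value").
#' @return A ggplot object.
#' @export
plot_metric_heatmap <- function(matrix, name = NULL) {
  name <- name %||% attr(matrix, "metric") %||% "value"
  ord <- cluster_metric_matrix(matrix)$leaf_order
  df <- tibble::as_tibble(as.table(matrix), .name_repair = ~c("row", "col", "value")) |>
    dplyr::mutate(row = factor(.data$row, levels = ord),
                  col = factor(.data$col, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "red", high = "white", name = name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Presence/absence heatmap of a reference cluster across strains
#'
#' Mirrors the black/grey gene-presence figures used for EPS clusters:
#' reference genes as rows (in synteny order), strains as columns.
#'
#' @param calls Named list of `cluster_presence` objects, one per strain.
#' @return A ggplot object.
#' @export
plot_cluster_presence <- function(calls) {
  df <- purrr::imap(calls, function(x, s) {
    dplyr::mutate(x$per_gene, strain = s)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(reference_gene = factor(
      .data$reference_gene, levels = rev(unique(.data$reference_gene))))
  ggplot2::ggplot(df, ggplot2::aes(.data$strain, .data$reference_gene,
                                   fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "grey80"),
                               name = "present") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
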