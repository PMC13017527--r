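# ggplot2 displays for the main result types

#' @export
autoplot.pi_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$h_n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$h, linetype = "dashed") +
    ggplot2::labs(x = "window size n", y = expression(h[n] ~ "(bits/symbol)"),
                  title = sprintf("Convergence to the entropy rate (E = %.3f bits)",
                                  object$E)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.baseline_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$E)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = object$E_attested, linewidth = 1) +
    ggplot2::facet_wrap(~baseline, scales = "free") +
    ggplot2::labs(x = "predictive information (bits)", y = "baseline density",
                  title = "Attested forms (line) vs counterfactual baselines") +
    ggplot2::theme_minimal()
}

#' Ranked-code scatter for an enumeration experiment
#'
#' Codes ordered by predictive information, coloured by a structural score
#' column (`systematicity`, `contiguous` or `well_nested`).
#'
#' @param data A table from [run_bijection_enumeration()],
#'   [run_locality_permutations()] or [run_hierarchy_permutations()].
#' @param colour Name of the score column to colour by (default: guessed).
#' @return A ggplot.
#' @export
plot_ranked_codes <- function(data, colour = NULL) {
  colour <- colour %||%
    intersect(c("systematicity", "contiguous", "well_nested"), names(data))[1]
  d <- dplyr::mutate(dplyr::arrange(data, .data$E), rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$E,
                                  colour = factor(.data[[colour]]))) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "codes ordered by E", y = "predictive information (bits)",
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise mutual-information matrix
#'
#' @param mat Matrix from [pairwise_feature_mi()] or a component of
#'   [cross_word_feature_mi()].
#' @return A ggplot.
#' @export
plot_mi_matrix <- function(mat) {
  d <- tibble::as_tibble(as.table(mat), .name_repair = ~c("row", "col", "mi"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "bits") +
    ggplot2::theme_minimal()
}
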