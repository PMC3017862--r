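#' Plot a within-helix separation histogram
#'
#' Bar chart of the percentage of within-helix correlated pairs per sequence
#' separation, the display in which one-turn periodicity (a peak at separation
#' 4 and a dip at 2) is visible.
#'
#' @param object A `separation_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot separation_histogram
#' @export
autoplot.separation_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_result(object)),
                  ggplot2::aes(x = .data$separation, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "sequence separation |i - j|",
                  y = "% of within-helix correlated pairs") +
    ggplot2::theme_minimal()
}

#' Plot a randomization test: null distribution and observed statistic
#'
#' @param object A `randomization_test` (including `periodicity_test`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot randomization_test
#' @export
autoplot.randomization_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "statistic under the null",
                  subtitle = sprintf("%s: observed = %.3g, p = %.3g",
                                     object$method, object$observed,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot distance enrichment: observed versus background fractions
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(unclass_result(object)) |>
    tidyr::pivot_longer(c("observed_fraction", "background_fraction"),
                        names_to = "which", values_to = "fraction") |>
    dplyr::mutate(which = sub("_fraction", "", .data$which),
                  threshold = factor(.data$threshold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$fraction,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(background = "grey70",
                                          observed = "grey25"),
                               name = NULL) +
    ggplot2::labs(x = "distance threshold (Å)",
                  y = "fraction of residue pairs within threshold") +
    ggplot2::theme_minimal()
}

#' Plot a helix/domain contact table as a tile map
#'
#' @param object A `contact_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_table
#' @export
autoplot.contact_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_result(object)),
                  ggplot2::aes(x = .data$bin_1, y = .data$bin_2,
                               fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "black") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
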