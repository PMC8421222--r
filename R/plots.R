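#' Plot the observed/expected edits profile
#'
#' Ratio of observed to expected edits by distance from the primer 3' end,
#' the standard readout of editing extent (a ratio near 1 marks complete
#' editing).
#'
#' @param object An `obs_exp` table from [observed_over_expected()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.obs_exp <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_from_3prime, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = df$distance_from_3prime) +
    ggplot2::labs(x = "Distance from primer 3' end (bases)",
                  y = "Observed / expected edits") +
    ggplot2::theme_minimal()
}

#' Plot per-position base composition of the primer region
#'
#' @param object An `edit_matrix` from [profile_primer_region()].
#' @param ... Unused.
#' @return A ggplot of per-position base proportions.
#' @export
autoplot.edit_matrix <- function(object, ...) {
  df <- tidy(object) |>
    group_by(.data$position) |>
    mutate(prop = .data$count / sum(.data$count)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$prop,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Primer position (5' -> 3')", y = "Base proportion",
                  fill = "Base") +
    ggplot2::theme_minimal()
}

#' Plot variant-primer amplification penalties
#'
#' Per-position aggregate fold-of-expected abundance of variant primers; a
#' fold below 1 marks an amplification penalty of the unedited mismatch.
#'
#' @param object A `penalty_table` from [penalty_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.penalty_table <- function(object, ...) {
  df <- object$positions
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$fold)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_col() +
    ggplot2::scale_x_reverse(breaks = df$position) +
    ggplot2::labs(x = "Distance from primer 3' end (bases)",
                  y = "Fold of expected abundance") +
    ggplot2::theme_minimal()
}
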