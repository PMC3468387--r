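#' Plot a misincorporation profile
#'
#' Dual-panel (5' and 3') per-position rate curves in the familiar
#' damage-plot style: the deamination classes C->T and G->A highlighted,
#' indel and soft-clip rates drawn alongside, remaining substitution
#' classes pooled in grey.
#'
#' @param object A `damage_profile` from [accumulate_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot damage_profile
#' @export
autoplot.damage_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$group <- dplyr::case_when(
    df$class == "C>T" ~ "C>T",
    df$class == "G>A" ~ "G>A",
    df$class == "insertion" ~ "Insertions",
    df$class == "deletion" ~ "Deletions",
    df$class == "softclip" ~ "Clipped bases",
    TRUE ~ "Other"
  )
  plot_df <- df |>
    dplyr::group_by(.data$end, .data$position, .data$group) |>
    dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(end = factor(.data$end, levels = c("5p", "3p"),
                               labels = c("5' end", "3' end")))
  cols <- c("C>T" = "red", "G>A" = "blue", "Insertions" = "hotpink",
            "Deletions" = "darkgreen", "Clipped bases" = "orange",
            "Other" = "grey50")
  ggplot2::ggplot(plot_df, ggplot2::aes(x = .data$position, y = .data$rate,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~end) +
    ggplot2::scale_colour_manual(values = cols, name = NULL) +
    ggplot2::labs(x = "Position from read end (nt)", y = "Rate") +
    ggplot2::theme_minimal()
}

#' Plot a divergence curve
#'
#' Divergence (black) and GC->AT misincorporation rate (red) as a
#' function of the base-quality threshold.
#'
#' @param object A `divergence_curve` from [divergence_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot divergence_curve
#' @export
autoplot.divergence_curve <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("divergence", "gc_to_at_rate"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bq_threshold, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(divergence = "black", gc_to_at_rate = "red"),
      labels = c(divergence = "Divergence", gc_to_at_rate = "GC>AT rate"),
      name = NULL) +
    ggplot2::labs(x = "Base-quality threshold", y = "Rate") +
    ggplot2::theme_minimal()
}

#' Plot the read-length-dependent edit-distance thresholds
#'
#' Step curve of maximum tolerated edit distance against read length for
#' one or more missing-alignment fractions.
#'
#' @param missing_fractions Numeric vector of `-n` values.
#' @param per_base_error Assumed per-base error rate.
#' @param min_len,max_len Length range.
#' @return A ggplot object.
#' @export
plot_edit_distance_model <- function(missing_fractions = c(0.02, 0.03, 0.04),
                                     per_base_error = 0.02,
                                     min_len = 17, max_len = 120) {
  df <- dplyr::bind_rows(lapply(missing_fractions, function(f) {
    tibble(missing_fraction = f, length = min_len:max_len,
           max_diff = max_edit_distance(min_len:max_len, per_base_error, f))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$max_diff,
                                   colour = factor(.data$missing_fraction))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Read length (nt)", y = "Maximum edit distance",
                  colour = "-n") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
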