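#' Plot a reliability report
#'
#' Dot plot of the intra- and interobserver ICC per parameter, colored by
#' classification band, with the SEM shown alongside as text. The dashed
#' lines mark the poor/moderate/good/excellent boundaries (0.50, 0.75,
#' 0.90).
#'
#' @param object A `scapula_reliability` table (from
#'   [reliability_table()] or `run$reliability`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scapula_reliability
#' @export
autoplot.scapula_reliability <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("parameter", "unit", "icc_intra", "icc_inter",
                  "sem_intra", "sem_inter") |>
    tidyr::pivot_longer(
      cols = c("icc_intra", "icc_inter", "sem_intra", "sem_inter"),
      names_to = c(".value", "scope"), names_sep = "_"
    ) |>
    dplyr::mutate(
      scope = factor(.data$scope, levels = c("intra", "inter"),
                     labels = c("intraobserver", "interobserver")),
      class = classify_icc(.data$icc),
      parameter = factor(.data$parameter, levels = PARAMETER_LEVELS)
    )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$parameter, y = .data$icc,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = c(0.50, 0.75, 0.90),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_point(size = 2.5, na.rm = TRUE) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f", .data$sem)),
      vjust = -1, size = 2.8, colour = "grey30", na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope), ncol = 1L) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(
      x = NULL, y = "intraclass correlation",
      colour = "ICC class",
      title = "Landmark and orientation reliability",
      subtitle = "point label: standard error of measurement (mm or deg)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot orientation dispersion around each scapula's mean
#'
#' Distribution of the per-measure Euler angle differences to the scapula
#' mean, one panel layer per angle: violin (distribution), boxplot
#' (quartiles) and the individual measures as jittered points.
#'
#' @param orientations An orientation table from [scapular_orientation()]
#'   (or `run$orientations`).
#' @return A ggplot object.
#' @export
plot_orientation_deviation <- function(orientations) {
  long <- orientations |>
    tidyr::pivot_longer(cols = c("e1_deg", "e2_deg", "e3_deg"),
                        names_to = "angle", values_to = "value") |>
    dplyr::group_by(.data$scapula_id, .data$angle) |>
    dplyr::mutate(deviation = .data$value - mean(.data$value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(angle = factor(
      .data$angle, levels = c("e1_deg", "e2_deg", "e3_deg"),
      labels = c("e1 (retraction/protraction)",
                 "e2 (lateral/medial rotation)",
                 "e3 (internal/external rotation)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$angle, y = .data$deviation)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, width = 0.9) +
    ggplot2::geom_boxplot(width = 0.15, outlier.colour = "grey40",
                          outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "difference to scapula mean (deg)",
                  title = "Scapular orientation dispersion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 15, hjust = 1))
}
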