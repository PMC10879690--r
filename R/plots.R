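#' Plot gel lane profiles
#'
#' @param gel Long gel tibble ([simulate_gel_lanes()]) or a single lane
#'   (`distance_mm`, `intensity`).
#' @return A ggplot.
#' @export
plot_lanes <- function(gel) {
  gel <- as_tibble(gel)
  if (!"lane" %in% names(gel)) gel$lane <- "lane"
  ggplot2::ggplot(gel, ggplot2::aes(.data$distance_mm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~lane, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Migration distance (mm)",
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot copy-number trajectories
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @return A ggplot; one line per replicate (faceted by homolog for
#'   diploids).
#' @export
plot_trajectories <- function(traj) {
  traj <- as_tibble(traj)
  p <- ggplot2::ggplot(traj,
    ggplot2::aes(.data$generation, .data$copies,
                 group = interaction(.data$replicate, .data$homolog),
                 colour = factor(.data$replicate))) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "Generation", y = "rDNA copies") +
    ggplot2::theme_minimal()
  if (length(unique(traj$homolog)) > 1) {
    p <- p + ggplot2::facet_wrap(~homolog, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a variant-frequency spectrum
#'
#' @param spectrum Tibble from [frequencies()].
#' @return A ggplot of non-reference frequency along the unit.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(dplyr::filter(as_tibble(spectrum), !is.na(.data$freq)),
                  ggplot2::aes(.data$pos, .data$freq)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "Unit position (bp)", y = "Non-reference frequency") +
    ggplot2::theme_minimal()
}

#' Plot a DNA-content histogram
#'
#' @param hist Tibble from [simulate_facs()].
#' @return A ggplot.
#' @export
plot_facs <- function(hist) {
  ggplot2::ggplot(as_tibble(hist),
                  ggplot2::aes(.data$fluorescence, .data$count)) +
    ggplot2::geom_col(width = diff(hist$fluorescence)[1]) +
    ggplot2::labs(x = "DNA content (a.u.)", y = "Cells") +
    ggplot2::theme_minimal()
}
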