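#' Biaxial scatter of two markers colored by population
#'
#' The standard gating view: cells plotted on two marker channels, colored
#' by their assigned population.
#'
#' @param sample a [flow_sample].
#' @param labels integer population labels, one per cell.
#' @param marker_x,marker_y distinct marker names present in the sample.
#' @return A ggplot object.
#' @export
plot_biaxial <- function(sample, labels, marker_x, marker_y) {
  stopifnot(inherits(sample, "flow_sample"))
  if (identical(marker_x, marker_y)) {
    stop("`marker_x` and `marker_y` must be different markers")
  }
  for (mk in c(marker_x, marker_y)) {
    if (!mk %in% sample$marker_names) {
      stop(sprintf("unknown marker '%s' (sample has: %s)", mk,
                   paste(sample$marker_names, collapse = ", ")))
    }
  }
  if (length(labels) != n_cells(sample)) stop("one label per cell required")
  df <- data.frame(
    x = sample$values[, marker_x],
    y = sample$values[, marker_y],
    population = factor(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$population)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = marker_x, y = marker_y, colour = "population",
                  title = sample$sample_id) +
    ggplot2::theme_minimal()
}

#' All-pairs biaxial plots
#'
#' @inheritParams plot_biaxial
#' @return A named list of ggplot objects, one per unordered marker pair
#'   (`M * (M - 1) / 2` plots).
#' @export
plot_biaxial_all <- function(sample, labels) {
  nm <- sample$marker_names
  out <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) {
        out[[paste(nm[i], nm[j], sep = "_vs_")]] <-
          plot_biaxial(sample, labels, nm[i], nm[j])
      }
    }
  }
  out
}

#' Density-peak decision plot (delta versus rho)
#'
#' Dominant peaks sit at high density and high distance; anomalous
#' subjects at low density and high distance. Flagged subjects are
#' highlighted.
#'
#' @param report an `anomaly_report` from [run_anomaly_pipeline()].
#' @return A ggplot object.
#' @export
plot_decision <- function(report) {
  stopifnot(inherits(report, "anomaly_report"))
  df <- data.frame(rho = report$rho, delta = report$delta,
                   subject = report$subject_ids,
                   flagged = seq_along(report$rho) %in% report$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$delta,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = expression(rho), y = expression(delta),
                  colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Sorted delta/rho ratio plot
#'
#' Subjects ordered by their `delta/rho` ratio; anomalous subjects emerge
#' at the extreme right.
#'
#' @param report an `anomaly_report` from [run_anomaly_pipeline()].
#' @return A ggplot object.
#' @export
plot_ratios <- function(report) {
  stopifnot(inherits(report, "anomaly_report"))
  ord <- order(report$ratios)
  df <- data.frame(rank = seq_along(ord), ratio = report$ratios[ord],
                   flagged = ord %in% report$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "subject (sorted)", y = expression(delta / rho),
                  colour = "flagged") +
    ggplot2::theme_minimal()
}
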