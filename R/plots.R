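#' Plot meta-cluster group composition
#'
#' Stacked bar chart of each meta-cluster's group composition, clusters
#' ordered by size.
#'
#' @param fit An `ev_som` object.
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(fit) {
  prof <- cluster_profiles(fit)
  ggplot2::ggplot(prof,
                  ggplot2::aes(x = factor(.data$metacluster),
                               y = .data$group_frac, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Meta-cluster", y = "Fraction of vesicles",
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a meta-cluster's protein detection frequencies
#'
#' @param fit An `ev_som` object.
#' @param metacluster Meta-cluster id.
#' @param n Number of top proteins shown.
#' @return A ggplot object.
#' @export
plot_detection_frequency <- function(fit, metacluster, n = 15L) {
  df <- detection_frequencies(fit)
  df <- df[df$metacluster == metacluster, ][seq_len(n), ]
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(.data$protein, .data$freq),
                               y = .data$freq)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Detection frequency",
                  title = paste("Meta-cluster", metacluster)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential table
#'
#' @param de Result of [differential_expression()] or
#'   [differential_combinations()].
#' @param q_max Significance threshold highlighted.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, q_max = 0.05) {
  d <- de[!is.na(de$p_value), ]
  d$log2fc <- log2((d$mean_case + 0.5) / (d$mean_control + 0.5))
  d$significant <- !is.na(d$q_value) & d$q_value < q_max
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p", colour = paste("q <", q_max)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param km Step-function tibble from [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- km |>
    dplyr::distinct(.data$stratum) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot2::ggplot(dplyr::bind_rows(start, km[, c("stratum", "time", "survival")]),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
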