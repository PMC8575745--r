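# ggplot2 displays for each result type. Figures are derived views of the
# tidy outputs; no analysis step depends on them.

#' Plot a curve set
#'
#' Death distributions over age, one line per (country, year, sex) unit,
#' coloured by year.
#'
#' @param object A [curve_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curve_set <- function(object, ...) {
  df <- as_tibble.curve_set(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$dx,
                                   group = interaction(.data$country,
                                                       .data$year,
                                                       .data$sex),
                                   colour = .data$year)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "age", y = "deaths (per 100,000 births)") +
    ggplot2::theme_minimal()
}

#' Plot smoothed curves with their raw observations
#'
#' @param object A `smoothed_curves` object.
#' @param ... Unused.
#' @return A ggplot of the fitted curves.
#' @export
autoplot.smoothed_curves <- function(object, ...) {
  n <- nrow(object$coef)
  df <- tibble::tibble(
    unit = rep(seq_len(n), each = length(object$ages)),
    age = rep(object$ages, n),
    dx = as.vector(t(object$fitted))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$dx,
                                   group = .data$unit)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "age", y = "smoothed deaths",
                  title = "Penalized B-spline fits") +
    ggplot2::theme_minimal()
}

#' Harmonic-variation panel for an FPCA
#'
#' For each retained component, the mean curve together with
#' mean +/- 2 sd(component) * eigenfunction: the (+) curve shows what a high
#' positive score does to the death distribution, the (-) curve the opposite.
#'
#' @param object A [fit_fpca()] result.
#' @param components Which harmonics to show (default: all retained).
#' @param multiple Multiple of each component's standard deviation.
#' @param ... Unused.
#' @return A ggplot, facetted by component.
#' @export
autoplot.mortality_fpca <- function(object, components = seq_len(object$q),
                                    multiple = 2, ...) {
  df <- dplyr::bind_rows(lapply(components, function(l) {
    dplyr::mutate(harmonic_variation(object, l, multiple = multiple),
                  component = paste0("PC", l, " (",
                                     sprintf("%.1f%%",
                                             100 * object$varprop[l]), ")"))
  }))
  long <- tidyr::pivot_longer(df, c("mean", "plus", "minus"),
                              names_to = "curve", values_to = "dx")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$dx,
                                     linetype = .data$curve,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_linetype_manual(values = c(mean = "solid", plus = "dashed",
                                              minus = "dotted")) +
    ggplot2::labs(x = "age", y = "deaths",
                  title = "Harmonic variation around the mean curve") +
    ggplot2::theme_minimal()
}

#' Country-by-year cluster membership heatmap
#'
#' @param assignment A `cluster_assignment` (or tidy data frame with
#'   `country`, `year`, `cluster`).
#' @param sex Optional sex filter.
#' @return A ggplot tile map: countries as rows, years as columns, fill =
#'   cluster.
#' @export
plot_membership <- function(assignment, sex = NULL) {
  mm <- membership_matrix(assignment, sex = sex)
  df <- dplyr::mutate(mm$tidy, cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$country,
                                   fill = .data$cluster)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "year", y = NULL, fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Score trajectories in the first principal subspace
#'
#' PC1-PC2 score paths over time for selected countries, optionally coloured
#' by cluster membership. The horizontal axis is the shift/compression
#' component: trajectories drifting from positive to negative scores track
#' the postponement and concentration of adult deaths.
#'
#' @param fpca A [fit_fpca()] result (q >= 2).
#' @param countries Countries to draw (default: all).
#' @param assignment Optional `cluster_assignment` used to colour points.
#' @return A ggplot.
#' @export
plot_score_trajectories <- function(fpca, countries = NULL,
                                    assignment = NULL) {
  stopifnot(inherits(fpca, "mortality_fpca"), fpca$q >= 2)
  df <- tidy.mortality_fpca(fpca)
  if (!is.null(assignment)) {
    df$cluster <- factor(assignment$labels)
  }
  if (!is.null(countries)) {
    df <- dplyr::filter(df, .data$country %in% countries)
  }
  df <- dplyr::arrange(df, .data$country, .data$year)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$score_1, .data$score_2,
                                         group = .data$country)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "PC1 score (shift/compression)", y = "PC2 score") +
    ggplot2::theme_minimal()
  if (!is.null(assignment)) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster))
  } else {
    gg <- gg + ggplot2::geom_point()
  }
  gg
}

#' Cluster mean curves
#'
#' @param smoothed A `smoothed_curves` object.
#' @param assignment A `cluster_assignment` over the same curves.
#' @return A ggplot of one mean curve per cluster.
#' @export
plot_cluster_means <- function(smoothed, assignment) {
  stopifnot(inherits(smoothed, "smoothed_curves"),
            inherits(assignment, "cluster_assignment"))
  B <- eval_basis(smoothed$basis, smoothed$ages)
  df <- dplyr::bind_rows(lapply(seq_len(assignment$K), function(k) {
    co <- colMeans(smoothed$coef[assignment$labels == k, , drop = FALSE])
    tibble::tibble(cluster = factor(k), age = smoothed$ages,
                   dx = drop(B %*% co))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$dx,
                                   colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "age", y = "deaths", colour = "cluster",
                  title = "Cluster mean death distributions") +
    ggplot2::theme_minimal()
}
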