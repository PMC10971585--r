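#' Plot a biomorph drawing
#'
#' @param object A `biomorph_drawing`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biomorph_drawing <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a phenotype grid
#'
#' @param object A `phenotype_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenotype_grid <- function(object, ...) {
  m <- unclass(object)
  df <- data.frame(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    on = as.vector(m) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$on)) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Rank curve of a GP map (phenotype bias)
#'
#' Neutral set size against rank on log-log axes; a straight line of slope
#' -1 is Zipf's law.
#'
#' @param object A `gp_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gp_map <- function(object, ...) {
  rc <- rank_curve(object)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$rank, y = .data$n_genotypes)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank (phenotypes with ≥ neutral set size)",
                  y = "neutral set size") +
    ggplot2::theme_minimal()
}

#' Robustness against frequency, with the uncorrelated null model
#'
#' @param stats Output of [gp_phenotype_stats()].
#' @return A ggplot (log x; the dashed line is the null model rho = f).
#' @export
plot_robustness_frequency <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$f, y = .data$robustness)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "phenotype frequency f", y = "phenotype robustness") +
    ggplot2::theme_minimal()
}

#' Evolvability-robustness relationships
#'
#' Phenotype-level: positive correlation; genotype-level ([gp_genotype_stats()]
#' input): the trade-off.
#'
#' @param stats Output of [gp_phenotype_stats()] or [gp_genotype_stats()].
#' @return A ggplot.
#' @export
plot_evolvability_robustness <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$robustness,
                                      y = .data$evolvability)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "robustness", y = "evolvability") +
    ggplot2::theme_minimal()
}

#' Neutral set size against complexity (simplicity bias)
#'
#' @param table Output of [complexity_frequency_table()].
#' @return A ggplot (log y).
#' @export
plot_complexity_frequency <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$complexity,
                                      y = .data$n_genotypes)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0("complexity (", table$method[1L], ")"),
                  y = "neutral set size") +
    ggplot2::theme_minimal()
}

#' Appearance frequency in a drifting population against f
#'
#' @param object A `flat_scenario`.
#' @param ... Unused.
#' @return A ggplot (log-log; solid line is the one-to-one relation).
#' @export
autoplot.flat_scenario <- function(object, ...) {
  df <- dplyr::filter(object$appearance, .data$occurrences > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$appearance_freq)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "phenotype frequency f",
                  y = "appearance frequency in population") +
    ggplot2::theme_minimal()
}

#' Heatmap of the two-peak scenario sweep
#'
#' @param object A `two_peak_result`.
#' @param measure Column to fill by (default `p2_appeared`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_peak_result <- function(object, measure = "p2_appeared", ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$s1), y = factor(.data$s2),
                                   fill = .data[[measure]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "s1 (frequent phenotype)", y = "s2 (rare phenotype)",
                  fill = measure) +
    ggplot2::theme_minimal()
}

#' Strip of phenotypes along a genotype path
#'
#' @param object A `genotype_path` with phenotype annotations.
#' @param config A [raster_config()] used to render each step.
#' @param ... Unused.
#' @return A ggplot faceted by path step (phenotype transitions only).
#' @export
autoplot.genotype_path <- function(object, config = raster_config(), ...) {
  df <- as.data.frame(object)
  keep <- if ("phenotype_changed" %in% names(df)) {
    c(1L, which(df$phenotype_changed))
  } else {
    seq_len(nrow(df))
  }
  cells <- lapply(keep, function(i) {
    m <- unclass(phenotype_grid_of(as_genotype(df[i, paste0("g", 1:9)]),
                                   config))
    data.frame(step = df$step[i],
               row = rep(seq_len(nrow(m)), times = ncol(m)),
               col = rep(seq_len(ncol(m)), each = nrow(m)),
               on = as.vector(m) == 1L)
  })
  ggplot2::ggplot(dplyr::bind_rows(cells),
                  ggplot2::aes(x = .data$col, y = -.data$row,
                               fill = .data$on)) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black")) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~step, nrow = 1) +
    ggplot2::theme_void()
}
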