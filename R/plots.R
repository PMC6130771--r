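# ggplot helpers for the main result types. Stages are plotted in sampled
# order; when a timeline is supplied, points are colored by period with the
# conventional palette (grey pre-MZT, blue early, red middle, green late).

period_palette <- function() {
  c(
    preMZT = "grey60", early = "#2166ac",
    middle = "#b2182b", late = "#1b7837"
  )
}

stage_factor <- function(stage) factor(stage, levels = unique(stage))

#' Plot a transcriptome index profile
#'
#' Line of the per-stage index with its bootstrap confidence band; points
#' are colored by developmental period when a timeline is given.
#'
#' @param object A [tei_profile].
#' @param timeline Optional [stage_timeline] for period coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tei_profile <- function(object, timeline = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$stage <- stage_factor(df$stage)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$tei, group = 1)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "developmental stage",
      y = sprintf("transcriptome index (%s)", attr(object, "param", exact = TRUE))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(timeline)) {
    df$period <- as.character(timeline$period)[match(as.character(df$stage), timeline$stage)]
    p <- p +
      ggplot2::geom_point(data = df, ggplot2::aes(color = .data$period), size = 2) +
      ggplot2::scale_color_manual(values = period_palette())
  } else {
    p <- p + ggplot2::geom_point()
  }
  p
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the permuted early-minus-middle statistics with the
#' observed statistic as a vertical line.
#'
#' @param object A `devo_perm` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.devo_perm <- function(object, ...) {
  df <- tibble::tibble(delta = object$null_deltas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$delta_observed, color = "#b2182b") +
    ggplot2::labs(
      x = "permuted early - middle difference",
      y = "count",
      title = sprintf(
        "%s: observed delta = %.3g (p = %.3g normal, %.3g empirical)",
        object$param, object$delta_observed, object$p_normal, object$p_empirical
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stage pleiotropic-gene proportions
#'
#' @param object A [pleiotropy_profile()] result.
#' @param timeline Optional [stage_timeline] for period coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pleiotropy_profile <- function(object, timeline = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$stage <- stage_factor(df$stage)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$proportion, group = 1)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::labs(x = "developmental stage", y = "proportion of pleiotropic genes") +
    ggplot2::theme_minimal()
  if (!is.null(timeline)) {
    df$period <- as.character(timeline$period)[match(as.character(df$stage), timeline$stage)]
    p <- p +
      ggplot2::geom_point(data = df, ggplot2::aes(color = .data$period), size = 2) +
      ggplot2::scale_color_manual(values = period_palette())
  } else {
    p <- p + ggplot2::geom_point(color = "darkorange")
  }
  p
}

#' Plot the retrogene expression trend
#'
#' @param object A [retrogene_trend()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.retro_trend <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$stage <- stage_factor(df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$median_expression, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "developmental stage", y = "median retrogene expression",
      title = sprintf(
        "rho = %.2f, p = %.3g (%d retrogenes)",
        attr(object, "rho", exact = TRUE),
        attr(object, "p_value", exact = TRUE),
        attr(object, "n_genes", exact = TRUE)
      )
    ) +
    ggplot2::theme_minimal()
}
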