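#' Plot a pointwise F map
#'
#' Sensor x time heat map of the forming-step F statistic, with the
#' forming threshold marked on the fill scale.
#'
#' @param object an `fmap`.
#' @param forming_alpha threshold to annotate (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fmap
#' @export
autoplot.fmap <- function(object, forming_alpha = 0.05, ...) {
  df <- tibble::tibble(
    sensor = rep(object$sensors, times = ncol(object$f)),
    time_ms = rep(object$time_ms, each = nrow(object$f)),
    f = as.vector(object$f)
  )
  thr <- stats::qf(1 - forming_alpha, object$df[1], object$df[2])
  ggplot2::ggplot(df, ggplot2::aes(time_ms, sensor, fill = f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F") +
    ggplot2::labs(
      x = "time (ms)", y = NULL,
      title = sprintf("%s: pointwise F (forming threshold %.2f)",
                      object$effect, thr)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a permutation-test result
#'
#' Histogram of the null maximum cluster masses with the critical mass
#' (95th percentile) and the empirical cluster masses overlaid.
#'
#' @param object a `perm_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perm_result
#' @export
autoplot.perm_result <- function(object, ...) {
  nulls <- tibble::tibble(mass = object$null_max)
  p <- ggplot2::ggplot(nulls, ggplot2::aes(mass)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$critical, linetype = 2) +
    ggplot2::labs(
      x = "max cluster mass (null)", y = "permutations",
      title = sprintf("%s: critical mass %.1f (%d permutations)",
                      object$effect$name, object$critical, object$n_perm)
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters)) {
    p <- p + ggplot2::geom_point(
      data = object$clusters,
      ggplot2::aes(x = mass, y = 0, color = significant), size = 3, shape = 17
    ) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "steelblue",
                                             `TRUE` = "firebrick"))
  }
  p
}

#' Plot condition-average ERP waveforms
#'
#' Grand-average waveform per condition over a sensor selection (default:
#' all sensors).
#'
#' @param object an `epoch_set`.
#' @param sensors sensor ids to average over (default all).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot epoch_set
#' @export
autoplot.epoch_set <- function(object, sensors = NULL, ...) {
  if (!is.null(sensors)) object <- subset_epochs(object, sensors = sensors)
  ga <- apply(object$values, c(2, 4), mean)
  df <- tibble::tibble(
    condition = rep(object$conditions, times = length(object$time_ms)),
    time_ms = rep(object$time_ms, each = length(object$conditions)),
    amplitude = as.vector(ga)
  )
  ggplot2::ggplot(df, ggplot2::aes(time_ms, amplitude, color = condition)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot memory indices by stratum and memory class
#'
#' @param indices a [memory_indices()] tibble.
#' @param index which index to plot ("pr" or "d_prime").
#' @return a ggplot.
#' @export
plot_memory_indices <- function(indices, index = c("pr", "d_prime")) {
  index <- match.arg(index)
  facets <- intersect(c("category", "stimulation", "phase"), names(indices))
  p <- ggplot2::ggplot(
    indices,
    ggplot2::aes(.data$memory_class, .data[[index]], fill = .data$memory_class)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = index) +
    ggplot2::theme_minimal()
  if (length(facets)) {
    p <- p + ggplot2::facet_grid(
      stats::reformulate(facets[1], if (length(facets) > 1) facets[2] else ".")
    )
  }
  p
}
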