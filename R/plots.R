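#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Decimate the time axis so raster plots stay light.
decimate_cols <- function(n, max_cols = 2000L) {
  if (n <= max_cols) seq_len(n) else round(seq(1L, n, length.out = max_cols))
}

#' Plot a wavelet power surface
#'
#' Time-frequency raster of wavelet power on a logarithmic frequency axis;
#' cone-of-influence cells are blanked.
#'
#' @param object A `tfr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tfr <- function(object, ...) {
  cols <- decimate_cols(length(object$times))
  p2 <- Mod(object$coef[, cols, drop = FALSE])^2
  p2[object$coi[, cols, drop = FALSE]] <- NA_real_
  df <- tibble::tibble(
    time = rep(object$times[cols], each = length(object$freqs)),
    frequency = rep(object$freqs, times = length(cols)),
    power = as.numeric(p2)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)", fill = "Power")
}

#' Plot time-localized wavelet phase coherence
#'
#' @param object A `tl_wpc` object.
#' @param ... Unused.
#' @return A ggplot raster of coherence over time and (log) frequency,
#'   masked cells blank.
#' @export
autoplot.tl_wpc <- function(object, ...) {
  cols <- decimate_cols(length(object$times))
  df <- tibble::tibble(
    time = rep(object$times[cols], each = length(object$freqs)),
    frequency = rep(object$freqs, times = length(cols)),
    coherence = as.numeric(object$values[, cols, drop = FALSE])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)", fill = "WPC")
}

#' Plot per-window coupling strengths
#'
#' @param object A `dbi_fit` object.
#' @param threshold Optional surrogate threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot of the two directional strength time courses.
#' @export
autoplot.dbi_fit <- function(object, threshold = NULL, ...) {
  df <- tidy.dbi_fit(object)
  p <- ggplot2::ggplot(df, ggplot2::aes((.data$t_start + .data$t_end) / 2,
                                        .data$strength,
                                        colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Coupling strength",
                  colour = "Direction")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a global-coherence spectrum
#'
#' @param object A `mean_field` object.
#' @param ... Unused.
#' @return A ggplot of global coherence against (log) frequency.
#' @export
autoplot.mean_field <- function(object, ...) {
  ggplot2::ggplot(object$global_coherence,
                  ggplot2::aes(.data$frequency, .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Global coherence")
}

#' Violin plot of group connectivity values
#'
#' Distribution of per-subject values by group, faceted by probe pair (and
#' direction for coupling times).
#'
#' @param values Tibble from [run_pipeline()] results (`coherence` or
#'   `coupling` element), with `group`, `pair`, `value` columns.
#' @return A ggplot.
#' @export
plot_group_values <- function(values) {
  facet <- if ("direction" %in% names(values)) "direction" else "pair"
  ggplot2::ggplot(values, ggplot2::aes(.data$group, .data$value,
                                       fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::facet_wrap(facet) +
    ggplot2::labs(x = "Group", y = "Connectivity value") +
    ggplot2::theme(legend.position = "none")
}
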