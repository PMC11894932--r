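#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a wavelet transform into a power spectrum
#'
#' @param x A `tfr` object.
#' @param ... Passed to [time_avg_power()] (e.g. `exclude_coi`).
#' @return Tibble with `frequency`, `power`, `n_used`.
#' @export
tidy.tfr <- function(x, ...) {
  time_avg_power(x, ...)
}

#' Summarize a wavelet transform
#'
#' @param x A `tfr` object.
#' @param ... Unused.
#' @return One-row tibble: grid size, band, duration, fraction of cells
#'   inside the cone of influence.
#' @export
glance.tfr <- function(x, ...) {
  tibble::tibble(
    n_freqs = length(x$freqs), n_times = length(x$times),
    fmin = min(x$freqs), fmax = max(x$freqs),
    duration = length(x$times) / x$fs, fs = x$fs,
    coi_fraction = mean(x$coi)
  )
}

#' Tidy time-localized coherence into its time-averaged spectrum
#'
#' With `localized = TRUE`, returns the full (frequency, time, coherence)
#' long table instead (large for long records).
#'
#' @param x A `tl_wpc` object.
#' @param localized Return the full time-localized field.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tl_wpc <- function(x, localized = FALSE, ...) {
  if (!localized) return(time_avg_wpc(x))
  tibble::tibble(
    frequency = rep(x$freqs, times = length(x$times)),
    time = rep(x$times, each = length(x$freqs)),
    coherence = as.numeric(x$values)
  )
}

#' Summarize time-localized coherence
#'
#' @param x A `tl_wpc` object.
#' @param band Band (Hz) for the band-averaged value.
#' @param ... Unused.
#' @return One-row tibble: band mean coherence, window setting, valid
#'   fraction.
#' @export
glance.tl_wpc <- function(x, band = c(3.5, 12), ...) {
  tibble::tibble(
    band_coherence = band_average(time_avg_wpc(x), band),
    window_cycles = x$window_cycles,
    valid_fraction = mean(x$valid)
  )
}

#' Tidy a mean field into its global-coherence spectrum
#'
#' @param x A `mean_field` object.
#' @param ... Unused.
#' @return Tibble with `frequency`, `coherence`.
#' @export
tidy.mean_field <- function(x, ...) x$global_coherence

#' Tidy a surrogate pool into per-frequency null summaries
#'
#' @param x A `surrogate_pool` object.
#' @param ... Unused.
#' @return Tibble with `frequency`, `null_mean`, `null_q95`.
#' @export
tidy.surrogate_pool <- function(x, ...) {
  tibble::tibble(
    frequency = x$freqs,
    null_mean = rowMeans(x$spectra),
    null_q95 = apply(x$spectra, 1L, stats::quantile, probs = 0.95, type = 7)
  )
}

#' Tidy a windowed coupling fit into per-window strengths
#'
#' @param x A `dbi_fit` object.
#' @param ... Unused.
#' @return Long tibble: `window`, `t_start`, `t_end`, `direction`,
#'   `strength`.
#' @export
tidy.dbi_fit <- function(x, ...) {
  tidyr::pivot_longer(
    x$windows, dplyr::starts_with("strength_"),
    names_to = "direction", names_prefix = "strength_", values_to = "strength"
  )
}

#' Summarize a windowed coupling fit
#'
#' @param x A `dbi_fit` object.
#' @param ... Unused.
#' @return One-row tibble: window count and median directional strengths.
#' @export
glance.dbi_fit <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    window = x$config$window,
    basis_order = x$config$basis_order,
    median_strength_ab = stats::median(x$windows$strength_ab),
    median_strength_ba = stats::median(x$windows$strength_ba)
  )
}
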