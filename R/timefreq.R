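#' Wavelet analysis parameters
#'
#' Bundles the settings of the continuous Morlet wavelet transform: the
#' frequency-resolution (central frequency) parameter of the mother wavelet,
#' the analysed frequency interval, and the density of the logarithmic
#' frequency grid.
#'
#' The frequency-resolution parameter `central_frequency` is the number of
#' cycles of the complex sinusoid per Gaussian time-decay length; larger
#' values trade time localization for frequency resolution. The default of 4
#' is the convention used for EEG theta/alpha analysis.
#'
#' @param fs Sampling frequency of the signal, Hz.
#' @param fmin,fmax Frequency interval analysed, Hz. Defaults to the merged
#'   theta-alpha band 3.5-12 Hz.
#' @param central_frequency Morlet frequency-resolution parameter (cycles).
#' @param voices_per_octave Number of logarithmically spaced frequency bins
#'   per octave. The default 24 keeps the relative bin spacing under 3%.
#' @return An object of class `wavelet_params`.
#' @examples
#' wavelet_params(fs = 256)
#' @export
wavelet_params <- function(fs, fmin = 3.5, fmax = 12, central_frequency = 4,
                           voices_per_octave = 24) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(fmin, "fmin", positive = TRUE)
  stopifnot_scalar(fmax, "fmax", positive = TRUE)
  stopifnot_scalar(central_frequency, "central_frequency", positive = TRUE)
  stopifnot_scalar(voices_per_octave, "voices_per_octave", positive = TRUE)
  if (!(fmin < fmax && fmax <= fs / 2)) {
    stop("need 0 < fmin < fmax <= fs/2", call. = FALSE)
  }
  structure(
    list(fs = fs, fmin = fmin, fmax = fmax,
         central_frequency = central_frequency,
         voices_per_octave = voices_per_octave),
    class = "wavelet_params"
  )
}

#' @export
print.wavelet_params <- function(x, ...) {
  cat(sprintf(
    "<wavelet_params> Morlet, central frequency %g, %g-%g Hz, %g voices/octave, fs %g Hz\n",
    x$central_frequency, x$fmin, x$fmax, x$voices_per_octave, x$fs))
  invisible(x)
}

# Logarithmic frequency grid: fmin * 2^(k / voices), strictly log-spaced,
# ascending, topping out at or below fmax.
wavelet_freq_grid <- function(params) {
  n_oct <- log2(params$fmax / params$fmin)
  k <- 0:floor(n_oct * params$voices_per_octave + 1e-9)
  params$fmin * 2^(k / params$voices_per_octave)
}

#' Morlet mother wavelet
#'
#' Evaluates the Morlet mother wavelet at scale `scale` and time `t`: a
#' complex sinusoid of `central_frequency / scale` Hz inside a Gaussian
#' envelope of time-decay length `scale`, minus the admissibility correction
#' `exp(-2 pi^2 wc^2)` that makes the wavelet exactly zero-mean.
#'
#' @param scale Wavelet scale in seconds (> 0).
#' @param t Time offset(s) in seconds; vectorized.
#' @param params A [wavelet_params()] object (only `central_frequency` is
#'   used).
#' @return Complex value(s) of the wavelet.
#' @examples
#' p <- wavelet_params(fs = 256)
#' morlet(scale = 0.5, t = 0, params = p)   # real and positive at the peak
#' @export
morlet <- function(scale, t, params) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  wc <- params$central_frequency
  K <- exp(-2 * pi^2 * wc^2)
  pi^(-1 / 4) * (exp(2i * pi * wc * t / scale) - K) * exp(-t^2 / (2 * scale^2))
}

# Analytic Fourier transform of the (1/scale)-normalized Morlet kernel used by
# the convolution. With this normalization a unit-amplitude sinusoid at an
# on-grid frequency produces a ridge amplitude of sqrt(2*pi)/(2*pi^(1/4))
# ~= 0.9414, independent of frequency.
morlet_kernel_ft <- function(xi, freq, params) {
  wc <- params$central_frequency
  s <- wc / freq
  K <- exp(-2 * pi^2 * wc^2)
  sqrt(2 * pi) * pi^(-1 / 4) *
    (exp(-2 * pi^2 * s^2 * (xi - freq)^2) - K * exp(-2 * pi^2 * s^2 * xi^2))
}

# Kernel matrix (nfft x n_freqs), cached per (params, nfft): repeated
# transforms on same-shaped records skip the exp evaluations.
.kernel_cache <- new.env(parent = emptyenv())
morlet_kernel_matrix <- function(params, nfft) {
  key <- paste(params$fs, params$fmin, params$fmax, params$central_frequency,
               params$voices_per_octave, nfft, sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  freqs <- wavelet_freq_grid(params)
  xi <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) / (nfft / params$fs)
  K <- vapply(freqs, function(f) morlet_kernel_ft(xi, f, params),
              numeric(nfft))
  if (length(ls(.kernel_cache)) > 30L) {
    rm(list = ls(.kernel_cache), envir = .kernel_cache)  # crude bound
  }
  .kernel_cache[[key]] <- K
  K
}

#' Continuous wavelet transform on a logarithmic frequency grid
#'
#' Convolves the signal with Morlet wavelets at logarithmically spaced
#' frequencies, via frequency-domain multiplication with zero padding.
#' Cells closer to either record edge than sqrt(2) Gaussian time-decay
#' lengths of the wavelet at that frequency are flagged in the
#' cone-of-influence mask and should be excluded from summary statistics.
#'
#' The record must contain at least two cycles of `fmin`; records shorter
#' than thirty cycles trigger a warning, since reliable detection of
#' oscillatory coupling requires observing of the order of thirty cycles of
#' the slowest oscillation of interest.
#'
#' @param x Numeric vector, the sampled signal.
#' @param params A [wavelet_params()] object.
#' @return An object of class `tfr` with elements
#'   \describe{
#'     \item{coef}{complex matrix, frequency rows by time columns}
#'     \item{freqs}{Hz, ascending, strictly log-spaced}
#'     \item{times}{seconds from record start}
#'     \item{coi}{logical matrix, `TRUE` where edge-contaminated}
#'   }
#' @examples
#' p <- wavelet_params(fs = 64, fmin = 4, fmax = 12, voices_per_octave = 8)
#' tf <- wavelet_transform(sin(2 * pi * 8 * seq(0, 30, by = 1/64)), p)
#' @export
wavelet_transform <- function(x, params) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  n <- length(x)
  fs <- params$fs
  cycles <- (n / fs) * params$fmin
  if (cycles < 2) {
    stop(sprintf(
      "insufficient cycles: record holds %.2f cycles of fmin = %g Hz; at least 2 required",
      cycles, params$fmin), call. = FALSE)
  }
  if (cycles < 30) {
    warning(sprintf(
      "record holds only %.1f cycles of fmin = %g Hz; at least ~30 are recommended for coupling analysis",
      cycles, params$fmin), call. = FALSE)
  }
  freqs <- wavelet_freq_grid(params)
  nf <- length(freqs)
  nfft <- next_pow2(2L * n)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- morlet_kernel_matrix(params, nfft)
  # batch all scales through one multi-column inverse FFT
  coef <- t(stats::mvfft(X * K, inverse = TRUE)[seq_len(n), , drop = FALSE]) / nfft
  times <- (seq_len(n) - 1L) / fs
  coi <- matrix(FALSE, nrow = nf, ncol = n)
  radius <- sqrt(2) * params$central_frequency / freqs  # seconds
  for (i in seq_len(nf)) {
    r <- ceiling(radius[i] * fs)
    if (2L * r >= n) {
      coi[i, ] <- TRUE
    } else if (r > 0L) {
      coi[i, c(seq_len(r), (n - r + 1L):n)] <- TRUE
    }
  }
  structure(
    list(coef = coef, freqs = freqs, times = times, fs = fs,
         params = params, coi = coi),
    class = "tfr"
  )
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf(
    "<tfr> %d frequencies (%.3g-%.3g Hz) x %d samples (%.3g s at %g Hz)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    max(x$times), x$fs))
  invisible(x)
}

#' Time-averaged wavelet power
#'
#' Mean squared modulus of the wavelet coefficients per frequency, optionally
#' restricted to columns outside the cone of influence. Frequencies at which
#' every cell is excluded are returned as `NA`.
#'
#' @param rep A `tfr` object from [wavelet_transform()].
#' @param exclude_coi Drop edge-contaminated cells (default `TRUE`).
#' @return A tibble with columns `frequency`, `power`, `n_used`.
#' @export
time_avg_power <- function(rep, exclude_coi = TRUE) {
  if (!inherits(rep, "tfr")) stop("`rep` must be a tfr", call. = FALSE)
  p2 <- Mod(rep$coef)^2
  if (exclude_coi) p2[rep$coi] <- NA_real_
  n_used <- rowSums(!is.na(p2))
  pw <- rowMeans(p2, na.rm = TRUE)
  pw[n_used == 0L] <- NA_real_
  tibble::tibble(frequency = rep$freqs, power = pw, n_used = n_used)
}

#' Instantaneous phase field
#'
#' Extracts the argument of each wavelet coefficient, in (-pi, pi]. Cells
#' with exactly zero modulus have no defined phase and are returned as `NA`;
#' downstream coherence estimates drop them.
#'
#' @param rep A `tfr` object.
#' @return An object of class `phase_field`: list with `phase` (matrix,
#'   frequency x time), `freqs`, `times`, `fs`, and the `coi` mask.
#' @export
extract_phase <- function(rep) {
  if (!inherits(rep, "tfr")) stop("`rep` must be a tfr", call. = FALSE)
  ph <- Arg(rep$coef)
  ph[Mod(rep$coef) == 0] <- NA_real_
  structure(
    list(phase = ph, freqs = rep$freqs, times = rep$times, fs = rep$fs,
         coi = rep$coi),
    class = "phase_field"
  )
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %d frequencies x %d samples at %g Hz\n",
              length(x$freqs), length(x$times), x$fs))
  invisible(x)
}
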