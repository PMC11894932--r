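#' Intersubject surrogate coherence pool
#'
#' Builds the null distribution of "apparent" coherence for one probe pair
#' within one group: the time-averaged coherence between probe-1 phases of
#' subject i and probe-2 phases of subject j, for every ordered pair of
#' distinct subjects (i != j). Signals from different subjects cannot share
#' genuine coupling, so these spectra measure the coherence level produced
#' by chance alone at the record length in use. For n subjects the pool
#' holds n^2 - n spectra (e.g. 156 for 13 subjects); the n same-subject
#' diagonal entries are the genuine coherences and are excluded.
#'
#' @param fields1 List of `phase_field` objects: the first probe of the
#'   pair, one per subject, in subject order.
#' @param fields2 List of `phase_field` objects: the second probe of the
#'   pair, same subjects, same order.
#' @param pair Optional character length-2, probe labels (metadata only).
#' @param window_cycles Window of the time-localized coherence (default 10).
#' @return An object of class `surrogate_pool`: list with `spectra` (matrix,
#'   frequency x (n^2 - n)), `freqs`, `count`, `n_subjects`, `pair`.
#' @export
intersubject_pool <- function(fields1, fields2, pair = c("probe1", "probe2"),
                              window_cycles = 10) {
  n <- length(fields1)
  if (length(fields2) != n) {
    stop("`fields1` and `fields2` must list the same subjects", call. = FALSE)
  }
  if (n < 3L) stop("at least 3 subjects are required", call. = FALSE)
  stopifnot(all(vapply(fields1, inherits, TRUE, "phase_field")),
            all(vapply(fields2, inherits, TRUE, "phase_field")))
  lens <- c(vapply(fields1, function(f) length(f$times), 1L),
            vapply(fields2, function(f) length(f$times), 1L))
  nt <- min(lens)
  if (any(lens != nt)) {
    warning("record lengths differ across subjects; truncating to the shortest",
            call. = FALSE)
    trunc <- function(f) {
      f$phase <- f$phase[, seq_len(nt), drop = FALSE]
      f$coi <- f$coi[, seq_len(nt), drop = FALSE]
      f$times <- f$times[seq_len(nt)]
      f
    }
    fields1 <- lapply(fields1, trunc)
    fields2 <- lapply(fields2, trunc)
  }
  freqs <- fields1[[1L]]$freqs
  count <- n^2 - n
  spectra <- matrix(NA_real_, nrow = length(freqs), ncol = count)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      k <- k + 1L
      tlc <- time_localized_wpc(fields1[[i]], fields2[[j]],
                                window_cycles = window_cycles)
      spectra[, k] <- time_avg_wpc(tlc)$coherence
    }
  }
  structure(
    list(spectra = spectra, freqs = freqs, count = count, n_subjects = n,
         pair = pair),
    class = "surrogate_pool"
  )
}

#' @export
print.surrogate_pool <- function(x, ...) {
  cat(sprintf("<surrogate_pool> %s-%s: %d surrogate spectra from %d subjects\n",
              x$pair[1], x$pair[2], x$count, x$n_subjects))
  invisible(x)
}

#' Effective (surrogate-subtracted) coherence
#'
#' Subtracts, frequency by frequency, the mean of the intersubject surrogate
#' pool from an actual coherence spectrum; values falling at or below the
#' surrogate level are set to zero. The band mean of the result is the
#' effective coherence: a single nonnegative scalar per participant and
#' probe pair.
#'
#' @param actual A tibble with `frequency` and `coherence` columns, as from
#'   [time_avg_wpc()].
#' @param pool A `surrogate_pool` on the same frequency grid.
#' @param band Frequency band over which to average, Hz.
#' @return Scalar effective coherence (>= 0). The subtracted spectrum is
#'   attached as attribute `"spectrum"` (a tibble).
#' @export
effective_coherence <- function(actual, pool, band = c(3.5, 12)) {
  stopifnot(inherits(pool, "surrogate_pool"))
  if (!isTRUE(all.equal(actual$frequency, pool$freqs))) {
    stop("actual spectrum and surrogate pool are on different frequency grids",
         call. = FALSE)
  }
  null_mean <- rowMeans(pool$spectra)
  eff <- pmax(actual$coherence - null_mean, 0)
  spec <- tibble::tibble(frequency = actual$frequency, coherence = eff,
                         surrogate_mean = null_mean)
  out <- band_average(spec, band)
  attr(out, "spectrum") <- spec
  out
}

#' Surrogate threshold for coupling strengths
#'
#' Empirical 95th percentile of a pool of null coupling strengths, used to
#' decide per analysis window whether an inferred coupling exceeds chance
#' level. The percentile is computed with linear interpolation between order
#' statistics (the type-7 convention), so thresholds are reproducible across
#' implementations.
#'
#' @param pool Numeric vector of surrogate coupling strengths.
#' @param probs Percentile level (default 0.95).
#' @return Scalar threshold.
#' @export
coupling_threshold <- function(pool, probs = 0.95) {
  if (length(pool) == 0L) stop("empty surrogate pool", call. = FALSE)
  if (length(pool) < 20L) {
    warning("fewer than 20 surrogate values; the percentile threshold is unstable",
            call. = FALSE)
  }
  stats::quantile(pool, probs = probs, type = 7, names = FALSE)
}
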