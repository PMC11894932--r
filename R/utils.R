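# Internal helpers shared across modules.

# Analytic signal via the one-sided FFT construction (Marple 1999).
# Returns a complex vector whose argument is the instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least two samples", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Wrap phases into (-pi, pi].
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Centred running mean of a (possibly NA-holding) complex vector with a
# half-width of `hw` samples. Positions whose window would leave the record
# are returned as NA (the caller masks them); NA entries inside a window are
# dropped from the average.
running_mean_complex <- function(z, hw) {
  n <- length(z)
  w <- 2L * hw + 1L
  if (w > n) return(rep(NA_complex_, n))
  ok <- !is.na(z)
  z0 <- z
  z0[!ok] <- 0 + 0i
  cs <- cumsum(z0)
  ck <- cumsum(as.numeric(ok))
  idx <- (hw + 1L):(n - hw)
  hi <- idx + hw
  lo <- idx - hw
  sums <- cs[hi] - c(0 + 0i, cs)[lo]
  cnts <- ck[hi] - c(0, ck)[lo]
  out <- rep(NA_complex_, n)
  vals <- sums / cnts
  vals[cnts == 0] <- NA_complex_
  out[idx] <- vals
  out
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
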