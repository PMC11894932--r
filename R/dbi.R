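#' Configuration for windowed dynamical Bayesian inference
#'
#' Settings of the sliding-window Bayesian inference of phase-coupling
#' functions. The defaults follow the analysis protocol for theta/alpha EEG:
#' 3-s windows (at least 10 cycles of the slowest 3.5 Hz oscillation,
#' 10/3.5 = 2.9 s), propagation constant 0.2 controlling how much
#' information is carried between consecutive windows, overlap parameter
#' unity (no overlap), and a second-order Fourier basis for the coupling
#' functions.
#'
#' @param window Window length, seconds.
#' @param propagation_constant Nonnegative factor inflating the posterior
#'   covariance when it becomes the next window's prior; 0 makes windows
#'   independent.
#' @param overlap Overlap parameter; unity means consecutive windows do not
#'   overlap (the only mode implemented).
#' @param basis_order Order of the 2-D Fourier basis.
#' @param band Frequency band (Hz) used when phases are extracted from raw
#'   signals.
#' @param phase_source How phases are obtained from signals: zero-phase
#'   bandpass plus analytic signal (default), or the wavelet ridge.
#' @param downsample_to Target phase sampling rate, Hz, before inference
#'   (phases are decimated by an integer factor; set `Inf` to disable).
#' @return An object of class `dbi_config`.
#' @export
dbi_config <- function(window = 3, propagation_constant = 0.2, overlap = 1,
                       basis_order = 2, band = c(3.5, 12),
                       phase_source = c("analytic", "wavelet_ridge"),
                       downsample_to = 40) {
  stopifnot_scalar(window, "window", positive = TRUE)
  stopifnot_scalar(propagation_constant, "propagation_constant")
  if (propagation_constant < 0) {
    stop("`propagation_constant` must be >= 0", call. = FALSE)
  }
  if (!identical(overlap, 1) && !identical(overlap, 1L)) {
    stop("only `overlap = 1` (no overlap) is implemented", call. = FALSE)
  }
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (window * band[1] < 10) {
    warning(sprintf(
      "window of %g s holds only %.1f cycles at %g Hz; at least 10 are recommended",
      window, window * band[1], band[1]), call. = FALSE)
  }
  structure(
    list(window = window, propagation_constant = propagation_constant,
         overlap = 1, basis_order = as.integer(basis_order), band = band,
         phase_source = match.arg(phase_source),
         downsample_to = downsample_to),
    class = "dbi_config"
  )
}

#' Band-limited instantaneous phase
#'
#' Extracts the unwrapped instantaneous phase of a signal within a frequency
#' band: zero-phase Butterworth bandpass (applied forward and backward), then
#' the argument of the analytic signal, unwrapped.
#'
#' @param x Numeric signal.
#' @param band Length-2 numeric, Hz, inside (0, fs/2).
#' @param fs Sampling frequency, Hz.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return Numeric vector of unwrapped phases (radians), same length as `x`.
#' @export
extract_band_phase <- function(x, band = c(3.5, 12), fs, order = 2) {
  stopifnot(length(band) == 2L)
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  phi <- Arg(analytic_signal(xb))
  as.numeric(signal::unwrap(phi))
}

# Fourier basis over the torus for a pair of phases. Terms: the constant,
# then cos/sin(m*phiA + n*phiB) for every (m, n) in the half-plane
# m > 0 or (m == 0 and n > 0), with |m|, |n| <= order. The half-plane
# restriction removes the (m, n)/(-m, -n) redundancy.
dbi_basis_index <- function(order) {
  grid <- expand.grid(m = -order:order, n = -order:order)
  grid <- grid[grid$m > 0 | (grid$m == 0 & grid$n > 0), ]
  idx <- rbind(
    data.frame(m = 0, n = 0, fun = "const"),
    data.frame(m = rep(grid$m, each = 2), n = rep(grid$n, each = 2),
               fun = rep(c("cos", "sin"), nrow(grid)))
  )
  rownames(idx) <- NULL
  idx
}

# Evaluate the basis (K x M) and its phase-derivatives at given phase pairs.
dbi_basis_eval <- function(idx, phiA, phiB, derivatives = FALSE) {
  arg <- outer(idx$m, phiA) + outer(idx$n, phiB)
  Phi <- matrix(0, nrow(idx), length(phiA))
  Phi[idx$fun == "const", ] <- 1
  ic <- idx$fun == "cos"; is <- idx$fun == "sin"
  Phi[ic, ] <- cos(arg[ic, , drop = FALSE])
  Phi[is, ] <- sin(arg[is, , drop = FALSE])
  if (!derivatives) return(list(Phi = Phi))
  dA <- matrix(0, nrow(idx), length(phiA))
  dB <- matrix(0, nrow(idx), length(phiA))
  # d/dphiA cos(arg) = -m sin(arg);  d/dphiA sin(arg) = m cos(arg)
  dA[ic, ] <- -idx$m[ic] * sin(arg[ic, , drop = FALSE])
  dA[is, ] <- idx$m[is] * cos(arg[is, , drop = FALSE])
  dB[ic, ] <- -idx$n[ic] * sin(arg[ic, , drop = FALSE])
  dB[is, ] <- idx$n[is] * cos(arg[is, , drop = FALSE])
  list(Phi = Phi, dA = dA, dB = dB)
}

# One window of the Bayesian inference. Phases phiA/phiB (unwrapped) at step
# h. The model, per oscillator i in {A, B}:
#   dphi_i/dt = sum_k c_k^{(i)} Phi_k(phiA, phiB) + xi_i,   E[xi xi^T] = E/h
# discretized at midpoints. Given a Gaussian prior N(c_prior, Sigma_prior)
# (supplied as precision P_prior), alternate the posterior update for the
# stacked coefficients c = (c_A, c_B) with the residual-based noise update
# until convergence:
#   Xi   = P_prior + h * (Einv (x) Phi Phi^T)            [posterior precision]
#   r_i  = (P_prior c_prior)_i + h * Phi (Einv phidot)_i - (h/2) sum_n dPhi/dphi_i
#   c    = Xi^{-1} r
#   E    = (h/M) (phidot - C Phi)(phidot - C Phi)^T
dbi_fit_window <- function(phiA, phiB, h, idx, c_prior, P_prior,
                           max_iter = 40, tol = 1e-8) {
  M <- length(phiA) - 1L
  midA <- (phiA[-1L] + phiA[-length(phiA)]) / 2
  midB <- (phiB[-1L] + phiB[-length(phiB)]) / 2
  dotA <- diff(phiA) / h
  dotB <- diff(phiB) / h
  be <- dbi_basis_eval(idx, midA, midB, derivatives = TRUE)
  Phi <- be$Phi
  K <- nrow(Phi)
  G <- Phi %*% t(Phi)
  vA <- rowSums(be$dA)
  vB <- rowSums(be$dB)
  pr <- as.numeric(P_prior %*% c_prior)
  c_cur <- c_prior
  # start the noise estimate from the prior-mean residuals
  resid <- rbind(dotA - as.numeric(t(Phi) %*% c_cur[1:K]),
                 dotB - as.numeric(t(Phi) %*% c_cur[K + 1:K]))
  # relative ridge keeps E invertible when the two equations' residuals are
  # (near-)perfectly correlated, e.g. for phase-locked channels
  regularize <- function(E) E + diag(1e-9 * mean(diag(E)) + 1e-12, 2)
  E <- regularize((h / M) * tcrossprod(resid))
  PhidotA <- Phi %*% dotA
  PhidotB <- Phi %*% dotB
  for (it in seq_len(max_iter)) {
    Einv <- solve(E)
    Xi <- P_prior + h * rbind(cbind(Einv[1, 1] * G, Einv[1, 2] * G),
                              cbind(Einv[2, 1] * G, Einv[2, 2] * G))
    r <- pr + h * c(
      Einv[1, 1] * PhidotA + Einv[1, 2] * PhidotB - vA / 2,
      Einv[2, 1] * PhidotA + Einv[2, 2] * PhidotB - vB / 2
    )
    c_new <- solve(Xi, r)
    resid <- rbind(dotA - as.numeric(t(Phi) %*% c_new[1:K]),
                   dotB - as.numeric(t(Phi) %*% c_new[K + 1:K]))
    E_new <- regularize((h / M) * tcrossprod(resid))
    delta <- max(abs(c_new - c_cur)) / (1 + max(abs(c_new)))
    c_cur <- c_new
    E <- E_new
    if (delta < tol) break
  }
  Sigma_post <- solve(Xi)
  list(c = c_cur, Sigma = Sigma_post, E = E)
}

#' Windowed dynamical Bayesian inference of phase couplings
#'
#' Infers, over a sequence of non-overlapping windows, the bidirectional
#' phase model
#' \deqn{\dot\varphi_i = \sum_k c_k^{(i)} \Phi_k(\varphi_A, \varphi_B) + \xi_i}
#' where the basis holds a constant plus sines and cosines of
#' `m * phiA + n * phiB` up to `basis_order`, phase derivatives are
#' midpoint-discretized, and the noise matrix is estimated from the
#' residuals. Between windows the Gaussian posterior over the coefficients
#' becomes the next prior with its covariance inflated by
#' `1 / propagation_constant^2`: at the default 0.2 the previous window
#' enters with about 4% of the weight of the new data, smoothing coefficient
#' trajectories without freezing them; `propagation_constant = 0` disables
#' propagation entirely (every window is fitted with a flat prior,
#' independently), and values toward 1 approach full posterior carry-over.
#'
#' @param phiA,phiB Unwrapped phase series of equal length (radians).
#' @param config A [dbi_config()].
#' @param fs Sampling rate of the supplied phases, Hz.
#' @return An object of class `dbi_fit`: list with `coef` (matrix,
#'   2K coefficients x windows, equation-A block then equation-B block),
#'   `noise` (2 x 2 x windows), `windows` (tibble: `window`, `t_start`,
#'   `t_end`, `strength_ab`, `strength_ba`), `basis` (index data frame),
#'   `config`, `fs`.
#' @export
fit_windows <- function(phiA, phiB, config = dbi_config(), fs) {
  stopifnot(inherits(config, "dbi_config"))
  if (length(phiA) != length(phiB)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  if (anyNA(phiA) || anyNA(phiB) || any(!is.finite(c(phiA, phiB)))) {
    stop("phases must be finite", call. = FALSE)
  }
  dec <- max(1L, floor(fs / config$downsample_to))
  if (dec > 1L) {
    keep <- seq(1L, length(phiA), by = dec)
    phiA <- phiA[keep]
    phiB <- phiB[keep]
    fs <- fs / dec
  }
  h <- 1 / fs
  L <- round(config$window * fs)
  n_win <- floor(length(phiA) / L)
  if (n_win < 1L) {
    stop("record shorter than one inference window", call. = FALSE)
  }
  idx <- dbi_basis_index(config$basis_order)
  K <- nrow(idx)
  c_prior <- numeric(2L * K)
  # near-flat first prior; the tiny ridge pins only the null space of a
  # degenerate design (phase-locked channels make the torus basis collinear)
  P_prior <- diag(1e-6, 2L * K)
  coef <- matrix(NA_real_, 2L * K, n_win)
  noise <- array(NA_real_, c(2L, 2L, n_win))
  p2 <- config$propagation_constant^2
  for (w in seq_len(n_win)) {
    ii <- ((w - 1L) * L + 1L):(w * L)
    fit <- dbi_fit_window(phiA[ii], phiB[ii], h, idx, c_prior, P_prior)
    coef[, w] <- fit$c
    noise[, , w] <- fit$E
    if (p2 > 0) {
      # next prior: posterior covariance inflated by 1/p^2
      P_prior <- solve(fit$Sigma / p2)
      c_prior <- fit$c
    }   # p == 0: keep the flat prior; windows stay independent
  }
  windows <- tibble::tibble(
    window = seq_len(n_win),
    t_start = ((seq_len(n_win) - 1L) * L) * h,
    t_end = (seq_len(n_win) * L) * h
  )
  out <- structure(
    list(coef = coef, noise = noise, windows = windows, basis = idx,
         config = config, fs = fs, n_basis = K),
    class = "dbi_fit"
  )
  out$windows$strength_ab <- coupling_strength(out, "a_to_b")
  out$windows$strength_ba <- coupling_strength(out, "b_to_a")
  out
}

#' @export
print.dbi_fit <- function(x, ...) {
  cat(sprintf(
    "<dbi_fit> %d windows of %g s, basis order %d (%d terms/equation)\n",
    nrow(x$windows), x$config$window, x$config$basis_order, x$n_basis))
  cat(sprintf("  median strength A->B %.3g, B->A %.3g\n",
              stats::median(x$windows$strength_ab),
              stats::median(x$windows$strength_ba)))
  invisible(x)
}

#' Directional coupling strength
#'
#' Euclidean norm, per window, of the coefficients in the target
#' oscillator's equation whose basis terms involve the source phase
#' (self-only terms and the constant are excluded). For direction `"a_to_b"`
#' these are the terms with `m != 0` in B's equation.
#'
#' @param fit A `dbi_fit`.
#' @param direction `"a_to_b"` or `"b_to_a"`.
#' @return Numeric vector, one nonnegative strength per window.
#' @export
coupling_strength <- function(fit, direction = c("a_to_b", "b_to_a")) {
  stopifnot(inherits(fit, "dbi_fit"))
  direction <- match.arg(direction)
  K <- fit$n_basis
  if (direction == "a_to_b") {
    rows <- K + which(fit$basis$m != 0)   # B's equation, source = phiA
  } else {
    rows <- which(fit$basis$n != 0)       # A's equation, source = phiB
  }
  sqrt(colSums(fit$coef[rows, , drop = FALSE]^2))
}

#' Reconstructed coupling function surface
#'
#' Evaluates the inferred coupling function for one direction over a regular
#' phase grid, using the time-averaged coefficients of the basis terms that
#' involve the source phase.
#'
#' @param fit A `dbi_fit`.
#' @param direction `"a_to_b"` (surface as a function of the driving phase
#'   `phi_a` and the driven phase `phi_b`) or `"b_to_a"`.
#' @param n_grid Grid points per phase axis.
#' @param windows Optional integer vector of windows to average (default
#'   all).
#' @return A tibble with columns `phi_a`, `phi_b`, `q` (`n_grid^2` rows),
#'   suitable for delimited export or plotting.
#' @export
coupling_surface <- function(fit, direction = c("a_to_b", "b_to_a"),
                             n_grid = 50, windows = NULL) {
  stopifnot(inherits(fit, "dbi_fit"))
  direction <- match.arg(direction)
  K <- fit$n_basis
  windows <- windows %||% seq_len(ncol(fit$coef))
  cbar <- rowMeans(fit$coef[, windows, drop = FALSE])
  if (direction == "a_to_b") {
    rows <- which(fit$basis$m != 0)
    cc <- cbar[K + rows]
  } else {
    rows <- which(fit$basis$n != 0)
    cc <- cbar[rows]
  }
  g <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  grid <- expand.grid(phi_a = g, phi_b = g)
  be <- dbi_basis_eval(fit$basis[rows, , drop = FALSE], grid$phi_a, grid$phi_b)
  tibble::tibble(phi_a = grid$phi_a, phi_b = grid$phi_b,
                 q = as.numeric(t(be$Phi) %*% cc))
}

#' Percentage of time coupled
#'
#' Fraction (as a percentage) of analysis windows in which the coupling
#' strength lies strictly above a surrogate-derived threshold. Used instead
#' of the time-averaged strength, which a single exceptionally strong window
#' could dominate.
#'
#' @param strengths Numeric vector of per-window coupling strengths (one
#'   direction), e.g. `fit$windows$strength_ab`.
#' @param threshold Scalar threshold from [coupling_threshold()].
#' @return Percentage in \[0, 100\].
#' @export
coupling_time <- function(strengths, threshold) {
  if (length(strengths) == 0L) stop("zero analysis windows", call. = FALSE)
  stopifnot_scalar(threshold, "threshold")
  100 * mean(strengths > threshold)
}

#' Phase-coupling inference from a pair of raw signals
#'
#' Convenience wrapper: extracts band-limited phases from both signals
#' (per `config$phase_source`) and runs [fit_windows()].
#'
#' @param x,y Numeric signals, equal length.
#' @param fs Sampling rate, Hz.
#' @param config A [dbi_config()].
#' @return A `dbi_fit`.
#' @export
dbi_couple <- function(x, y, fs, config = dbi_config()) {
  stopifnot(length(x) == length(y))
  if (config$phase_source == "analytic") {
    phiA <- extract_band_phase(x, config$band, fs)
    phiB <- extract_band_phase(y, config$band, fs)
  } else {
    phiA <- ridge_phase(x, fs, config$band)
    phiB <- ridge_phase(y, fs, config$band)
  }
  fit_windows(phiA, phiB, config, fs)
}

# Wavelet-ridge phase: unwrapped phase along the maximum-amplitude ridge of
# the wavelet transform within the band.
ridge_phase <- function(x, fs, band = c(3.5, 12)) {
  p <- wavelet_params(fs = fs, fmin = band[1], fmax = band[2])
  tf <- wavelet_transform(x, p)
  ridge <- max.col(t(Mod(tf$coef)))
  phi <- Arg(tf$coef[cbind(ridge, seq_along(ridge))])
  as.numeric(signal::unwrap(phi))
}
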