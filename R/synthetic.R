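#' Specification of a two-mode non-autonomous signal pair
#'
#' Describes a pair of simulated EEG-like channels, each holding a
#' theta-like and an alpha-like oscillatory mode whose frequencies drift
#' slowly in time (non-autonomous dynamics). The alpha mode is shared (same
#' phase) between the two channels only from `shared_onset` onwards; before
#' that, the first channel has no alpha mode at all, so the channels hold no
#' common high-frequency component. Independent white Gaussian noise is
#' added to each channel.
#'
#' Default mode trajectories: theta at 5.5 Hz with a slow sinusoidal drift
#' of +/- 0.4 Hz, alpha centred at 11 Hz with +/- 0.3 Hz drift; unit mode
#' amplitudes and noise standard deviation 0.5.
#'
#' Mode instances that are *not* shared between channels (the two theta
#' modes) are decorrelated by drawing, per channel, a uniform base-frequency
#' offset of up to `freq_jitter` Hz and a random time offset of the drift
#' law, in addition to a random initial phase. Without this, two modes
#' following the same deterministic trajectory would keep a constant phase
#' difference and register as perfectly coherent however their initial
#' phases differ.
#'
#' @param duration Record length, seconds.
#' @param fs Sampling frequency, Hz; must exceed twice the fastest
#'   instantaneous frequency.
#' @param theta_freq,alpha_freq Functions of time (seconds) returning the
#'   instantaneous mode frequency in Hz.
#' @param shared_onset Time (seconds) after which the alpha mode is common
#'   to both channels.
#' @param mode_amplitudes Named numeric, amplitudes of the `theta` and
#'   `alpha` modes.
#' @param noise_sd Standard deviation of the additive white Gaussian noise.
#' @param freq_jitter Half-width (Hz) of the uniform per-channel base
#'   frequency offset applied to non-shared modes.
#' @param seed Optional integer seed for reproducible generation.
#' @return An object of class `two_mode_spec`.
#' @export
two_mode_spec <- function(duration = 400, fs = 256,
                          theta_freq = function(t) 5.5 + 0.4 * sin(2 * pi * t / 40),
                          alpha_freq = function(t) 11 + 0.3 * sin(2 * pi * t / 30),
                          shared_onset = 200,
                          mode_amplitudes = c(theta = 1, alpha = 1),
                          noise_sd = 0.5, freq_jitter = 0.3, seed = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(shared_onset, "shared_onset")
  stopifnot_scalar(noise_sd, "noise_sd")
  stopifnot(is.function(theta_freq), is.function(alpha_freq),
            all(c("theta", "alpha") %in% names(mode_amplitudes)),
            noise_sd >= 0)
  if (shared_onset < 0 || shared_onset > duration) {
    stop("`shared_onset` must lie within [0, duration]", call. = FALSE)
  }
  tt <- seq(0, duration, length.out = 1024L)
  fmax <- max(theta_freq(tt), alpha_freq(tt)) + freq_jitter
  if (fs <= 2 * fmax) {
    stop(sprintf(
      "sampling-theorem violation: fs = %g Hz but trajectories reach %.3g Hz",
      fs, fmax), call. = FALSE)
  }
  structure(
    list(duration = duration, fs = fs, theta_freq = theta_freq,
         alpha_freq = alpha_freq, shared_onset = shared_onset,
         mode_amplitudes = mode_amplitudes, noise_sd = noise_sd,
         freq_jitter = freq_jitter, seed = seed),
    class = "two_mode_spec"
  )
}

# Phase trajectory from an instantaneous-frequency function: cumulative
# trapezoid of 2*pi*f(t), plus an initial phase.
freq_to_phase <- function(f, t, phi0 = 0) {
  ft <- f(t)
  dt <- c(0, diff(t))
  phi0 + 2 * pi * cumsum((ft + c(ft[1L], ft[-length(ft)])) / 2 * dt)
}

#' Generate a two-mode signal pair
#'
#' Samples the pair of channels described by a [two_mode_spec()]. Channel
#' `a` carries the alpha mode only from `shared_onset` on; channel `b`
#' carries it throughout; where both are present the alpha phase is
#' identical across channels. Theta modes have independent random initial
#' phases, and each channel receives an independent white Gaussian noise
#' realization.
#'
#' @param spec A [two_mode_spec()].
#' @return A tibble with columns `time`, `a`, `b`. The noiseless mode
#'   components are attached as attribute `"components"` (a list of numeric
#'   vectors `theta_a`, `theta_b`, `alpha_a`, `alpha_b`).
#' @export
generate_two_mode_pair <- function(spec) {
  stopifnot(inherits(spec, "two_mode_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  amp <- spec$mode_amplitudes
  phi0 <- stats::runif(3L, 0, 2 * pi)  # theta_a, theta_b, alpha (shared)
  # decorrelate the per-channel theta instances: random base offset and a
  # random time offset into the drift law
  jit <- stats::runif(2L, -spec$freq_jitter, spec$freq_jitter)
  tau <- stats::runif(2L, 0, 100)
  th_a <- function(tt) spec$theta_freq(tt + tau[1L]) + jit[1L]
  th_b <- function(tt) spec$theta_freq(tt + tau[2L]) + jit[2L]
  theta_a <- amp[["theta"]] * cos(freq_to_phase(th_a, t, phi0[1L]))
  theta_b <- amp[["theta"]] * cos(freq_to_phase(th_b, t, phi0[2L]))
  alpha <- amp[["alpha"]] * cos(freq_to_phase(spec$alpha_freq, t, phi0[3L]))
  alpha_a <- alpha * as.numeric(t >= spec$shared_onset)
  a <- theta_a + alpha_a + stats::rnorm(n, sd = spec$noise_sd)
  b <- theta_b + alpha + stats::rnorm(n, sd = spec$noise_sd)
  out <- tibble::tibble(time = t, a = a, b = b)
  attr(out, "components") <- list(theta_a = theta_a, theta_b = theta_b,
                                  alpha_a = alpha_a, alpha_b = alpha)
  attr(out, "fs") <- spec$fs
  out
}

#' Inject amplitude spikes into a recording
#'
#' Adds brief, large-amplitude Gaussian-envelope transients at random times
#' — a crude stand-in for movement artefacts, used by robustness tests of
#' the phase-based measures. Spikes hit every channel with independent
#' random polarity.
#'
#' @param rec A [recording()].
#' @param n_spikes Number of transients over the record.
#' @param amplitude Peak amplitude of each transient (same units as the
#'   signal).
#' @param width Gaussian time-decay length of each transient, seconds.
#' @param seed Optional integer seed.
#' @return The spiked [recording()].
#' @export
inject_spikes <- function(rec, n_spikes = 5, amplitude = 10, width = 0.1,
                          seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(rec$data)
  t <- (seq_len(n) - 1L) / rec$fs
  centers <- stats::runif(n_spikes, 0, max(t))
  for (ct in centers) {
    env <- amplitude * exp(-(t - ct)^2 / (2 * width^2))
    sgn <- sample(c(-1, 1), nrow(rec$data), replace = TRUE)
    rec$data <- rec$data + outer(sgn, env)
  }
  rec
}

#' Specification of a unidirectionally coupled phase-oscillator pair
#'
#' Two phase oscillators X and P: X rotates freely at `omega_x`, while P's
#' phase velocity is modulated by X through the coupling function
#' `E * cos(phi_x + phase_shift)`, i.e.
#' `dphi_p/dt = omega_p + E cos(phi_x + phase_shift) + noise`. The coupling
#' is strictly unidirectional (X drives P, never the reverse). Integration
#' is by fixed-step Euler-Maruyama at the sampling rate.
#'
#' @param omega_x,omega_p Natural angular frequencies, rad/s.
#' @param E Coupling amplitude (>= 0), rad/s.
#' @param phase_shift Phase shift inside the coupling function, radians
#'   (default pi/2.5).
#' @param noise_sd_x,noise_sd_p Phase-noise intensities, rad/sqrt(s).
#' @param duration Seconds.
#' @param fs Integration/sampling rate, Hz; must exceed omega/pi for both
#'   natural frequencies.
#' @param seed Optional integer seed.
#' @return An object of class `phase_oscillator_spec`.
#' @export
phase_oscillator_spec <- function(omega_x = 2 * pi * 5.5, omega_p = 2 * pi * 8,
                                  E = 0, phase_shift = pi / 2.5,
                                  noise_sd_x = 0.1, noise_sd_p = 0.1,
                                  duration = 200, fs = 400, seed = NULL) {
  for (nm in c("omega_x", "omega_p", "E", "phase_shift", "noise_sd_x",
               "noise_sd_p", "duration", "fs")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (E < 0) stop("`E` must be >= 0", call. = FALSE)
  if (duration <= 0 || fs <= 0) stop("`duration` and `fs` must be > 0", call. = FALSE)
  if (fs <= max(omega_x, omega_p) / pi) {
    stop("sampling-theorem violation: fs must exceed omega/pi for both oscillators",
         call. = FALSE)
  }
  structure(
    list(omega_x = omega_x, omega_p = omega_p, E = E,
         phase_shift = phase_shift, noise_sd_x = noise_sd_x,
         noise_sd_p = noise_sd_p, duration = duration, fs = fs, seed = seed),
    class = "phase_oscillator_spec"
  )
}

#' Simulate the coupled phase-oscillator pair
#'
#' Integrates the unidirectionally coupled pair of a
#' [phase_oscillator_spec()] with the Euler-Maruyama scheme at the sampling
#' rate, from uniformly random initial phases.
#'
#' @param spec A [phase_oscillator_spec()].
#' @return A tibble with columns `time`, `phi_x`, `phi_p` (unwrapped
#'   phases), `phi_x_wrapped`, `phi_p_wrapped` (in (-pi, pi]), and the
#'   cosine projections `x`, `p`.
#' @export
generate_coupled_oscillators <- function(spec) {
  stopifnot(inherits(spec, "phase_oscillator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  h <- 1 / spec$fs
  phi_x <- numeric(n)
  phi_p <- numeric(n)
  phi_x[1L] <- stats::runif(1, 0, 2 * pi)
  phi_p[1L] <- stats::runif(1, 0, 2 * pi)
  xi_x <- stats::rnorm(n - 1L, sd = spec$noise_sd_x * sqrt(h))
  xi_p <- stats::rnorm(n - 1L, sd = spec$noise_sd_p * sqrt(h))
  for (k in seq_len(n - 1L)) {
    phi_x[k + 1L] <- phi_x[k] + spec$omega_x * h + xi_x[k]
    phi_p[k + 1L] <- phi_p[k] +
      (spec$omega_p + spec$E * cos(phi_x[k] + spec$phase_shift)) * h + xi_p[k]
  }
  tibble::tibble(
    time = (seq_len(n) - 1L) * h,
    phi_x = phi_x, phi_p = phi_p,
    phi_x_wrapped = wrap_phase(phi_x), phi_p_wrapped = wrap_phase(phi_p),
    x = cos(phi_x), p = cos(phi_p)
  )
}

#' Specification of a two-group synthetic cohort
#'
#' Describes a multichannel, multi-subject, two-group cohort with a
#' controllable inter-channel phase-coupling deficit: channels listed in
#' `coupled_pairs` share a common alpha-band oscillation whose amplitude in
#' group 2 is multiplied by `group_effect` (1 = no deficit, 0 = coupling
#' removed). All channels additionally carry an independent theta mode, an
#' independent alpha mode, and white noise.
#'
#' Defaults mirror a frontal-network study design: groups of 13 and 9 male
#' subjects, the four frontal probes of the 10-20 montage, six 3-minute
#' segments per subject at 256 Hz.
#'
#' @param n_per_group Integer length-2, subjects in groups 1 and 2.
#' @param channel_labels Unique montage labels.
#' @param coupled_pairs List of character length-2 vectors; both members of
#'   each pair must appear in `channel_labels`.
#' @param group_effect Multiplicative reduction (in \[0, 1\]) of the shared
#'   alpha amplitude in group 2.
#' @param segment_count Number of 3-minute-style segments per subject.
#' @param duration Segment length, seconds.
#' @param fs Sampling frequency, Hz.
#' @param amplitudes Named numeric: `theta`, `alpha_shared`, `alpha_own`
#'   mode amplitudes.
#' @param noise_sd White-noise standard deviation.
#' @param seed Optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(13, 9),
                        channel_labels = c("Fp1", "Fp2", "F3", "F4"),
                        coupled_pairs = list(c("Fp1", "Fp2"), c("F3", "Fp2"),
                                             c("Fp1", "F4"), c("F3", "F4")),
                        group_effect = 1, segment_count = 6,
                        duration = 180, fs = 256,
                        amplitudes = c(theta = 1, alpha_shared = 1,
                                       alpha_own = 0.5),
                        noise_sd = 0.5, seed = NULL) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1),
            is.list(coupled_pairs))
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels", call. = FALSE)
  }
  for (p in coupled_pairs) {
    if (length(p) != 2L || !all(p %in% channel_labels)) {
      stop("each coupled pair must name two channels from `channel_labels`",
           call. = FALSE)
    }
  }
  stopifnot_scalar(group_effect, "group_effect")
  if (group_effect < 0 || group_effect > 1) {
    stop("`group_effect` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("theta", "alpha_shared", "alpha_own") %in% names(amplitudes)))
  structure(
    list(n_per_group = as.integer(n_per_group),
         channel_labels = channel_labels, coupled_pairs = coupled_pairs,
         group_effect = group_effect, segment_count = as.integer(segment_count),
         duration = duration, fs = fs, amplitudes = amplitudes,
         noise_sd = noise_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic two-group cohort
#'
#' Samples every subject, segment and channel of a [cohort_spec()]. Within a
#' subject and segment, all channels participating in coupled pairs share a
#' single common alpha-band oscillation ("frontal network" common mode),
#' with amplitude scaled by `group_effect` for group-2 subjects; every
#' channel also carries an independent theta mode, an independent alpha
#' mode, and independent white Gaussian noise. With `group_effect = 1` the
#' two groups are statistically identical.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per (subject, segment): columns `subject`,
#'   `group` (factor "1"/"2"), `segment`, and a list-column `recording` of
#'   [recording()] objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  coupled <- unique(unlist(spec$coupled_pairs))
  amp <- spec$amplitudes
  # every independent mode instance gets its own base frequency (uniform
  # jitter) and drift offset, so unshared modes decohere; only the shared
  # alpha instance is common across coupled channels
  theta_inst <- function() {
    base <- 5.5 + stats::runif(1, -0.3, 0.3)
    tau <- stats::runif(1, 0, 40)
    function(t) base + 0.4 * sin(2 * pi * (t + tau) / 40)
  }
  alpha_inst <- function(jit = 0.3) {
    base <- 11 + stats::runif(1, -jit, jit)
    tau <- stats::runif(1, 0, 30)
    function(t) base + 0.3 * sin(2 * pi * (t + tau) / 30)
  }
  subjects <- sprintf("s%02d", seq_len(sum(spec$n_per_group)))
  groups <- rep(c("1", "2"), spec$n_per_group)
  n_rows <- length(subjects) * spec$segment_count
  recs <- vector("list", n_rows)
  subj_col <- character(n_rows)
  group_col <- character(n_rows)
  seg_col <- integer(n_rows)
  k <- 0L
  for (s in seq_along(subjects)) {
    gain <- if (groups[s] == "1") 1 else spec$group_effect
    for (seg in seq_len(spec$segment_count)) {
      shared <- amp[["alpha_shared"]] *
        cos(freq_to_phase(alpha_inst(jit = 0.2), t, stats::runif(1, 0, 2 * pi)))
      dat <- matrix(0, nrow = length(spec$channel_labels), ncol = n,
                    dimnames = list(spec$channel_labels, NULL))
      for (ch in spec$channel_labels) {
        sig <- amp[["theta"]] *
          cos(freq_to_phase(theta_inst(), t, stats::runif(1, 0, 2 * pi))) +
          amp[["alpha_own"]] *
          cos(freq_to_phase(alpha_inst(), t, stats::runif(1, 0, 2 * pi))) +
          stats::rnorm(n, sd = spec$noise_sd)
        if (ch %in% coupled) sig <- sig + gain * shared
        dat[ch, ] <- sig
      }
      k <- k + 1L
      subj_col[k] <- subjects[s]
      group_col[k] <- groups[s]
      seg_col[k] <- seg
      recs[[k]] <- recording(dat, fs = spec$fs,
                             meta = list(subject = subjects[s],
                                         group = groups[s], segment = seg))
    }
  }
  tibble::new_tibble(
    list(subject = subj_col, group = factor(group_col, levels = c("1", "2")),
         segment = seg_col, recording = recs),
    nrow = n_rows
  )
}
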