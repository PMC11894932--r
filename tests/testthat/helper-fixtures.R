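# Shared small fixtures. Everything is generated in code at test time.

# Wavelet settings small enough for fast unit tests.
small_params <- function(fs = 32, fmin = 3.5, fmax = 12, vpo = 6) {
  wavelet_params(fs = fs, fmin = fmin, fmax = fmax, voices_per_octave = vpo)
}

# Phase field of a signal, silencing the short-record advisory warning.
quiet_phase <- function(x, params) {
  extract_phase(suppressWarnings(wavelet_transform(x, params)))
}

# A tiny two-channel cohort spec used across surrogate/pipeline tests.
tiny_cohort_spec <- function(n_per_group = c(4, 3), group_effect = 1,
                             duration = 12, fs = 32, segment_count = 1,
                             seed = NULL) {
  cohort_spec(
    n_per_group = n_per_group, channel_labels = c("F3", "F4"),
    coupled_pairs = list(c("F3", "F4")), group_effect = group_effect,
    segment_count = segment_count, duration = duration, fs = fs, seed = seed
  )
}

# Band time-averaged WPC between the two channels of one recording.
band_wpc <- function(rec, params, band = c(3.5, 12)) {
  f1 <- quiet_phase(rec$data[1L, ], params)
  f2 <- quiet_phase(rec$data[2L, ], params)
  band_average(time_avg_wpc(time_localized_wpc(f1, f2)), band)
}

# Brute-force reference for the time-localized coherence of a toy phase
# grid: direct loop over centred window sums (the independent oracle for
# the vectorized running-mean implementation).
brute_force_tl_wpc <- function(ph1, ph2, fs, freqs, window_cycles = 10) {
  nf <- length(freqs)
  n <- ncol(ph1)
  out <- matrix(NA_real_, nf, n)
  for (i in seq_len(nf)) {
    hw <- round(window_cycles / 2 * fs / freqs[i])
    if (2L * hw + 1L > n) next
    for (j in (hw + 1L):(n - hw)) {
      acc <- 0 + 0i
      for (k in (j - hw):(j + hw)) {
        acc <- acc + exp(1i * (ph1[i, k] - ph2[i, k]))
      }
      out[i, j] <- Mod(acc / (2 * hw + 1))
    }
  }
  out
}

# Wrap a bare phase matrix as a phase_field (no COI) for oracle tests.
as_phase_field <- function(ph, fs, freqs) {
  structure(
    list(phase = ph, freqs = freqs, times = (seq_len(ncol(ph)) - 1) / fs,
         fs = fs, coi = matrix(FALSE, nrow(ph), ncol(ph))),
    class = "phase_field"
  )
}
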