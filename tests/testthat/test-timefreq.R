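test_that("morlet wavelet has a real positive peak, zero mean, and a symmetric envelope", {
  p <- wavelet_params(fs = 256)
  v0 <- morlet(scale = 0.5, t = 0, params = p)
  expect_equal(Im(v0), 0)
  expect_gt(Re(v0), 0)

  tt <- seq(-5, 5, by = 1e-4)
  vals <- morlet(scale = 0.5, t = tt, params = p)
  expect_lt(abs(sum(vals) * 1e-4), 1e-12)          # admissibility: zero mean
  expect_equal(Mod(vals), rev(Mod(vals)))          # Gaussian envelope symmetry
})

test_that("frequency grid is strictly log-spaced at the configured density", {
  p <- wavelet_params(fs = 256, fmin = 3.5, fmax = 12, voices_per_octave = 24)
  f <- phaseconn:::wavelet_freq_grid(p)
  ratios <- diff(log2(f))
  expect_equal(ratios, rep(1 / 24, length(ratios)))
  expect_equal(f[1], 3.5)
  expect_lte(max(f), 12)
})

test_that("a pure sinusoid produces a single ridge at its frequency with the documented amplitude", {
  fs <- 256
  p <- wavelet_params(fs = fs)
  f0 <- phaseconn:::wavelet_freq_grid(p)[25]   # an exactly on-grid frequency
  x <- cos(2 * pi * f0 * (0:(fs * 60 - 1)) / fs)
  tf <- suppressWarnings(wavelet_transform(x, p))
  pw <- time_avg_power(tf)
  expect_equal(pw$frequency[which.max(pw$power)], f0)
  # ridge amplitude: within 5% of sqrt(2*pi)/(2*pi^(1/4))
  ridge <- Mod(tf$coef[which.max(pw$power), !tf$coi[which.max(pw$power), ]])
  expect_lt(abs(mean(ridge) / (sqrt(2 * pi) / (2 * pi^0.25)) - 1), 0.05)
})

test_that("FFT evaluation agrees with direct quadrature of the transform integral", {
  fs <- 64
  p <- wavelet_params(fs = fs, fmin = 4, fmax = 10, voices_per_octave = 4)
  set.seed(11)
  n <- fs * 16
  x <- rnorm(n)
  tf <- suppressWarnings(wavelet_transform(x, p))
  tt <- (seq_len(n) - 1) / fs
  wc <- p$central_frequency
  for (i in c(1, length(tf$freqs))) {
    s <- wc / tf$freqs[i]
    for (j in round(n / 2) + c(0L, 17L)) {
      # WT(t) = (1/s) * sum_u x(u) Psi(s, t - u) / fs, far from the edges
      quad <- sum(x * morlet(s, tt[j] - tt, p)) / (s * fs)
      expect_equal(tf$coef[i, j], quad, tolerance = 1e-10)
    }
  }
})

test_that("zero signal transforms to zero and short records are rejected", {
  p <- small_params()
  tf <- suppressWarnings(wavelet_transform(rep(0, 32 * 12), p))
  expect_true(all(tf$coef == 0))
  expect_true(all(is.na(time_avg_power(tf)$power) |
                    time_avg_power(tf)$power == 0))
  expect_error(wavelet_transform(rnorm(10), p), "insufficient cycles")
  expect_warning(wavelet_transform(rnorm(32 * 3), p), "recommended")
})

test_that("phase extraction is amplitude-invariant and conjugation-odd", {
  p <- small_params()
  set.seed(3)
  x <- rnorm(32 * 12)
  tf <- suppressWarnings(wavelet_transform(x, p))
  tf8 <- suppressWarnings(wavelet_transform(8 * x, p))  # dyadic gain: exact
  expect_identical(extract_phase(tf)$phase, extract_phase(tf8)$phase)
  tf_pi <- suppressWarnings(wavelet_transform(pi * x, p))
  expect_equal(extract_phase(tf)$phase, extract_phase(tf_pi)$phase,
               tolerance = 1e-12)
  conj_tf <- tf
  conj_tf$coef <- Conj(tf$coef)
  ph <- extract_phase(tf)$phase
  ph_c <- extract_phase(conj_tf)$phase
  inner <- abs(ph) < pi - 1e-9  # the branch point pi maps to itself
  expect_equal(ph_c[inner], -ph[inner])
})

test_that("unwrapped ridge phase advances one cycle per period", {
  fs <- 256
  p <- wavelet_params(fs = fs)
  x <- cos(2 * pi * 8 * (0:(fs * 60 - 1)) / fs)
  tf <- suppressWarnings(wavelet_transform(x, p))
  i <- which.min(abs(tf$freqs - 8))
  ph <- extract_phase(tf)$phase[i, !tf$coi[i, ]]
  up <- as.numeric(signal::unwrap(ph))
  slope <- stats::coef(stats::lm(up ~ seq_along(up)))[2] * fs / (2 * pi)
  expect_lt(abs(slope / 8 - 1), 0.01)
})

test_that("time-shift covariance: shifting the input shifts the ridge phase pattern", {
  fs <- 64
  p <- wavelet_params(fs = fs, fmin = 4, fmax = 10, voices_per_octave = 8)
  set.seed(4)
  base <- as.numeric(stats::filter(rnorm(fs * 20 + 50), rep(1, 5), sides = 2))
  base[is.na(base)] <- 0
  k <- 32
  x1 <- base[1:(fs * 18)]
  x2 <- base[(1 + k):(fs * 18 + k)]
  t1 <- suppressWarnings(wavelet_transform(x1, p))
  t2 <- suppressWarnings(wavelet_transform(x2, p))
  i <- 4
  core <- (fs * 6):(fs * 10)   # away from both records' edges
  expect_equal(Mod(t1$coef[i, core + k]), Mod(t2$coef[i, core]),
               tolerance = 1e-6)
})

test_that("two-mode signal shows exactly two persistent ridges and an HF power step", {
  spec <- two_mode_spec(duration = 120, fs = 128, shared_onset = 60, seed = 5)
  sig <- generate_two_mode_pair(spec)
  p <- wavelet_params(fs = 128)
  tfa <- wavelet_transform(sig$a, p)
  pw <- time_avg_power(tfa)
  # local maxima of the time-averaged power; a sinusoidally drifting mode can
  # show a double hump (dwell at the drift turning points), so peaks closer
  # than 20% in frequency are clustered into one ridge
  pk <- which(diff(sign(diff(pw$power))) == -2) + 1L
  pk <- pk[pw$power[pk] > 0.25 * max(pw$power)]
  f_pk <- pw$frequency[pk]
  cluster_id <- cumsum(c(1, diff(log(f_pk)) > log(1.2)))
  centers <- vapply(split(seq_along(pk), cluster_id), function(ii) {
    f_pk[ii][which.max(pw$power[pk[ii]])]
  }, 1.0)
  expect_equal(length(centers), 2L)
  expect_lt(abs(centers[1] - 5.5), 0.7)
  expect_lt(abs(centers[2] - 11), 0.7)
  # HF-band power larger in the half where the mode is present
  i11 <- which.min(abs(tfa$freqs - 11))
  ok <- !tfa$coi[i11, ]
  tt <- tfa$times
  p_first <- mean(Mod(tfa$coef[i11, ok & tt < 60])^2)
  p_second <- mean(Mod(tfa$coef[i11, ok & tt >= 60])^2)
  expect_gt(p_second, 2 * p_first)
})

test_that("band-integrated wavelet power scales with signal variance", {
  # oracle: direct variance computation of each bandlimited component
  fs <- 128
  t <- (0:(fs * 60 - 1)) / fs
  m1 <- cos(2 * pi * 6 * t)
  m2 <- 0.5 * cos(2 * pi * 9 * t + 1)
  p <- wavelet_params(fs = fs, fmin = 3, fmax = 16)
  band_power <- function(x) {
    pw <- time_avg_power(suppressWarnings(wavelet_transform(x, p)))
    sum(pw$power * c(diff(log(pw$frequency)), 0), na.rm = TRUE)
  }
  b1 <- band_power(m1)
  b2 <- band_power(m2)
  bx <- band_power(m1 + m2)
  expect_lt(abs(b1 / b2 - var(m1) / var(m2)) / (var(m1) / var(m2)), 0.1)
  expect_lt(abs(bx - (b1 + b2)) / (b1 + b2), 0.1)
})
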