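test_that("band-phase extraction recovers the slope of a pure tone", {
  fs <- 128
  t <- (0:(fs * 20 - 1)) / fs
  x <- cos(2 * pi * 8 * t)
  phi <- extract_band_phase(x, band = c(3.5, 12), fs = fs)
  core <- (fs * 2):(fs * 18)   # away from filter edge transients
  slope <- stats::coef(stats::lm(phi[core] ~ t[core]))[2] / (2 * pi)
  expect_lt(abs(slope / 8 - 1), 0.01)
  # slow amplitude modulation leaves the phase slope unchanged
  xm <- (1 + 0.5 * sin(2 * pi * 0.2 * t)) * x
  phim <- extract_band_phase(xm, band = c(3.5, 12), fs = fs)
  slope_m <- stats::coef(stats::lm(phim[core] ~ t[core]))[2] / (2 * pi)
  expect_lt(abs(slope_m / 8 - 1), 0.01)
  expect_error(extract_band_phase(x, band = c(3.5, 70), fs = fs), "band")
})

test_that("broadband noise yields a monotone-trending phase with slope inside the band", {
  fs <- 128
  set.seed(51)
  phi <- extract_band_phase(rnorm(fs * 30), band = c(3.5, 12), fs = fs)
  slope <- (phi[length(phi)] - phi[1]) / 30 / (2 * pi)
  expect_gt(slope, 3.5)
  expect_lt(slope, 12)
})

test_that("window bookkeeping: a 180 s record at 3 s windows gives 60 fits", {
  set.seed(52)
  fs <- 40
  n <- fs * 180
  phiA <- cumsum(rep(2 * pi * 5 / fs, n)) + rnorm(n, sd = 0.02)
  phiB <- cumsum(rep(2 * pi * 8 / fs, n)) + rnorm(n, sd = 0.02)
  fit <- fit_windows(phiA, phiB, dbi_config(), fs = fs)
  expect_equal(nrow(fit$windows), 60L)
  expect_equal(ncol(fit$coef), 60L)
  expect_equal(nrow(fit$coef), 2L * fit$n_basis)
  expect_error(fit_windows(phiA[1:50], phiB[1:50], dbi_config(), fs = fs),
               "shorter")
  expect_error(fit_windows(c(phiA[-1], NA), phiB, dbi_config(), fs = fs),
               "finite")
})

test_that("uncoupled oscillators: strengths near zero, natural frequencies recovered", {
  spec <- phase_oscillator_spec(E = 0, duration = 120, fs = 400, seed = 53)
  osc <- generate_coupled_oscillators(spec)
  fit <- fit_windows(osc$phi_x, osc$phi_p, dbi_config(), fs = 400)
  K <- fit$n_basis
  # the constant term of each equation estimates the natural frequency
  expect_lt(abs(mean(fit$coef[1, ]) / spec$omega_x - 1), 0.05)
  expect_lt(abs(mean(fit$coef[K + 1, ]) / spec$omega_p - 1), 0.05)
  expect_lt(mean(fit$windows$strength_ab), 0.5)
  expect_lt(mean(fit$windows$strength_ba), 0.5)
})

test_that("coupling strength is the norm of the cross-term coefficients", {
  set.seed(54)
  fs <- 40
  n <- fs * 9
  phiA <- cumsum(rep(2 * pi * 5 / fs, n))
  phiB <- cumsum(rep(2 * pi * 8 / fs, n))
  fit <- fit_windows(phiA + rnorm(n, sd = 0.05), phiB + rnorm(n, sd = 0.05),
                     dbi_config(), fs = fs)
  K <- fit$n_basis
  idx <- fit$basis
  # all cross-coefficients zero -> 0; a single coefficient a -> |a|
  fit0 <- fit
  fit0$coef[] <- 0
  expect_equal(coupling_strength(fit0, "a_to_b"),
               rep(0, ncol(fit0$coef)))
  cross_rows <- K + which(idx$m != 0)
  fit1 <- fit0
  fit1$coef[cross_rows[1], ] <- -0.37
  expect_equal(coupling_strength(fit1, "a_to_b"),
               rep(0.37, ncol(fit1$coef)))
  # hand-check the norm against the stored per-window strengths
  expect_equal(fit$windows$strength_ab,
               sqrt(colSums(fit$coef[cross_rows, , drop = FALSE]^2)))
})

test_that("inferred strength grows monotonically with E and stays unidirectional", {
  strengths <- sapply(c(0, 5, 10), function(E) {
    spec <- phase_oscillator_spec(E = E, duration = 100, fs = 400,
                                  seed = 55 + E)
    osc <- generate_coupled_oscillators(spec)
    fit <- fit_windows(osc$phi_x, osc$phi_p, dbi_config(), fs = 400)
    c(fwd = mean(fit$windows$strength_ab), rev = mean(fit$windows$strength_ba))
  })
  expect_true(all(diff(strengths["fwd", ]) > 0))
  # E is recovered to within 25%
  expect_lt(abs(strengths["fwd", 2] / 5 - 1), 0.25)
  expect_lt(abs(strengths["fwd", 3] / 10 - 1), 0.25)
  # reverse direction stays at the uncoupled baseline level
  expect_lt(strengths["rev", 3], 3 * max(strengths["rev", 1], 0.1))
  expect_lt(strengths["rev", 3], 0.1 * strengths["fwd", 3])
})

test_that("the reconstructed coupling surface matches E cos(phi_x + pi/2.5)", {
  spec <- phase_oscillator_spec(E = 10, duration = 100, fs = 400, seed = 56)
  osc <- generate_coupled_oscillators(spec)
  fit <- fit_windows(osc$phi_x, osc$phi_p, dbi_config(), fs = 400)
  surf <- coupling_surface(fit, "a_to_b", n_grid = 50)
  expect_equal(nrow(surf), 2500L)
  truth <- 10 * cos(surf$phi_a + pi / 2.5)
  expect_gt(stats::cor(surf$q, truth), 0.9)
})

test_that("zero propagation gives independent windows; propagation smooths trajectories", {
  spec <- phase_oscillator_spec(E = 5, noise_sd_x = 0.3, noise_sd_p = 0.3,
                                duration = 60, fs = 400, seed = 57)
  osc <- generate_coupled_oscillators(spec)
  cfg <- function(p) dbi_config(propagation_constant = p)
  traj_var <- function(p) {
    f <- fit_windows(osc$phi_x, osc$phi_p, cfg(p), fs = 400)
    mean(apply(f$coef, 1, stats::var))
  }
  v <- vapply(c(0, 0.3, 0.9), traj_var, 1.0)
  expect_true(all(diff(v) < 0))   # more propagation, smoother trajectories
  # p = 0 reproduces an isolated single-window fit exactly (independence)
  f0 <- fit_windows(osc$phi_x, osc$phi_p, cfg(0), fs = 400)
  L <- round(3 * f0$fs)
  w5 <- (4 * L + 1):(5 * L)
  dec <- 400 / f0$fs
  keep <- seq(1, length(osc$phi_x), by = dec)
  solo <- fit_windows(osc$phi_x[keep][w5], osc$phi_p[keep][w5], cfg(0),
                      fs = f0$fs)
  expect_equal(f0$coef[, 5], solo$coef[, 1], tolerance = 1e-7)
})

test_that("strengths are invariant to amplitude scaling of the raw signals", {
  spec <- phase_oscillator_spec(E = 5, duration = 40, fs = 200, seed = 58)
  osc <- generate_coupled_oscillators(spec)
  x <- cos(osc$phi_x)
  y <- cos(osc$phi_p)
  f1 <- dbi_couple(x, y, fs = 200)
  f2 <- dbi_couple(4 * x, 0.25 * y, fs = 200)
  expect_equal(f1$windows$strength_ab, f2$windows$strength_ab,
               tolerance = 1e-9)
})

test_that("coupling time is the exceedance percentage with strict thresholding", {
  expect_equal(coupling_time(c(1, 2, 3, 4), 0), 100)
  expect_equal(coupling_time(c(1, 2, 1, 2), 1.5), 50)
  expect_equal(coupling_time(c(1, 1), 1), 0)    # strictly above
  expect_error(coupling_time(numeric(0), 1), "zero")
})

test_that("intermittent coupling registers as ~50% coupling time", {
  # coupling present only in the second half of the record
  fs <- 400
  spec_on <- phase_oscillator_spec(E = 8, duration = 60, fs = fs, seed = 59)
  spec_off <- phase_oscillator_spec(E = 0, duration = 60, fs = fs, seed = 60)
  on <- generate_coupled_oscillators(spec_on)
  off <- generate_coupled_oscillators(spec_off)
  phiA <- c(off$phi_x, on$phi_x + off$phi_x[length(off$phi_x)])
  phiB <- c(off$phi_p, on$phi_p + off$phi_p[length(off$phi_p)])
  fit <- fit_windows(phiA, phiB, dbi_config(), fs = fs)
  # null level from uncoupled runs of the same length
  null_fit <- fit_windows(off$phi_x, off$phi_p, dbi_config(), fs = fs)
  thr <- coupling_threshold(null_fit$windows$strength_ab)
  ct <- coupling_time(fit$windows$strength_ab, thr)
  expect_gt(ct, 35)
  expect_lt(ct, 65)
})

test_that("dbi_config validates its inputs and warns on short windows", {
  expect_warning(dbi_config(window = 2), "cycles")
  expect_error(dbi_config(propagation_constant = -1), "propagation")
  expect_error(dbi_config(overlap = 0.5), "overlap")
})
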