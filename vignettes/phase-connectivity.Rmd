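---
title: "Time-resolved phase connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved phase connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(phaseconn)
```

## The problem

Resting-state EEG in young children is contaminated by movement: amplitude
artefacts are unavoidable, and any connectivity measure weighted by
amplitude inherits them. The underlying neural oscillations are also
*non-autonomous* — their frequencies drift on the scale of seconds — so
time-asymptotic spectral estimates blur together modes that a time-resolved
view keeps apart. `phaseconn` implements a connectivity pipeline built
entirely on instantaneous *phases*: the continuous Morlet wavelet transform
supplies a phase at every point of the time-frequency plane, wavelet phase
coherence (WPC) quantifies how consistently two channels' phases co-vary,
intersubject surrogates calibrate what coherence arises by chance at a
given record length, and windowed dynamical Bayesian inference (DBI)
reconstructs directed phase-coupling functions and the percentage of time
a coupling exceeds its chance level. Group machinery (rank-sum, Friedman,
Kruskal-Wallis, Cohen's *d*, a shuffled-segment repeatability test, and a
minimum-detectable-effect-size calculation) compares two cohorts on these
values.

Everything operates inside a single merged theta-alpha band, 3.5-12 Hz.
Traditional band limits are ill-defined in young children — alpha sits
lower (~8 Hz) and spectra shift with maturation — so the pipeline treats
the merged interval as one analysis band and averages over it after time
averaging.

## Time-frequency representation

The transform convolves the signal with Morlet wavelets on a logarithmic
frequency grid. The mother wavelet at scale $s$ is a complex sinusoid of
frequency $\omega_c/s$ Hz inside a Gaussian envelope of time-decay length
$s$, minus the small constant $e^{-2\pi^2\omega_c^2}$ that makes it
exactly zero-mean (admissibility):

$$\Psi(s,t) = \pi^{-1/4}\left(e^{2\pi i \omega_c t/s} -
  e^{-2\pi^2\omega_c^2}\right) e^{-t^2/2s^2}.$$

Parameters that matter:

* **`central_frequency`** ($\omega_c$, default 4) — the
  frequency-resolution parameter: cycles of the sinusoid per Gaussian
  decay length. The term "frequency resolution" is used loosely in the
  applied literature; here it is interpreted as $\omega_c$ in the equation
  above, so larger values narrow the frequency response and widen the time
  smoothing. 4 gives a relative frequency bandwidth of
  $1/(2\pi\omega_c) \approx 4\%$, appropriate for separating a 5.5 Hz and
  an 11 Hz mode.
* **`voices_per_octave`** (default 24) — grid density;
  $\le 3\%$ spacing over 3.5-12 Hz at negligible cost.
* **Normalization** — the convolution kernel carries a $1/s$ factor so a
  unit-amplitude sinusoid at an on-grid frequency produces a ridge of
  modulus $\sqrt{2\pi}/(2\pi^{1/4}) \approx 0.9414$ at every frequency.
* **Edges** — evaluation is by frequency-domain multiplication with zero
  padding (verified in the tests against direct quadrature of the
  convolution integral at $10^{-10}$ relative error). Zero padding biases
  coefficients near the record ends, so cells closer than $\sqrt2\,s$
  (the cone of influence, COI) to either end are flagged and excluded
  from every summary; exclusion rather than tapering keeps phase
  estimates unbiased.
* Records shorter than two cycles of `fmin` are rejected; shorter than
  thirty cycles, a warning is raised — reliably detecting oscillatory
  coupling needs of the order of thirty cycles of the slowest oscillation.

```{r fig1-style}
spec <- two_mode_spec(duration = 120, fs = 128, shared_onset = 60, seed = 1)
sig <- generate_two_mode_pair(spec)
p <- wavelet_params(fs = 128)
tf_a <- wavelet_transform(sig$a, p)
tidy(tf_a)  # time-averaged power spectrum as a tibble
```

## Wavelet phase coherence

At each time-frequency cell the phase difference
$\Delta\phi = \phi^{(1)} - \phi^{(2)}$ defines a unit phasor
$e^{i\Delta\phi}$. The *time-localized* WPC is the modulus of the mean
phasor over a centred window of 10 complete oscillations ($\pm 5/f$
seconds at frequency $f$): 1 when the phase difference is constant over
the window, 0 when it drifts uniformly. Windows that would leave the
record are masked rather than shortened — a shortened window inflates
coherence at the edges. Because only phases enter, the statistic is
invariant to any positive amplitude gain on either channel.

Two time-collapsed summaries exist and they are *not* the same estimator:

* `time_avg_wpc(..., method = "phasor")` (default) — the modulus of the
  mean phasor over the whole retained record. This is the quantity used
  for significance testing: its chance level for unrelated signals falls
  off with record length (roughly as one over the square root of the
  number of independent phase samples).
* `method = "modulus"` — the mean of the windowed moduli. Descriptive
  only: the 10-cycle window holds few independent phase samples once the
  wavelet's own time smoothing is accounted for, so this average carries
  a bias of 0.4-0.8 that *does not* shrink with record length.

The surrogate machinery consumes the phasor form. `wpc_spectrum()`
computes it directly from two wavelet transforms (the phasor is
$W_1\overline{W_2}/|W_1 W_2|$), which is the cheap route when only
spectra are needed — e.g. the $n^2-n$ cross-subject pairs of a surrogate
pool. Band averaging (3.5-12 Hz) is applied after time averaging.

```{r wpc}
tf_b <- wavelet_transform(sig$b, p)
tlc <- time_localized_wpc(extract_phase(tf_a), extract_phase(tf_b))
i11 <- which.min(abs(tlc$freqs - 11))
c(first_half = time_avg_wpc(tlc, tmax = 60)$coherence[i11],
  second_half = time_avg_wpc(tlc, tmin = 60)$coherence[i11])
```

The two channels share their 11 Hz mode only from `shared_onset` on, and
the coherence at 11 Hz reflects exactly that.

## Global coherence: the wavelet mean field

For $N$ channels, each transform is normalized by the root of the grand
mean squared modulus across channels and times at that scale, and the
normalized transforms are averaged across channels:
$r_\sigma(t) = \frac1N \sum_n w_{n,\sigma}(t)$. Synchronized channels
reinforce; unsynchronized phasors cancel. The mean squared modulus
$\frac1T\sum_t |r_\sigma(t)|^2$ is the global coherence: exactly 1 for
complete synchrony (including $N = 1$), near $1/N$ for independent
channels. An "effective" global value is obtained the same way as for
pairs: subtract an intersubject surrogate level via
`effective_coherence()` applied to the global-coherence spectrum.

## Intersubject surrogates and effective coherence

Genuine coupling cannot exist between signals recorded from *different*
subjects. For a probe pair within a group of $n$ subjects, the pipeline
therefore computes the time-averaged coherence for all $n^2 - n$ ordered
cross-subject channel pairings (both directions included; the $n$
same-subject diagonal entries are the genuine values and are excluded):
13 subjects give 156 surrogate spectra. The per-frequency mean of the
pool is subtracted from each subject's actual spectrum, negatives are
clipped to zero, and the band mean gives one nonnegative *effective
coherence* per subject and pair.

For coupling strengths from DBI the null values run systematically
higher, so the threshold is the empirical 95th percentile of the pool
(type-7 linear interpolation between order statistics, stated so that
thresholds are reproducible; `coupling_threshold(1:100)` is 95.05). The
null statistic is the per-pair *time-averaged* coupling strength from
cross-subject phase pairs; a per-window alternative would mix window
noise into the null and is not used.

## Dynamical Bayesian inference

Functional coherence cannot distinguish mutual interaction from common
drive, and says nothing about direction. DBI fits, over a sequence of
windows, the coupled phase model

$$\dot\varphi_i = \sum_k c_k^{(i)}\, \Phi_k(\varphi_A, \varphi_B) + \xi_i,
  \qquad i \in \{A, B\},$$

with $\Phi$ a constant plus $\sin/\cos(m\varphi_A + n\varphi_B)$ up to
order 2 ($(2\cdot2+1)^2 = 25$ functions per equation; one member of each
$(m,n)/(-m,-n)$ pair), $\dot\varphi$ midpoint-discretized, a Gaussian
posterior over the stacked coefficients, and a $2\times2$ noise matrix
re-estimated from the residuals until convergence. The Bayesian machinery
itself (likelihood, noise update, prior propagation) is the standard
inference scheme for stochastic phase models, imported from the DBI
literature rather than invented here.

Numerical choices and parameters:

* **Window** 3 s — at least 10 cycles of the slowest band frequency
  (10/3.5 = 2.9 s). A 180 s segment yields 60 fits.
* **Propagation constant** $p$ (default 0.2) — between windows the
  posterior becomes the next prior with covariance inflated by $1/p^2$.
  $p = 0$ disables propagation (flat prior, independent windows);
  increasing $p$ tightens the prior and smooths coefficient trajectories.
  At 0.2 the previous window carries ~4% of the weight of the new data:
  enough to stabilize, not enough to freeze the inference when a coupling
  switches on mid-record.
* **Phases** — zero-phase Butterworth bandpass (3.5-12 Hz) followed by
  the analytic-signal argument, unwrapped (`extract_band_phase()`); a
  wavelet-ridge alternative sits behind `phase_source = "wavelet_ridge"`.
  Phases are decimated to ~40 Hz before inference (an integer factor of
  the sampling rate; ≥3x the band top) — unwrapped phases alias no
  information and the cost drops ~6x.
* **Degeneracy** — when two channels are strongly phase-locked the torus
  basis becomes collinear along $\varphi_A - \varphi_B$. A weak ridge
  prior ($10^{-6}$ precision) on the first window and a relative ridge on
  the noise matrix pin only that null space; both are orders of magnitude
  below any data-driven precision.
* **Coupling strength** — the Euclidean norm of the coefficients in the
  target's equation whose terms involve the source phase (all cross
  terms, $m \ne 0$ for A-to-B; constants and self terms excluded). For a
  pure $E\cos(\varphi_A + \text{shift})$ coupling this recovers $E$
  itself. The norm-over-all-cross-terms convention (rather than only
  pairwise-function terms) is deliberate: mixed terms carry genuine
  directed influence.
* **Coupling time** — a time-averaged strength can be dominated by one
  strong window, so the reported statistic is the percentage of windows
  strictly above the surrogate threshold.

```{r dbi}
osc <- generate_coupled_oscillators(
  phase_oscillator_spec(E = 10, duration = 100, fs = 400, seed = 2))
fit <- fit_windows(osc$phi_x, osc$phi_p, dbi_config(), fs = 400)
glance(fit)
```

The driven direction recovers the imposed amplitude ($E = 10$) while the
reverse direction stays at the noise floor; `coupling_surface()` exports
the reconstructed function on a phase grid for plotting.

## The synthetic-data module

No clinical recordings ship with the package; three generators stand in
for them, and their defaults *are* the study conditions the tests assume.

**Two-mode pairs** (`generate_two_mode_pair`) emulate the staged-
synchronization demonstration: theta near 5.5 Hz (±0.4 Hz slow sinusoidal
drift, 40 s period), alpha near 11 Hz (±0.3 Hz, 30 s period), unit
amplitudes, white noise of SD 0.5, 400 s at 256 Hz, with the alpha mode
shared between channels only from 200 s on. The drift laws and amplitudes
are documented stand-ins chosen to look like paediatric theta/alpha
activity — the reference simulation's exact constants were not available
— and every one is overridable. One subtlety is load-bearing: two modes
following the *same* deterministic frequency trajectory keep a constant
phase difference forever and register as perfectly coherent, whatever
their initial phases. Non-shared mode instances therefore get a random
base-frequency offset (±0.3 Hz uniform) and a random time offset into the
drift law, which makes "independent" mean independent in phase as well.

**Coupled phase oscillators** (`generate_coupled_oscillators`) integrate
$\dot\varphi_X = \omega_X$,
$\dot\varphi_P = \omega_P + E\cos(\varphi_X + \pi/2.5)$ plus white phase
noise by Euler-Maruyama at the sampling rate — the same discretization
the inference stage assumes. Natural frequencies default to
$2\pi\cdot5.5$ and $2\pi\cdot8$ rad/s (inside the analysis band; the
reference values were not available), noise 0.1 rad/$\sqrt{s}$, 200 s at
400 Hz, coupling strictly unidirectional.

**Cohorts** (`generate_cohort`) default to the study's shape: groups of
13 and 9, the four frontal probes (Fp1, Fp2, F3, F4), six 3-minute
segments at 256 Hz. Channels in `coupled_pairs` share one common
alpha-band oscillation per subject and segment; `group_effect` scales its
amplitude in group 2 (1 = identical groups, 0 = coupling removed). Each
channel additionally carries an independent theta mode, an independent
alpha mode (half amplitude), and noise. With `group_effect = 1` the
groups are exchangeable, which is what the null-calibration tests
exploit. The generator makes no attempt to mimic real artefact
morphology (blinks, EMG), volume conduction, or 1/f background — so
passing tests demonstrate correctness of the *methods* under controlled
oscillatory dynamics, not robustness to every property of clinical EEG.
The one artefact-like ingredient provided is `inject_spikes()`, which
adds brief large-amplitude transients; the robustness tests use it to
show that the phase-based coherence barely moves under heavy spiking.

## Group statistics

Rank-sum comparisons are exact when the smaller group has ≤10
observations and no ties occur, otherwise normally approximated with
midrank tie correction. Friedman's test gates whether segments can be
treated as repeated measures (fully tied blocks return $p = 1$ rather
than `NaN`); the Kruskal-Wallis test checks per-subject consistency.
Cohen's *d* uses the pooled-SD convention. The shuffled-segment test
draws one random segment per subject, compares groups, and repeats (1000
times by default), reporting the percentage of significant draws; with a
fixed seed it is bit-reproducible. A Bonferroni-adjusted threshold
(0.05/4 = 0.0125 for four frontal pairs; `adjust_group_stats()`) is
available as a reporting choice, not applied by default.

`sensitivity_mdes()` answers "what effect size could this design reliably
detect": it solves the noncentral-*t* power equation after multiplying
each group size by the asymptotic relative efficiency of the rank-sum
test. The default parent assumption is the distribution-free bound
(A.R.E. 0.864) — the convention of the standard power-analysis software
for this test, and the one that reproduces the published value for 13 vs
9 at 80% power, $d = 1.387$; normal ($3/\pi$), Laplace, logistic and
uncorrected variants are options. The assumed power level 0.80 is the
convention when none is stated.

```{r mdes}
sensitivity_mdes(13, 9, alpha = 0.05, power = 0.80)
```

## Problem sizes used by the test suite

The packaged tests run everything end to end at desk scale, chosen as the
smallest sizes at which each property is unambiguous: unit tests use
12-60 s records at 32-128 Hz with 4-12 voices per octave; the
staged-synchronization check runs the full 400 s at 256 Hz; DBI recovery
uses 20 replicates of 100-200 s simulations; the null calibration runs
12 000 effect-free cohorts (13 vs 9 subjects, 12 s records at 32 Hz, one
probe pair) through the complete simulate-transform-coherence-test chain
— the exact rank-sum test's true size at these group sizes is 0.0434,
and the replicate count pins the Monte-Carlo estimate to ±0.005 of it.
Clinical-scale records (3 min at 256 Hz, 19 channels) run through exactly
the same code paths; only the grids grow.

## Known limitations

* Coherence and coupling between scalp channels of *real* EEG partly
  reflect volume conduction; the package quantifies, but cannot remove,
  that contribution. Spatially separated pairs are the safer targets.
* The DBI noise model is white; strongly coloured phase noise biases the
  inferred noise matrix, though the surrogate thresholding absorbs much
  of the effect.
* `read_recording()` expects delimited channel-by-sample matrices; EDF
  containers must be converted upstream.
* The amplitude-invariance guarantees are exact in IEEE754 arithmetic for
  power-of-two gains; arbitrary positive gains agree to last-ulp rounding
  of the phase argument (~$10^{-12}$ relative), which is the best any
  floating-point implementation can do.
* Classification of subjects from the exported feature tables is out of
  scope: `run_pipeline()` writes the per-subject connectivity tables and
  any external learner can consume them.
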