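# phaseconn

Time-resolved, phase-based connectivity analysis for multichannel
resting-state EEG.

Amplitude-weighted connectivity measures inherit every movement artefact in
a recording — a serious problem for paediatric EEG — and time-asymptotic
spectral estimates blur oscillatory modes whose frequencies drift.
`phaseconn` implements a pipeline built entirely on instantaneous phases:

* **Continuous Morlet wavelet transform** on a logarithmic frequency grid
  with cone-of-influence masking (`wavelet_transform()`, `extract_phase()`).
* **Wavelet phase coherence** — time-localized over 10-cycle windows and
  time-averaged:
  `WPC(t,f) = (f/10) |∫_{t-5/f}^{t+5/f} e^{i(φ¹_{s,f} − φ²_{s,f})} ds|`,
  a value in [0, 1] that is exactly invariant to amplitude gains
  (`time_localized_wpc()`, `time_avg_wpc()`, `wpc_spectrum()`).
* **Wavelet mean field** `r_σ(t) = (1/N) Σ_n w_{n,σ}(t)` over normalized
  transforms, whose mean squared modulus is the global coherence across all
  channels (`wavelet_mean_field()`).
* **Intersubject surrogates**: the n² − n cross-subject coherences of a
  group bound what coherence arises by chance; subtracting their
  per-frequency mean (clipped at zero, band-averaged over 3.5–12 Hz) gives
  the *effective coherence* per subject and probe pair
  (`intersubject_pool()`, `effective_coherence()`), and their 95th
  percentile thresholds coupling strengths (`coupling_threshold()`).
* **Windowed dynamical Bayesian inference** of the coupled phase model
  `dφ_i/dt = Σ_k c_k⁽ⁱ⁾ Φ_k(φ_A, φ_B) + ξ_i` over a second-order Fourier
  basis, giving directional coupling strengths, reconstructed coupling
  functions, and the percentage of time coupled
  (`fit_windows()`, `coupling_strength()`, `coupling_surface()`,
  `coupling_time()`).
* **Group statistics**: Wilcoxon rank-sum, Friedman and Kruskal–Wallis
  consistency gates, Cohen's d, a 1000-shuffle segment-repeatability test,
  age regression, and a minimum-detectable-effect-size sensitivity analysis
  (`rank_sum()`, `shuffled_segment_test()`, `sensitivity_mdes()`, ...).
* **Synthetic data**: two-mode non-autonomous signal pairs, unidirectionally
  coupled phase oscillators, and two-group multichannel cohorts with a
  controllable coupling deficit (`generate_two_mode_pair()`,
  `generate_coupled_oscillators()`, `generate_cohort()`).

Results come back as tibbles; fitted objects have broom-style `tidy()` /
`glance()` methods and `autoplot()` graphics, so everything chains with the
pipe.

## Worked example

Two simulated channels share an 11 Hz mode only in the second half of the
record; phase coherence at 11 Hz finds exactly that:

```r
library(phaseconn)

spec <- two_mode_spec(duration = 400, fs = 256, shared_onset = 200, seed = 1)
sig  <- generate_two_mode_pair(spec)
p    <- wavelet_params(fs = 256)          # Morlet, 3.5-12 Hz, 24 voices/octave
tlc  <- time_localized_wpc(extract_phase(wavelet_transform(sig$a, p)),
                           extract_phase(wavelet_transform(sig$b, p)))
i11  <- which.min(abs(tlc$freqs - 11))
c(first  = time_avg_wpc(tlc, tmax = 200)$coherence[i11],
  second = time_avg_wpc(tlc, tmin = 200)$coherence[i11])
#>      first     second
#> 0.03583218 0.99777519
```

Coherence at 11 Hz is at chance level (0.036) while the mode is unshared
and near-perfect (0.998) once the channels synchronize.

Directed coupling on a unidirectionally driven oscillator pair
(`dφ_P/dt = ω_P + 10 cos(φ_X + π/2.5)`):

```r
osc <- generate_coupled_oscillators(
  phase_oscillator_spec(E = 10, duration = 200, fs = 400, seed = 100))
fit <- fit_windows(osc$phi_x, osc$phi_p, dbi_config(), fs = 400)
glance(fit)
#> # A tibble: 1 x 5
#>   n_windows window basis_order median_strength_ab median_strength_ba
#> 1        66      3           2               9.69              0.356
```

The driven direction recovers the imposed amplitude (median 9.7 for
E = 10) while the reverse direction stays near the noise floor — the
inference sees the coupling's direction, not just its presence.

A full two-group comparison on a synthetic cohort with the coupling removed
in group 2:

```r
coh <- generate_cohort(cohort_spec(
  n_per_group = c(13, 9), channel_labels = c("F3", "F4"),
  coupled_pairs = list(c("F3", "F4")), group_effect = 0,
  segment_count = 1, duration = 60, fs = 64, seed = 7))
res <- run_pipeline(coh, pairs = list(c("F3", "F4")),
                    wavelet = wavelet_params(fs = 64))
res$stats[, c("pair", "min_p", "median_p")]
#> # A tibble: 1 x 3
#>   pair       min_p median_p
#> 1 F3-F4 0.00000402 0.00000402
```

The groups separate completely: every group-1 subject's effective
coherence exceeds every group-2 subject's, so the rank-sum p-value equals
the exact minimum for these group sizes, 2/choose(22, 13).

`run_pipeline()` returns the per-subject effective-coherence table, the
group statistics per pair (rank-sum p, Cohen's d, shuffle percentages), and
a manifest; `write_results()` exports `coherence.csv`,
`coupling_time.csv`, `group_stats.json` and `manifest.json`.

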