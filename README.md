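# tcspcdna

Time-correlated single photon counting (TCSPC) analysis of the
intrinsic fluorescence of adenine–thymine DNA duplexes.

DNA duplexes are almost dark (fluorescence quantum yields ~10⁻⁴), but
single-photon counting resolves minor excited-state populations that
emit for nanoseconds. Besides the long-known low-energy (~420 nm)
excimer-like emission, homopolymeric A·T duplexes show a *high-energy*
long-lived component peaking below ~305 nm with an anisotropy plateau
of only 0.02–0.04 — the signature of mixed ππ*/charge-transfer
excitons delocalized over stacked bases (HELM excitons). This package
provides the full quantitative toolchain used to identify and weigh
such components, together with a calibrated synthetic-data generator
so that every stage is testable without any measured decay:

* photon-counting decay simulation: multi-exponential models convolved
  with a Gaussian instrument response (80 ps FWHM), Poisson noise,
  polarized channel pairs derived from an anisotropy model r(t);
* mono-exponential tail fits on 1.5–10.5 ns (Poisson-weighted, free
  background, no reconvolution);
* photon fractions after a 1 ns cut, and photon budgets over
  successive time intervals;
* time-resolved emission spectra (TRES): window integration, detector
  response correction, peak normalization, peak and width readouts;
* the relative-importance statistic
  **R = (f₃₀₅ / f₄₂₀) · I_ss(305)/I_ss(420)**, combining the
  long-lived photon fractions at 305 and 420 nm with the steady-state
  intensity ratio;
* fluorescence anisotropy traces
  **r(t) = (I∥ − G·I⊥)/(I∥ + 2G·I⊥)** with propagated Poisson errors,
  plateau estimation, and the analytic limits r(90°) = −0.2 and
  r = 0.1 for in-plane randomized emission dipoles;
* melting-curve analysis at 260 nm: two-state logistic fit with linear
  baselines, melting temperature and hyperchromicity.

Named presets (`get_preset()`) encode the published photophysics of
the polymeric duplex pA·pT (excitation 267/285 nm; standard,
six-fold-diluted and KCl-matched buffers) and the oligomer A₂₀·T₂₀
(285 nm): tail lifetimes 2.6/2.2/2.7 ns, per-wavelength photon
fractions, anisotropy plateaus 0.02/0.04, spectral widths
5400/6900 cm⁻¹, steady-state ratio 3.9, hyperchromicities 70/40/60%.
A deterministic calibration solves the decay amplitudes so that
noise-free analysis reproduces these values exactly; the tests verify
that the analysis side recovers them from noisy photon data.

## Worked example

Simulate the oligomer dataset at 10⁶ photons and run the analysis
chain:

```r
library(tcspcdna)

preset <- get_preset("A20T20", 285)
decays <- simulate_preset_decays(preset, n_photons = 1e6, seed = 11,
                                 wavelengths = c(305, 330, 420))

tail_fit(decays[["305"]])
#> <tail_fit> tau = 2.684 +/- 0.015 ns on [1.5, 10.5] ns (chi2_red 1.06)

100 * fraction_after(decays[["305"]])   # percent emitted after 1 ns
#> 49.9

spectrum <- simulate_steady_state_spectrum(preset)
r_from_dataset(decays, spectrum)
#> <rstat> R = 3.70  (frac305 = 0.499, frac420 = 0.359, Iss305/Iss420 = 2.66, t_cut = 1 ns)

pair <- simulate_preset_pair(preset, 305, n_photons = 2e6, seed = 11)
plateau_r(compute_r_trace(pair$parallel, pair$perpendicular))$r
#> 0.039

curve <- simulate_melting_curve(preset$melt_params, noise_sd = 0.005, seed = 11)
fit_melting(curve)
#> <melt_fit> Tm = 63.04 degC, width = 2.53 degC, hyperchromicity = 40.2% (rmse 0.0043)
```

Reading the output: the 305 nm decay carries a clean 2.7 ns tail and
half of its photons arrive after 1 ns; weighting the 305/420 fraction
ratio by the steady-state spectrum gives R ≈ 3.7, i.e. the long-lived
emission is dominated by the high-energy component; its anisotropy
plateau of ~0.04 is far below the 0.1 in-plane limit, indicating
out-of-plane (charge-transfer) character; and the 40% hyperchromicity
quantifies the base stacking released on melting.

`run_reproduction(run_manifest(seed = 1))` runs the same chain over
all presets and returns tables of recovered versus encoded values.

## Package layout

* `R/` — forward model and simulators (`grid.R`, `irf.R`, `models.R`,
  `convolve.R`, `simulate.R`, `spectra.R`, `presets.R`), analysis
  stages (`decay_ops.R`, `anisotropy.R`, `tres.R`, `helm_stat.R`,
  `melting.R`), IO and orchestration (`io.R`, `reproduce.R`).
* `inst/extdata/presets/presets.json` — ground-truth parameters the
  calibration consumes.
* `vignettes/tcspc-helm-analysis.Rmd` — models, calibration scheme,
  numerical choices and limitations.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
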