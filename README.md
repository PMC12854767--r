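# mpaspec

Post-processing for multiphoton-absorption studies of protein-bound
chromophores (for example the retinal Schiff base of channelrhodopsin-2).
Quantum-chemistry workflows for such systems produce, per
molecular-dynamics snapshot, a table of excited states: excitation energy
`ω_i`, oscillator strength `f_i`, and two-/three-photon transition
strengths `δ_i`. mpaspec turns those tables into science:

* **Spectra** — ensemble-averaged one-photon molar absorption
  `ε(ω) ∝ Σ_i (ω/ω_i) f_i g(ω; ω_i, γ_i)` (L mol⁻¹ cm⁻¹) and
  multiphoton cross sections
  `σ^TPA(ω) = k_TPA Σ_i ω² δ_i^TPA g(2ω; ω_i, γ_i)` (Göppert-Mayer
  units) and `σ^3PA(ω) = k_3PA Σ_i ω³ δ_i^3PA g(3ω; ω_i, γ_i)`, with
  unit-area Lorentzian broadening (γ = HWHM) and conversion constants
  derived from fundamental constants
  (`k_TPA = 8π³αa₀⁵/c ≈ 2.50547e-2`, `k_3PA = 16π⁴αa₀⁸/c² ≈ 7.78131e-7`),
  plus band-peak location and peak-deviation tables.
* **Sampling** — lagged autocorrelation
  `C(k) = (1/nσ²) Σ_{t≤n−k} (x_t−μ)(x_{t+k}−μ)` of a per-snapshot
  observable, exponential decay fits `C(t) = A e^(−t/τ)`, recommended
  decorrelated snapshot spacing, and down-sampling convergence studies.
* **Structure** — per-frame bond-length alternation
  `BLA = (Σσ_i − Σπ_i)/5` and dihedral planarity
  `P = Σ_i (||θ_i|−90|)/90 ∈ [0, 10]` from multi-frame XYZ trajectories
  and a JSON conjugation topology.
* **Correlation** — nearest-time joins of structural descriptors with
  excitation energies and descriptive Pearson/Spearman/OLS coefficients.
* **Coupling & polarization (toy scale)** — exact pairwise Coulomb
  references, single-center Cartesian multipole far fields (orders to 8),
  ESP-fitted charges, hybrid cutoff schemes with (R_exact, p) error
  scans, and a self-consistent induced-dipole solver over polarizable
  sites.
* **Synthetic data** — AR(1) excited-state ensembles, internal-coordinate
  chain trajectories with exact ground-truth sidecars, structure-coupled
  datasets, and charge/site layouts, all driven by a single seed.

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
methods for every result type, `tidy()`/`glance()` for fitted objects.

## Worked example

```r
library(mpaspec)

# two-photon spectrum of a 200-snapshot ensemble at 200 fs spacing
ens <- make_ensemble(n_snapshots = 200, dt_fs = 200, seed = 1)
tpa <- tpa_spectrum(ens$records, gamma = 0.1)
find_peaks(tpa, default_bands(ens$records, "TPA", states = 1:2))
#> # A tibble: 2 x 3
#>    band peak_energy_eV peak_intensity
#>   <int>          <dbl>          <dbl>
#> 1     1           1.41           99.3
#> 2     2           2.08          441.
```

The first TPA band peaks at 1.41 eV — half the 2.81 eV mean first
excitation energy of the generated ensemble, as it must on the
photon-energy axis — with a cross section of about 99 GM.

```r
# how far apart are snapshots statistically independent?
dense <- make_ensemble(n_snapshots = 1000, dt_fs = 5, seed = 1)
acf <- autocorrelation(tpa_strength_series(dense$records), max_lag = 150)
fit <- fit_acf_decay(acf)
fit
#> Exponential ACF fit: C(t) = A exp(-t/tau), A = 1.027, tau = 11.4 fs
decorrelation_spacing(fit$A, fit$tau_fs, tolerance = 0.01,
                      frame_interval_fs = 5)
#> [1] 55
```

The TPA cross-section autocorrelation of the densely sampled ensemble
decays with a fitted time of ~11 fs (generated with τ = 15 fs), and
residual correlation falls below 0.01 at a 55 fs spacing — frames taken
every few tens of fs are effectively uncorrelated.

```r
# structure-energy coupling on a synthetic chromophore
d <- make_coupled_dataset(n_frames = 200, seed = 1)
tl <- structure_timeline(d$trajectory, d$topology)
joined <- join_structure_spectra(tl, d$records)
tidy(descriptor_correlation(joined, "bla"))
#> # A tibble: 1 x 7
#>   x     y     pearson_r spearman_rho slope intercept     n
#>   <chr> <chr>     <dbl>        <dbl> <dbl>     <dbl> <int>
#> 1 bla   e1_eV     0.693        0.698  4.11      2.33   200
```

Lower bond-length alternation comes with lower first excitation energy
(r = 0.69, OLS slope 4.11 eV/Å against a generating coefficient of
4 eV/Å); the planarity correlation on the same data is negative.

A command-line wrapper over the same functions ships at `inst/cli/mpa`
(subcommands `generate-ensemble`, `generate-chain`, `spectra`, `acf`,
`downsample`, `structure`, `correlate`, `coupling-scan`, `polarize`; see
`?mpa_cli`).

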