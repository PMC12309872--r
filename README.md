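# veasl

Simulation, encoding design and decoding for **vessel-encoded
pseudo-continuous arterial spin labeling (VEASL)** — noninvasive MRI mapping
of which artery perfuses which brain territory, aimed at the demanding case
of labeling the many tortuous arterial branches just above the circle of
Willis.

## What it does

PCASL inverts arterial blood flowing through a thin labeling plane; adding
transverse gradient blips modulates the inversion efficiency sinusoidally
across the plane, so each acquisition cycle drives different vessels into
label or control states. Stacking cycles gives an encoding matrix `A`
(cycles × vessels + static tissue) whose pseudoinversion separates the
per-vessel perfusion signals. The package implements:

* **Bloch simulation of the labeling process** (`simulate_spin()`,
  `laminar_average_efficiency()`): a spin traversing the Hann-pulse train
  with T1/T2 relaxation, T1-corrected inversion efficiency, laminar
  flux-weighted velocity averaging, and vessel-angulation sweeps.
* **PCASL parameter optimization** (`optimize_pcasl()`): grid search for a
  thin labeling plane — effective width
  `z = 2 / (γ̄ · G_max · τ_RF) < 6 mm` — under an ≥ 85 % efficiency floor
  for mean velocities 5–50 cm/s and an alias-distance constraint,
  preferring short RF duration and then high mean gradient. It selects
  9 mT/m, 0.45 mT/m, 870 µs, 1560 µs, 30°.
* **Spatial modulation profiles** (`simulate_modulation()`): the inversion
  profile across the plane for bipolar/unipolar blips, including their
  very different off-resonance behavior.
* **Encoding design** (`oes()`, `ioes()`): Hadamard ideal matrices, a
  Fourier point-source cycle matcher with low-frequency weighting under the
  hard constraint `λ/2 > M` (M = expected vessel displacement, 4 mm), and
  the IOES outer loop — 100 randomized Hadamard column orderings scored by
  `cost = (1 − 1/C²)² + (1/(λ_min/2M − 1))²`.
* **Evaluation** (`snr_efficiency()`, `motion_robustness()`,
  `off_resonance_study()`, `relative_inversion_efficiency()`): theoretical
  per-territory SNR efficiency (ideal Hadamard ⇒ 1), Monte-Carlo motion
  robustness, duty-cycle/off-resonance studies.
* **Decoding** (`decode_linear()`, `classify_territories()`): voxelwise
  least-squares unmixing plus a simplified maximum-a-posteriori territory
  classifier (single vessel per voxel, Gaussian marginal likelihood with an
  amplitude prior).
* **Synthetic fixtures** (`make_vessels()`, `synthesize_stack()`):
  deterministic neck (4-vessel) and circle-of-Willis (9-vessel) geometries
  and ground-truth perfusion phantoms, so the whole pipeline is testable
  offline.
* **File formats / CLI**: vessel CSV/JSON, scheme JSON, profile CSV, NIfTI
  stacks, and a `veasl` command-line launcher
  (`system.file("cli", "veasl.R", package = "veasl")`) with subcommands
  `simulate-pcasl`, `optimize-pcasl`, `modulation`, `design`, `evaluate`,
  `synth`, `synth-stack`, `decode`.

## Worked example

Design encodings for nine vessels above the circle of Willis, synthesize a
vessel-encoded acquisition, and decode it:

```r
library(veasl)

optimal_pcasl_params()
#> PCASL parameters:
#>   g_max         9.00 mT/m
#>   g_mean        0.45 mT/m
#>   rf_duration    870 us
#>   rf_interval   1560 us  (duty cycle 55.8%)
#>   flip_angle    30.0 deg (hann envelope)
#>   effective width 6.00 mm, alias spacing 33.5 mm

vessels <- make_vessels("cow9")
scheme  <- ioes(vessels, n_iter = 100, seed = 7)
scheme
#> Encoding scheme: 13 cycles (11 selective), 9 vessels, Hadamard order 12
#>   condition number 1.7072, min wavelength 15.89 mm, cost 1.45937
#>   wavelengths 15.9, 17.2, 18.1, 20.3, 20.6, 33.5, 36.0, 39.0, 47.9,
#>   52.8, 56.0 mm

round(scheme_snr_efficiency(scheme), 3)
#>   ACA RMCA1 RMCA2 RMCA3 LMCA1 LMCA2 LMCA3  RPCA  LPCA
#> 0.868 0.742 0.846 0.814 0.789 0.860 0.856 0.895 0.842

syn <- synthesize_stack(vessels, scheme,
                        phantom_spec(noise_sd = sqrt(8) / 10, seed = 2))
map <- classify_territories(syn$stack)
perfused <- syn$truth > 0
mean(map$assignment[perfused] == syn$truth[perfused])
#> [1] 1
```

The 13 cycles are the 12 rows derived from an order-12 Hadamard matrix (one
of which is the all-control cycle) plus an appended nonselective label
cycle. Condition number 1.71 means the realized (non-ideal) encodings
amplify decoding noise modestly relative to a perfect Hadamard design —
per-vessel SNR efficiencies around 0.83 on the scale where an ideal design
scores 1 — and every wavelength stays above twice the 4 mm expected motion.
At an effective SNR of 10 the decoder recovers 100 % of perfused voxels on
this phantom.

The `ioes()` design improves on the canonical-order baseline `oes()` in
both conditioning and wavelength; compare
`oes(vessels)$cost` with `scheme$cost`, or run
`motion_robustness()` on both schemes to reproduce the motion advantage.

## Vignette

`vignettes/veasl-methods.Rmd` documents the model and the numerical
choices: the Bloch integrator and flux-weighted laminar averaging, the
modulation-profile phase conventions, the low-frequency weighting in the
Fourier cycle matcher, the cost function, the motion model, the simplified
Bayesian classifier, and what the synthetic phantoms do and do not
demonstrate.
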