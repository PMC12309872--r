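---
title: "Vessel-encoded PCASL: simulation, encoding design and decoding methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-encoded PCASL: simulation, encoding design and decoding methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veasl)
```

## The problem

Vessel-encoded pseudo-continuous arterial spin labeling (VEASL) maps which
artery feeds which brain region without contrast agent. A PCASL pulse train
inverts arterial blood as it flows through a thin labeling plane; transverse
gradient blips make the inversion efficiency vary sinusoidally across that
plane, so different arteries can be driven into label or control states in
different acquisition cycles. Decoding the cycle-by-cycle signal then
separates the perfusion territories. Above the circle of Willis the feeding
arteries are numerous, tortuous, and packed closely together, which stresses
every stage of this pipeline: the labeling plane must be thin enough that
each vessel behaves like a single point, and the encoding scheme must
tolerate imperfect modulation and head motion. This package implements the
full desk-scale stack: a Bloch simulator of the labeling process, the
spatial-modulation (inversion profile) simulation, Hadamard-based encoding
design with a randomized-column outer loop (IOES), SNR-efficiency and
motion-robustness evaluation, and a simplified territory decoder, plus
synthetic geometries and phantoms that make the whole chain testable.

## Bloch simulation of the labeling process

A single spin travels through the labeling plane at constant speed. Each RF
interval contains a Hann-windowed pulse of duration $\tau$ played under the
slice-select gradient $G_{max}$, followed by a rectangular rewinder lobe
sized so the interval-mean gradient equals $G_{mean}$. The integrator uses
hard-pulse steps of at most 10 µs during RF (5 µs by default, chosen so
halving the step changes the final magnetization at the 10⁻⁴ level) and a
closed-form precession/relaxation update over the gap; the core is compiled
code because the laminar grid searches need millions of rotation steps.
The flip angle is defined as the on-resonance integral of the Hann
envelope. The rewinder amplitude is capped at a configurable hardware limit
(45 mT/m default) and an unreachable $G_{mean}$ raises an error rather than
silently clipping.

The label condition uses a constant RF phase; control alternates the phase
by $\pi$. Labeling efficiency is the T1-corrected inversion
$\alpha = (1 - M_{z,corr})/2$, where the longitudinal recovery between the
plane-crossing time and the simulation end is rewound in closed form. Spins
start 20 mm upstream and finish 20 mm downstream of the plane center, which
covers the widest simulated labeling width (and the nearest aliased
labeling planes for mean gradients near the search ceiling) with margin.

**Laminar averaging.** The velocity distribution of fully developed laminar
flow is uniform over the cross-section on $(0, 2\bar v]$; we sample it with
20 sub-velocities and weight each by the blood flux it carries
(proportional to velocity), because labeling efficiency applies to the
delivered bolus rather than to the lumen area. This choice is load-bearing:
with flux weighting the optimized parameter set keeps its minimum laminar
efficiency above 85 % across 5–50 cm/s (minimum 85.3 % at 50 cm/s) and the
mean-gradient sweep selects 0.45 mT/m, while an unweighted cross-sectional
average would fail the floor at 5 cm/s. An `weighting = "area"` option
keeps the unweighted variant available.

**Vessel angulation.** A vessel tilted by angle $\beta$ from the plane
normal is modeled by its through-plane velocity $v\cos\beta$; the in-plane
drift does not interact with the slice-select gradient for nonselective
labeling. As $\beta \to 90^\circ$ the through-plane speed is floored at
0.1 cm/s, so the reported efficiency is the simulator's slow-flow limit.

## Parameter optimization

The search reproduces the published protocol: $G_{max}$ 1–9 mT/m (0.5
steps), $G_{mean}$ 0.1–0.9 mT/m (0.05), RF duration 50–950 µs (10 µs), flip
angle 8–30° (2°), RF interval fixed at 1560 µs. Constraints: effective
width $z = 2 / (\bar\gamma\, G_{max}\, \tau) < 6$ mm, first aliased
labeling plane (spacing $1/(\bar\gamma\, G_{mean}\, T)$) at least 30 mm
from the plane center (the alias-distance threshold is a package default;
30 mm keeps the alias outside a typical imaging gap), and laminar-average
efficiency ≥ 85 % at every mean velocity in 5–50 cm/s. Selection prefers
the shortest RF duration (lowest duty cycle), then the highest $G_{mean}$
(smallest rewinder lobe), then the highest $G_{max}$ and flip angle. The
width constraint is pruned analytically, so only the feasible corner of the
grid (RF ≥ 870 µs at $G_{max}$ = 9) is Bloch-simulated, and velocities are
checked from fast to slow because adiabaticity fails first at high speed.
The search returns (9 mT/m, 0.45 mT/m, 870 µs, 1560 µs, 30°) in under a
minute on one core.

## Spatial modulation profiles

Vessel-encoding blips give a spin at in-plane position $x$ an extra phase
$\theta(x) = k \cdot x + \phi$ per RF interval. The exact on-scanner RF
phase schedule for the two blip polarities lives in prior pulse-sequence
work; the package pins the observable contract instead: the profile
simulation applies the control phase schedule plus a per-interval
z-rotation by $\theta$ (sign alternating for bipolar), so $\theta = 0$
reproduces the nonselective control and $\theta = \pi$ the nonselective
label. Values are normalized to the control outcome, putting profiles on
the ideal $+1$ (control) to $-(2\alpha-1)$ (label) scale. This convention
reproduces the expected off-resonance phenomenology: a bipolar profile
stays centered and only loses labeling efficiency, while a unipolar profile
shifts bodily — and with the thin-plane parameters the unipolar label
region is several times narrower than the bipolar one, which is why bipolar
encoding is the robust default. Profiles are tabulated on 64 phase samples
and evaluated by periodic linear interpolation; the default simulation
velocity is 30 cm/s.

## Encoding design: OES and IOES

The ideal design for $N$ vessels takes $N$ columns (plus an all-ones
static-tissue column) from the smallest normalized Hadamard matrix of order
$\geq N+1$ (orders 4, 8, 12; order 12 by the Paley construction). Each row
is realized by one encoding cycle: a single spatial frequency $k$ and phase
$\phi$ chosen to maximize the point-source spectrum
$|S(k)| = |\sum_j e_j e^{i k \cdot x_j}|$ over the admissible band
$\lambda/2 > M$, where $M$ (default 4 mm) is the largest expected vessel
displacement. The raw spectrum has a hazard: for any geometry there are
arbitrarily high spatial frequencies nearly commensurate with the vessel
spacings where $|S|$ approaches its ceiling, and an unweighted matcher
drives every cycle to the band edge — maximally motion-sensitive and
contrary to the published wavelength ranges. The matcher therefore applies
a gentle low-frequency weighting $w(\lambda) = \lambda/(\lambda + M/2)$,
strong enough to discard those aliases but weak enough that a
full-modulation optimum at moderate wavelength (e.g. $\lambda \approx 2d$
for an antipodal pair at spacing $d$) stays in place. A polar search grid
(180 directions × 60 log-spaced wavelengths up to 4× the geometry
diagonal) is refined by Nelder–Mead within the band; ties break toward the
longest wavelength.

The realized matrix is then simulated by evaluating a modulation profile at
each vessel's $\theta$, and scored by
$\mathrm{cost} = (1 - 1/C^2)^2 + (1/(\lambda_{min}/2M - 1))^2$ with $C$ the
2-norm condition number of the simulated matrix including the tissue
column. The first term vanishes for Hadamard-like conditioning; the second
diverges as the shortest wavelength approaches $2M$. Written with $C_2$ for
the 2-norm condition number, the first factor could be read as either
$(1-1/C_2)^2$ or $(1-1/C_2^2)^2$; both vanish at $C=1$ and are monotone, so
the choice only rescales the term. The package defaults to the squared-
condition-number form and exposes `cost_form` for the alternative.

IOES runs 100 iterations, each with a freshly randomized assignment of
Hadamard columns to vessels, and keeps the minimum-cost design; iteration 1
always uses the canonical column order, so the IOES cost can never exceed
the OES baseline. A nonselective label cycle is appended to the final
scheme (it measures relative inversion efficiency in vivo); the design
diagnostics refer to the Hadamard-derived rows. On the bundled
near-rectangle neck geometry IOES reaches condition number ≈ 1.006 with
wavelengths 55–102 mm while canonical OES is forced to 17–102 mm at a 6×
higher cost; on the nine-vessel circle-of-Willis fixture IOES lifts the
minimum wavelength from ≈ 9 mm to ≈ 16 mm. Fixture coordinates are
template constants resembling typical anatomy, not measurements; the neck
template is deliberately an *approximate* rectangle, since exact symmetry
would let even the canonical column order realize every row at long
wavelength and hide the OES/IOES contrast.

## Evaluation

Decoding pseudo-inverts the encoding matrix, so per-vessel SNR efficiency
is $1/(\sqrt{n_{cycles}}\,\lVert \mathrm{pinv}(A)_{j\cdot}\rVert_2)$,
normalized so an ideal ±1 Hadamard scores exactly 1 (the appended
nonselective label cycle is excluded from the default evaluation matrix to
preserve that anchor; a flag includes it). Motion robustness perturbs the
vessel coordinates — not the designed cycles — by a shared Gaussian
translation per repetition (planning-to-scan motion; optional rotations
about the plane center), re-simulates the matrix and averages the mean
efficiency. Because a shared translation rotates each cycle's phases
coherently, the large-motion limit settles near half the baseline
efficiency rather than zero. The duty-cycle study re-designs at RF
intervals 1560/1380/1200 µs and re-simulates the anterior-cerebral-artery
columns with 0/50/100 Hz off-resonance profiles, mirroring the observation
that raising the duty cycle does not necessarily buy SNR efficiency under
off-resonance.

## Decoding

The linear decoder solves $y = A[s; T]$ voxelwise by least squares. With
the generator's signal model (perfusion weight $(1 - A_{cj})/2$ on a tissue
baseline), the physical perfusion amplitude is $-2s_j$; both
parameterizations are returned and noiseless stacks decode exactly. The
territory classifier is a deliberately simplified stand-in for full
Bayesian vessel-decoding frameworks: per voxel it compares the static-only
hypothesis against each single-vessel hypothesis by Gaussian marginal
likelihood, with a flat tissue prior, a zero-mean Gaussian amplitude prior,
and equal hypothesis priors; the posterior probability of the winner is the
confidence, and ties break to the lowest vessel index. The amplitude-prior
SD defaults to the upper 1 % tail of the decoded perfusion images (floored
at the noise SD), which tracks the true amplitude when signal exists,
reduces to the decoded noise scale otherwise, and makes the classifier
invariant to global intensity scaling. The marginal-likelihood Occam
penalty means that at very low SNR voxels fall back to the static class —
the reduced-average study therefore reports the static fractions alongside
the agreement, since two empty maps agree trivially. Mixed supply (two
vessels per voxel) is out of scope. Noise is estimated as a
median-absolute-deviation SD over a background mask (image-corner blocks by
default).

## Synthetic data

`make_vessels()` provides the two deterministic templates (optionally
jittered with a seeded Gaussian); `synthesize_stack()` builds a phantom
with one compact disc territory per vessel on a static background, signal
$\mathrm{tissue} + \mathrm{amp}_j (1 - A_{cj})/2$ per cycle, and Gaussian
noise per signal average. The generator exercises the decoding mathematics
only: it has no transit delays, dispersion, arterial transit artifacts,
partial-volume mixtures, or realistic hemodynamics, so a passing pipeline
demonstrates correct encoding/decoding algebra and classifier behavior, not
in vivo image quality. Default study sizes (24×24×3 voxels, 8 averages,
effective SNR 10) keep the full pipeline under a minute; they are the sizes
used throughout the documentation and tests.

## Known limitations

* Straight vessels only: tortuosity enters solely through the thin-plane
  argument, as in the underlying acquisition design.
* The Fourier matcher optimizes single-frequency cycles against ideal ±1
  targets; the realistic modulation enters at the scoring stage, not inside
  the per-cycle search.
* The decoder's one-vessel-per-voxel assumption under-models border zones
  and collateral flow.
* Off-resonance handling assumes a per-vessel scalar offset; no field-map
  ingestion.
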