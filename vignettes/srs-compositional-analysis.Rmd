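---
title: "Compositional analysis of hyperspectral SRS images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of hyperspectral SRS images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsfa)
```

## The problem

Stimulated Raman scattering (SRS) microscopy images live cells label-free:
the signal at each pixel is proportional to the concentration of molecules
whose vibrational bands fall at the probed wavenumber. In the C–H stretch
region (~2800–3050 cm⁻¹) proteins and fatty acids are bright but spectrally
overlapping, so a hyperspectral stack — a full intensity-versus-wavenumber
spectrum at every pixel — must be decomposed into per-chemical concentration
maps before anything quantitative can be said about fatty-acid production in
engineered microbes. `srsfa` implements that decomposition and the
downstream composition analytics: saturated chain-length estimation,
unsaturation quantification, and single-cell/colony production statistics.

## Pixel-wise sparse unmixing

The stack is reshaped to a pixel-by-wavenumber matrix $D \in
\mathbb{R}^{N_xN_y \times N_\lambda}$ and modeled as $D = CS + E$, where the
rows of $S \in \mathbb{R}^{K \times N_\lambda}$ are reference spectra of $K$
pure components, $C$ holds the per-pixel concentrations and $E$ is noise.
Because SRS intensity is linear in concentration, each pixel $i$ is an
independent regression; to suppress crosstalk between overlapping references
we solve the non-negative LASSO

$$\hat c_i = \arg\min_{c \ge 0} \tfrac12 \lVert d_i - cS \rVert^2
  + \beta \lVert c \rVert_1 ,$$

reflecting the observation that a few components dominate any one pixel.
Non-negativity is on by default because concentrations are physical;
`unmix_config(nonnegative = FALSE)` reproduces the unconstrained problem.

**Solver.** Cyclic coordinate descent, vectorized across pixels through the
Gram matrix $G = SS^\top$, with a fixed component order (deterministic, no
random initialization). A pixel stops iterating when its objective decrease
per sweep falls below `tolerance * (1 + |objective|)` (default `1e-8`);
frozen pixels leave the working set, which makes the slowly converging tail
on nearly collinear references cheap. After the descent, every pixel gets a
KKT *polish*: the optimality system is solved exactly on the pixel's active
set, coordinates that cross zero are dropped and the worst violator of the
Karush–Kuhn–Tucker conditions is added until the conditions hold; the
polished solution is kept only if it improves the objective. The polish
matters because chain-length references are strongly correlated and plain
coordinate descent can stall far from the per-pixel optimum.

**Intensity normalization.** Before solving, the stack is scaled so the
median per-pixel spectral norm equals 1, computed over signal-bearing pixels
(norm above 10⁻³ of the maximum — otherwise an almost empty background sets
the scale). This makes one `beta` transfer across acquisitions with
different gains; maps are rescaled back afterwards.

**Choosing `beta`.** The default `beta = 1e-6` (on the normalized scale) is
the largest order of magnitude at which the ground-truth support of the
bundled synthetic benchmark is recovered after GC-MS scaling. The penalty
acts on coefficients that are inflated by inverse composition shares (a
component carrying 3% of the mass needs a ~33× larger coefficient), so
values that look small are already strongly selective: by `beta = 1e-4` the
whole scene collapses onto the largest-share component. `beta_sweep()`
writes residual/sparsity curves for choosing a value on new data.

## GC-MS augmentation

With eight overlapping references, unbiased per-pixel regression is
unreliable. Bulk-culture GC-MS composition provides a physical prior:
references are area-normalized, then each saturated reference is multiplied
by its species' share of total fatty-acid concentration and the composite
unsaturated reference by the summed unsaturated share
(`scale_references_by_gcms()`). Shares are computed over fatty-acid species
only and sum to one; the protein reference is untouched; zero-share species
stay in the library as inert rows so map indices are stable across strains.
Because the reference spectra carry the shares, all mass-valued summaries
multiply each concentration map by its reference's trapezoidal area
(`ref_auc`), which makes results comparable between plain and augmented
libraries.

## Chain length from the CH2/CH3 band ratio

A saturated fatty acid with $n$ carbons has $n-2$ internal CH₂ groups and
one terminal CH₃, so the ratio of integrated intensity in the methylene
window (2832–2888 cm⁻¹) to the methyl window (2909–2967 cm⁻¹) grows nearly
linearly with chain length. `fit_chain_length_calibration()` regresses chain
length on that trapezoidal AUC ratio over pure standards (C6:0–C20:0) by
ordinary least squares; `chain_length_map()` reconstructs each pixel's
saturated-only spectrum from the maps ($\sum_k C_k S_k$ over saturated
components), forms the ratio and applies the calibration. Predictions are
continuous (a mixed pixel can read 14.9) and clipped to the standards' span
[6, 20]; for comparison with GC-MS they are binned to the nearest even
carbon, with odd-integer midpoints rounding down (14.9 and 15.0 both bin to
C14). Pixels whose saturated total does not exceed a threshold are left
`NA`: low-signal ratio estimates fluctuate strongly. The default threshold
is five times a robust noise estimate (the median absolute deviation of the
saturated-total image, which background pixels dominate in typical fields);
it scales with intensity, so chain-length maps are invariant to global
rescaling of the stack.

Two distribution routes are provided by `chain_length_distribution()`: the
default *mass* route assigns each saturated component's concentration mass
to its chain-length bin (suited to single-cell distributions from the maps
themselves), and a *pixel* route bins the per-pixel average prediction
weighted by saturated mass (the route a per-pixel image analysis would
take). Out-of-range mass is clipped into the terminal bins with a warning.
Agreement with a GC-MS ground truth is scored by the base-2 Jensen–Shannon
divergence (`js_divergence()`), symmetric and bounded in [0, 1].

## Unsaturation

Unsaturated fatty acids share a distinct ≈3000 cm⁻¹ =C–H marker band but
cannot be speciated by chain length, so the library carries one composite
unsaturated reference (a GC-MS-weighted average of the unsaturated species).
`unsaturation_ratio()` reports unsaturated over saturated concentration
mass, each map sum weighted by its reference area. Restrict the ratio to a
sample mask when background dominates the field: with non-negative
regression, noise-only pixels rectify into small positive coefficients that
inflate whole-frame ratios.

## Single-cell and colony analytics

`quantify_regions()` sums protein and fatty-acid signal over the regions of
an integer label mask (masks come from external segmentation; 0 is
background and is always excluded). Two normalizations are always reported:
fatty acid per cell area for single-cell production (cells lie side by
side), and fatty acid per protein for microcolony-level production (protein
accounts for cells stacking). `classify_high_producers()` flags the top 15%
by the headline metric using the linear-interpolation empirical quantile,
ties included; if every region is identical all are flagged, with a warning.
`growth_rate()` is the centered logarithmic derivative of cell length,
$\mu_k = \ln(L_{k+1}/L_{k-1}) / (2\Delta t)$, defined at interior frames
only — exact for exponential growth. Division events appear as negative
spikes (length halving); `mask_divisions = TRUE` blanks rates within one
frame of a >30% length drop. `colony_time_series()` applies the region
quantification frame by frame; missing masks become recorded gaps, never
interpolations.

## The synthetic scene generator

No public SRS stacks of production strains exist, so every stage is
validated against `make_scene()`: rod-shaped cells (default 1–2 µm long,
placed without overlap by rejection sampling) and circular extracellular
droplets on a dark background, 256 × 256 px at 150 nm/px with 40 wavenumbers
over 2800–3050 cm⁻¹ by default. Cells carry protein; a configurable
fraction (default 0.1, emulating the observation that a few cells produce
most of the fatty acid) additionally carry a fatty-acid mixture drawn from
a GC-MS profile; droplets carry the same mixture at higher concentration.
The stack is truth × references plus additive Gaussian noise at a stated
SNR, defined as mean foreground peak signal over noise sigma. Three preset
profiles (`make_gcms_profile()`) emulate the qualitative shapes of known
thioesterases — short-chain dominated (C8:0), mixed with C14:0 largest, and
long-chain with large C14:0/C16:0 — with invented fractions documented as
fixtures.

Reference spectra come from a Gaussian-band model whose parameters live in
`inst/extdata/spectral_model.yaml`, not in code: two CH₂ bands whose
amplitude scales with $(n-2)$, two constant-amplitude CH₃ bands, a broad
protein band at 2930 cm⁻¹, and unsaturated species with a dominant broad
2900 cm⁻¹ band plus the 3000 cm⁻¹ marker (>20% of composite mass above
2985 cm⁻¹). Two modeling choices deserve explanation:

* **Band balance.** CH₂ amplitudes are 0.13/0.06 per methylene so the
  CH₂/CH₃ AUC ratio spans ≈0.4–2.1 across C6:0–C20:0 — short chains
  CH₃-dominant, long chains CH₂-dominant, as real standards are. A much
  steeper balance makes the ratio hypersensitive to noise and is not
  physical.
* **Shape drift.** Band centers and widths drift mildly with chain length
  (CH₂ centers by 1.3/0.5 cm⁻¹ per carbon; CH₃ centers by +1.2/−0.8 inside
  their window). Real standards change shape with chain length, not just
  amplitude; without drift the reference matrix is numerically rank
  deficient (condition number ~10¹³) and per-pixel decomposition is not
  identifiable — no solver could attribute mass to the correct species.
  The CH₃ drift is internal to the methyl window, so window AUCs and hence
  ratio linearity are nearly unaffected.

Growth trajectories are exponential with multiplicative log-normal length
noise and halving at a division threshold; the default rate 0.0115 min⁻¹
(~60 min doubling) is typical of slow growth on minimal-medium pads at
31 °C and makes a division drop (~37%) clearly exceed the 30% detection
threshold at 20-min frames.

**What passing tests do and do not show.** The generator draws spectra from
the same band family used for references, uses ideal geometry (no point
spread, no focal drift, no texture), additive Gaussian noise (no shot
noise, no baseline), and compositions that are homogeneous within a
compartment. Passing the round-trip suites therefore demonstrates that the
algorithms are correct and well-conditioned under the stated model — not
that instrument spectra are fit by Gaussian bands, nor that real cellular
heterogeneity matches the presets.

## Numerical choices

* Integration is trapezoidal on the native (possibly non-uniform) axis;
  window endpoints off-grid are included by linear interpolation, so window
  integrals are exact for piecewise-linear spectra.
* Reference normalization is unit trapezoidal area (the convention the
  GC-MS scaling constants act on).
* Axis mismatches resample the library onto the stack axis by linear
  interpolation; extrapolation is refused.
* Degenerate inputs fail loudly: all-zero spectra, zero fatty-acid shares,
  empty masks, non-uniform frame spacing, zero ratio variance and
  mismatched bins are errors, not silent repairs. A near-zero CH₃ area
  yields `NaN` with a warning, leaving the policy to the caller.
* Problem sizes in the test suite (256² acceptance scenes, 128² sweep
  scenes, 48–64² unit scenes) were chosen so the full suite and the
  acceptance script each complete in minutes on one CPU.

## Known limitations

* Per-pixel speciation of unsaturated chain lengths is out of scope (their
  spectra are too similar); only the total unsaturated pool is estimated.
* The LASSO is solved independently per pixel; no spatial regularization.
* Blind (reference-free) unmixing is not attempted.
* Whole-frame unsaturation ratios are biased upward by non-negative
  rectification of background noise; use a sample mask.
* TIFF storage uses 32-bit samples scaled to [0, 1] with the scale recorded
  in the JSON sidecar (round trips are lossless to float32 precision);
  negative intensities are clipped on write.
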