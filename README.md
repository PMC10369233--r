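# srsfa — compositional analysis of hyperspectral SRS images

`srsfa` quantifies free fatty-acid production in engineered microbes (such
as thioesterase-expressing *E. coli*) from hyperspectral stimulated Raman
scattering (SRS) image stacks in the C–H region (~2800–3050 cm⁻¹). It is
written for microbial metabolic engineers and imaging scientists who have
per-pixel Raman spectra plus bulk GC-MS composition tables and want
single-cell chemical readouts that GC-MS alone cannot give.

## What it computes

**Pixel-wise sparse unmixing.** A stack is modeled as `D = C S + E`, with
`S` the matrix of pure-component reference spectra (protein, saturated
fatty acids C6:0–C20:0, one composite unsaturated reference). Each pixel is
decomposed by a non-negative LASSO,

    ĉ = argmin_{c ≥ 0}  ½‖d − cS‖² + β‖c‖₁ ,

solved by deterministic coordinate descent with an exact KKT polish. The
L1 penalty suppresses crosstalk between overlapping references; bulk GC-MS
composition can be folded in as a prior by rescaling each normalized
reference by its species' share of total fatty-acid mass (GC-MS
augmentation).

**Chain length.** A saturated fatty acid with *n* carbons has *n* − 2
internal CH₂ groups and one terminal CH₃, so the AUC ratio of the CH₂
window (2832–2888 cm⁻¹) to the CH₃ window (2909–2967 cm⁻¹) grows nearly
linearly with *n*. The package fits that calibration on pure standards by
OLS and applies it per pixel to the reconstructed saturated-only spectrum,
yielding chain-length maps, binned distributions, and base-2 Jensen–Shannon
divergences against GC-MS ground truth.

**Unsaturation, cells and growth.** The ≈3000 cm⁻¹ =C–H marker supports an
unsaturated/saturated mass ratio; label masks turn maps into per-cell and
per-colony production tables with top-15% high-producer classification; and
cell-length trajectories give per-frame growth rates via the centered log
derivative μₖ = ln(L₍ₖ₊₁₎/L₍ₖ₋₁₎)/(2Δt).

**Synthetic scenes.** Because no public instrument data exist for these
strains, a first-class generator builds reference spectra (Gaussian-band
model, parameters in `inst/extdata/spectral_model.yaml`), GC-MS profile
presets, hyperspectral scenes of rod-shaped cells and droplets with full
ground truth, and growth trajectories — every stage of the pipeline is
testable end to end.

## Worked example

```r
library(srsfa)

# a mixed-chain producer strain: C14:0 largest component, ~16% unsaturated
prof <- make_gcms_profile("mixed_producer")
lib  <- make_reference_spectra(unsat_weights = prof)   # unit-area references
slib <- scale_references_by_gcms(lib, prof)            # GC-MS augmentation

# chain-length calibration from noisy synthetic standards (SNR 20, 6 reps)
std <- simulate_standard_replicates(snr = 20, seed = 1)
cal <- fit_chain_length_calibration(std$spectra, std$chain_length)
cal
#> Chain-length calibration: n = 9.3797 * ratio + 2.4868 (R^2 = 0.9846)
#>   CH2 window 2832-2888 cm^-1, CH3 window 2909-2967 cm^-1

# synthetic field of view: cells + droplets at SNR 20, then unmix
sc   <- make_scene(scene_spec(nx = 128L, ny = 128L, seed = 1L), lib, prof)
maps <- unmix_stack(sc$stack, slib)

round(chain_length_distribution(maps), 3)
#>    C8   C10   C12   C14   C16   C18
#> 0.095 0.097 0.250 0.338 0.102 0.117
round(gcms_chain_length_distribution(prof), 3)   # generating truth
#>    C8   C10   C12   C14   C16   C18
#> 0.095 0.119 0.190 0.357 0.167 0.071
js_divergence(chain_length_distribution(maps),
              gcms_chain_length_distribution(prof))
#> 0.0135

fg <- sc$cell_mask > 0 | sc$droplet_mask > 0
unsaturation_ratio(maps, region = fg)            # true value is 0.190
#> 0.191

tab <- classify_high_producers(quantify_regions(maps, sc$cell_mask))
sum(tab$high_producer)                           # top 15% of 20 cells
#> 3
```

The recovered distribution has a Jensen–Shannon divergence of 0.013 from
the generating profile (0 means identical, 1 disjoint; values under 0.1
indicate highly similar distributions), the unsaturated/saturated mass
ratio matches the generating 0.190, and 3 of 20 cells are flagged as
high producers.

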