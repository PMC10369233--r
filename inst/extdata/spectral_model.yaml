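# Gaussian-band spectral model for synthetic C-H region (2800-3050 cm^-1)
# SRS references. Band positions honor the CH2 (2832-2888) and CH3
# (2909-2967) integration windows; saturated CH2 amplitudes scale with the
# number of internal methylene groups (n - 2) while CH3 amplitudes are
# constant, and band centers/widths drift mildly with chain length so that
# references of different chain lengths are linearly independent, as real
# standards are. Widths are Gaussian standard deviations in cm^-1.
axis:
  min_cm1: 2800
  max_cm1: 3050
  n_points: 40
saturated:
  # amplitude of each CH2 band is (amplitude * (n - 2)); center and width
  # drift linearly in (n - 6)
  ch2_bands:
    - {center: 2850, center_slope: 1.30, width: 13.0, width_slope: 0.30, amplitude: 0.13}
    - {center: 2880, center_slope: 0.50, width: 9.0, width_slope: 0.10, amplitude: 0.06}
  # CH3 centers/widths also drift with n (both bands stay well inside the
  # 2909-2967 window, so the CH3 AUC -- and with it ratio linearity -- is
  # nearly unaffected while the spectra decorrelate)
  ch3_bands:
    - {center: 2935, center_slope: 1.20, width: 12.0, width_slope: 0.30, amplitude: 1.20}
    - {center: 2960, center_slope: -0.80, width: 9.0, width_slope: -0.15, amplitude: 0.80}
protein:
  bands:
    - {center: 2930, width: 30.0, amplitude: 1.00}
unsaturated:
  species: ["C12:1", "C14:1", "C16:1", "C18:1"]
  # amplitude of each band is (amplitude + amplitude_slope * (n - 12));
  # the ~3000 cm^-1 =C-H marker is common to all unsaturated species
  bands:
    - {center: 2855, width: 14.0, amplitude: 0.25, amplitude_slope: 0.010}
    - {center: 2900, width: 28.0, amplitude: 1.00, amplitude_slope: 0.000}
    - {center: 3005, width: 13.0, amplitude: 1.00, amplitude_slope: 0.000}
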