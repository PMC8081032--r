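---
title: "Backscatter-based visualization of a focused ultrasound beam: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backscatter-based visualization of a focused ultrasound beam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusbeam)
```

## The problem

Focused ultrasound (FUS) therapies deposit energy at a focal spot inside
tissue. If the focus drifts — breathing, probe motion — the therapy hits the
wrong place, so the beam's position must be monitored continuously. The
approach implemented here uses the backscatter of a short, low-power focused
*visualization* pulse, received on the same diagnostic array that transmits
it, to reconstruct the beam's intensity field and overlay it on a coaligned
B-mode image. `fusbeam` implements that reconstruction chain together with a
point-scatterer RF simulator so that every claim can be tested on synthetic
scenes with known ground truth.

## Signal model and the simulator

The received channel signal is modeled as a linear superposition of echoes
from discrete scatterers: each transmitting element `e`, delayed by its
focusing delay, insonifies scatterer `k`, which returns a band-limited
wavelet to every receiving element `j` with total delay
`delays[e] + (d_ek + d_kj) / c`. The wavelet stands in for the *combined*
two-way electromechanical response of the probe; it is a raised-cosine
tapered tone burst referenced to its temporal center, so an echo's envelope
peak lands exactly at its round-trip time of flight. Amplitudes optionally
decay as `1/r` per path (on by default) with an optional cosine element
directivity (off by default — element directivity is not otherwise
specified by the hardware we emulate, and leaving it out keeps the element
model minimal).

Deliberate simplifications, and what they imply for the tests:

* **Point elements, no diffraction impulse responses.** The focal field is
  the superposition of spherical wavelets, which produces a physically
  plausible focus, beamwidth and sidelobe structure, but not the exact
  pressure field of a finite-aperture element. Absolute field values are
  therefore meaningless; every test works with ratios, positions, or dB
  differences.
* **No attenuation, no nonlinearity, no multiple scattering.** Passing
  tests show the *reconstruction algebra* behaves as designed; they cannot
  show how the method degrades with dispersive attenuation or a strongly
  nonlinear therapy beam, which real tissue would add.
* **Discretization.** Sub-sample delays use linear interpolation. The
  implementation accumulates each scatterer's transmit waveform on the RF
  sample grid and then shifts it per receive channel — two linear
  interpolations instead of one per transmit/receive pair. This is an
  interpolation-kernel change (triangular kernels compose), roughly an
  order of magnitude faster, and keeps every echo-timing test within its
  one-sample tolerance.

Scenes are rectangular speckle fields: uniformly placed scatterers with
`N(0, sigma^2)` amplitudes, 15 per −6 dB resolution cell by default — enough
for fully developed speckle, the regime the method assumes. Echogenicity
regions (e.g. a +15 dB disk) multiply in-region amplitudes by
`10^(offset/20)`; wires and pins are single scatterers 40 dB above the
background scale. Scene realization is bit-reproducible from its seed and
leaves the caller's RNG state untouched.

## Beamforming and reconstruction

The delay law, dynamic receive aperture (fixed f-number, default 1), Hanning
apodization over the *nominal* subaperture width (elements beyond the array
edge contribute nothing; no renormalization), and coherence-factor (CF)
weighting follow the standard delay-and-sum formulation; the intensity field
is a sliding axial integral of `|y_CF|^2` over the visualization pulse
length `L`, zero-padded at the deep edge. Image lines sit at the element
positions and the axial step is `c / (2 fs)`, matching the RF sampling.

Choices the formulation leaves open, and what this package does:

* **CF from apodized or raw samples.** The CF is computed from the same
  Hanning-apodized samples that are summed (switchable via `cf_samples`).
  This keeps the weighting consistent with the summed data, at the cost
  that a perfectly coherent wavefront has CF = 2/3 rather than 1 (the
  Hann window's coherence deficit); since every image is max-normalized,
  only CF *contrast* matters.
* **Time origin.** Transmit delays are normalized so the earliest element
  fires at t = 0, and that instant is the shared time origin of simulator
  and beamformer. The focused delay law uses the firing delay of the
  line's own element as its transmit reference.
* **Normalization route.** The echogenicity factor is applied to the
  integrated intensity (`I * L * lambda^2`) rather than to `y_CF`; the two
  are algebraically equivalent and the global factor `L` cancels under
  max-normalization. Gated pixels (smoothed B-mode below `gate_db`,
  default −60 dB re max) keep `lambda = 1`, preserving the formula's shape
  while leaving presumed-noise regions untouched.
* **Kernel sizes.** Wavelength-specified kernels (5.5 × 7 smoothing,
  5.5 × 5 median) convert to pixels by rounding to the nearest odd integer,
  minimum 1; filters pad by symmetric reflection.
* **Envelope detection** uses the per-line analytic signal (FFT Hilbert),
  the standard choice.
* **Degenerate inputs.** CF of a zero-energy subaperture is defined as 0;
  all-zero images refuse log compression and normalization with an error;
  beamforming grids that overreach the record window gather zeros and warn.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `n_elements`, `pitch` | 128, 0.3048 | –, mm | 38.7 mm aperture of the emulated L9-4/38-class probe (pitch assumed; the probe datasheet value is not public) |
| `f0`, `fs` | 5, 20 | MHz | four samples per wavelength |
| `c` | 1540 / 1480 | m/s | phantom–tissue vs degassed-water scenes |
| visualization pulse | 2 cycles | – | short pulse keeps axial resolution of the beam map |
| mock therapy burst | 25 cycles | – | logged in the sequence, never reconstructed |
| plane-wave angles | −18°…18°, 7 | – | compounded B-mode transmits |
| receive f-number | 1 | – | dynamic subaperture width z/f# |
| `gate_db` | −60 | dB | below this, B-mode is treated as noise |
| smoothing kernel | 5.5 × 7 | wavelengths | remove speckle, keep large-scale echogenicity |
| median kernel (MSE) | 5.5 × 5 | wavelengths | suppress speckle variance in comparisons |
| scatterer density | 15 | per res. cell | fully developed speckle |
| point/wire boost | 40 | dB | bright isolated target |

## What the tests establish (and how they are sized)

The test suite runs the full chain on scenes small enough for minutes-scale
runtimes on one CPU, chosen as the smallest sizes at which the relevant
physics is developed:

* **Oracles.** The beamformer is checked against an independently coded
  naive delay-and-sum on ≤8-element, ≤10-scatterer scenes (relative error
  < 1e-6), and simulator echo peaks against a hand time-of-flight
  calculation (±1 sample).
* **Localization.** A point scatterer at the 30 mm transmit focus of the
  full 128-element array reconstructs its intensity maximum within one
  image line laterally and one −6 dB axial length in depth. (The sliding
  integral looks forward, which biases the axial peak shallow by about
  L/2 samples — within that tolerance.)
* **Equalization.** Two scenes sharing one scatterer geometry — uniform
  vs a +15 dB disk spanning the focal zone (12 × 10 mm field, ~21k
  scatterers) — yield raw intensities differing by the full contrast
  (~15 dB) inside the disk, while the normalized, max-normalized
  reconstructions agree to within 1 dB in the regional mean over the disk
  interior eroded by 2 mm. The mean is the right statistic here: pointwise
  dB differences in dim speckle pixels reflect interference between scaled
  and unscaled echo contributions, not the systematic offset the
  normalization removes.
* **Sidelobes.** On a wire in degassed water (sensor noise at 40 dB
  channel SNR relative to the plane-wave wire echo, so the B-mode has a
  realistic noise floor), CF weighting lowers the peak lateral sidelobe at
  the wire depth by tens of dB, and normalization with the gate disabled
  elevates the sidelobe region of the lateral profile by well over 5 dB —
  the elevation is measured as the mean dB level outside the main lobe,
  matching how profile elevation is read off a lateral-slice comparison.
* **MSE direction.** A +15 dB contrast scene compared against five
  homogeneous baseline scenes (8 × 8 mm fields, ~10k scatterers each,
  comparison cropped to the fielded region) has a smaller
  baseline-averaged display-domain MSE after normalization than before.

## Known limitations

* Absolute intensity calibration is out of scope; all outputs are
  max-normalized.
* The simulator's element model is a point source; aperture diffraction,
  elevation focusing, element sub-dicing and frequency-dependent
  attenuation are not modeled.
* No time-gain compensation is applied anywhere; with `1/r` spreading on,
  deep targets are genuinely dimmer.
* The CF's dark-region artifact around bright targets (well known for
  coherence weighting) is reproduced, not mitigated; generalized CF and
  Wiener postfilters are out of scope.
* Real-time operation (GPU kernels, frame-rate guarantees) is out of
  scope; this is a reference implementation for analysis, not an imaging
  loop.
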