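# fusbeam

Visualizing where a focused ultrasound (FUS) therapy beam actually is, using
nothing but the backscatter the beam itself produces. During an FUS therapy
the focus must stay on target while tissue moves; `fusbeam` implements a
monitoring approach in which a diagnostic linear array fires a short focused
visualization pulse, records the per-channel radio-frequency (RF)
backscatter, reconstructs the pulse intensity field of the beam, and overlays
it on a coaligned B-mode image formed from steered plane waves. Because no
hydrophone or therapy hardware is involved, the whole chain runs on a bundled
point-scatterer RF simulator, which makes the method testable end to end on a
desk.

The package is aimed at ultrasound-imaging researchers who want a compact,
fully scripted reference implementation of backscatter-based beam
visualization: the beamformer, the intensity reconstruction, the
echogenicity normalization, and the evaluation metrics, all exercised on
synthetic phantoms (speckle backgrounds, ±dB contrast disks, wire targets).

## Method

For each image line at lateral position $x_c$ (one line per array element),
channel data are delayed by the two-way time of flight

$$\tau(x, z) = \tau_F(x_c) + \frac{z + \sqrt{z^2 + (x - x_c)^2}}{c},$$

where $\tau_F(x_c)$ is the transmit focusing delay of the line's element.
A dynamic receive subaperture of fixed f-number (width $z/f_\#$) is
Hanning-apodized and summed (delay-and-sum, DAS). Each point is weighted by
the coherence factor

$$\mathrm{CF}(x, z) = \frac{\left|\sum_{i=1}^{N} s(x_i, z)\right|^2}
{N \sum_{i=1}^{N} |s(x_i, z)|^2} \in [0, 1],$$

the ratio of coherent to incoherent energy across the subaperture, which
suppresses sidelobes: $y_{CF} = \mathrm{CF} \cdot y$. The beam's intensity
field is a sliding axial integral over the visualization pulse length $L$:

$$I(x, z) = \sum_{i=0}^{L-1} \Delta z \, |y_{CF}(x, z + i)|^2 .$$

Backscatter strength varies with the medium, so $I$ confounds the beam with
local echogenicity. A plane-wave compounded B-mode of the same frame is
envelope-detected, smoothed with a 5.5 × 7 wavelength moving average, and
used to equalize the reconstruction:

$$\lambda(x, z) = \frac{B_{\max}}{B(x, z)}, \qquad
I_{\mathrm{norm}} = I \times L \times \lambda^2,$$

with $\lambda = 1$ wherever $B$ falls below a −60 dB gate (assumed noise).
Evaluation helpers provide the theoretical focal metrics
($R_{-3\,\mathrm{dB}} = 1.028 \lambda f_\#$,
$\mathrm{DOF}_{-3\,\mathrm{dB}} = 7.08 \lambda f_\#^2$), measured widths by
interpolated dB-level crossings, and a display-domain MSE protocol
(10 log10, clip to [−60, 0] dB, 5.5 × 5 wavelength median filter) for
comparing reconstructions across regions.

## Worked example

A +15 dB hyperechoic contrast disk at the 30 mm focus inside a fully
developed speckle background, simulated, reconstructed and normalized:

```r
library(fusbeam)

arr <- make_array()                    # 128 elements, 5 MHz, 20 MHz sampling
cfg <- recon_config(fus_focus = c(0, 30e-3))

spec <- scene_spec(x_range = c(-4e-3, 4e-3), z_range = c(26e-3, 34e-3),
                   regions = list(region_disk(c(0, 30e-3), 2.5e-3, 15)))
rec <- fus_pipeline(spec, arr, cfg, seed = 7)
print(rec)
#> <fus_recon> das-cf + echogenicity normalization, 312 x 128 grid
#>   intensity peak at x = -0.46 mm, z = 31.32 mm

max(rec$cf_map$values)   # peak coherence factor (Hann-apodized): 0.67
max(rec$lambda$values)   # strongest un-gated equalization factor: 194.9

pk <- arg_max_image(rec$intensity_norm)
lat <- lateral_profile(rec$beam_db, pk["z"])
measure_width(lat$values, lat$x * 1e3, -6)
#> [1] 0.7469  # measured -6 dB transmit-receive beamwidth, mm
```

The reconstructed beam peaks within half a millimeter of the configured
focus; the measured −6 dB transmit–receive beamwidth (0.75 mm) is wider than
the one-way theoretical −3 dB width for this geometry (0.25 mm at
f# = 0.78), as expected for a two-way, speckle-limited measurement. The
`rec$overlay` array (beam in a warm colormap over the grayscale B-mode) can
be written with `make_overlay(..., path = "overlay.png")`.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fusbeam.R", package = "fusbeam"))')" \
    demo --config inst/extdata/demo_config.yaml
```

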