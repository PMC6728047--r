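# halometry

Morphometry of asymmetric neurite outgrowth from ganglion explants.

Explants of embryonic ganglia cultured on an adhesive substrate extend a
radial corona of neurites — a *halo*. Halos are frequently asymmetric: one
side carries longer, sparser, thinner neurites, the opposite side shorter,
densely packed neurites with club-like endings. Strikingly, neighboring
explants in the same dish tend to point the same way, while dissociated
single neurons show no such organization. `halometry` implements the
quantitative toolkit for this phenomenon, for cell biologists and
image-analysis folk who want the measurements reproducible end to end:

* **Asymmetry index.** Ellipses with the same centroid, area and second
  central moments as the traced halo and core outlines (the ImageJ
  "Fit Ellipse" convention) are fit to both contours; the index is
  `100 * |(c − h)·u| / a` — the core-center displacement projected on the
  halo's major axis `u`, as a percent of the semi-major length `a`. 0% =
  core at the halo center; 100% = core at the end of the major axis.
* **Blinded orientation protocol.** Round-field cropping, per-explant
  random rotation, equatorial-line scoring by an automated morphology
  surrogate (plus optional simulated noisy observers), decoding, and
  circular averaging.
* **Circular statistics.** Mean resultant length, the Rayleigh test of
  circular uniformity (`Z = n r²` with the standard small-sample series
  p-value), von Mises sampling and concentration estimation.
* **Spectral anisotropy.** Organized parallel neurites concentrate 2D
  Fourier power perpendicular to the neurite direction; the anisotropy
  score (power-weighted axial resultant of spectral angles) separates
  organized halo crops from unorganized dissociated-neuron fields, with a
  null-calibrated threshold.
* **Synthetic dishes.** A seeded generator renders explant dishes with
  known per-explant asymmetry and orientation, dish-level co-orientation
  (von Mises), dissociated and re-aggregated scenarios, and ground-truth
  tables — so every stage of the chain is testable without microscope data.

## Worked example

Simulate a dish of six co-oriented explants and run the full pipeline
(segment → fit ellipses → asymmetry index → orientations → Rayleigh test →
cohort summary):

```r
library(halometry)

cfg <- dish_config(n_explants = 6, coorientation_kappa = 30, rng_seed = 42)
report <- run_pipeline(cfg, rng_seed = 1)
report
#> cohort_summary: 6 explants (6 measured, 0 excluded)
#>   fraction with asymmetry >= 15%: 1.000
#>   mode bin midpoint: 32.5%
#>   asymmetry vs core area: spearman = NA (p = NA)
#>   asymmetry vs halo area: spearman = 0.943 (p = 0.0167)
#>   per-dish Rayleigh co-orientation:
#>   dish_id n         r mean_direction_deg      p_value
#> 1       1 6 0.9747764           340.9143 0.0002678663
```

All six explants were rendered at amplitude 0.35 (true index 35%), and the
measured mode bin sits at 32.5%: the traced outline is slightly
conservative on the ragged long side. The Rayleigh mean resultant length
r = 0.975 over the six recovered orientations rejects uniformity
(p ≈ 3e-4): the dish is co-oriented. (The core-area correlation is `NA`
here because every simulated explant shares the same core template — zero
variance.)

A single explant, measured explicitly:

```r
ex  <- render_explant(explant_params(asymmetry_amplitude = 0.35,
                                     orientation_deg = 60),
                      rng_seed = 7, noise_sd = 0)
seg <- segment_explants(ex$image)
m   <- measure_dish(seg)
attr(m, "measurements")[["1"]]
#> asymmetry 31.1%, long neurites toward 61.6 deg
```

The index (31.1%) and long-neurite direction (61.6° vs the true 60°) come
from the halo and core ellipse fits alone. `plot_asymmetry_histogram()` and
`plot_orientation_polar()` draw the cohort histogram and the per-dish polar
diagram; `write_report()` persists the full bundle (CSV tables + JSON
summary + 16-bit TIFF) byte-reproducibly.

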