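---
title: "Quantifying asymmetric neurite outgrowth: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric neurite outgrowth: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halometry)
```

## The measurement problem

Ganglion explants cultured on an adhesive substrate extend a radial corona
of neurites — a *halo*. Halos are often asymmetric: neurites on one side are
longer, sparser and thinner, while the opposite side carries shorter,
densely packed neurites with flattened club-like endings. Neighboring
explants in a dish frequently point the same way (*co-orientation*), while
dissociated single neurons do not. `halometry` provides the measurement
chain needed to quantify this: a percent asymmetry index, an orientation for
each explant, a within-dish co-orientation test, and a spectral detector of
organized parallel growth — plus a seeded synthetic image generator so every
stage has a controlled test surface.

## The asymmetry index

Ellipses are fit to the halo and core outlines by the method of moments: the
fitted ellipse has the same centroid, area and second central moments as the
filled polygon (the convention of ImageJ's "Fit Ellipse"). Polygon moments
are evaluated exactly with Green's theorem, and the axes are rescaled so the
ellipse area equals the polygon area.

With halo ellipse center $h$, unit major-axis direction $u$ and semi-major
length $a$, and core ellipse center $c$, the index is

$$\mathrm{asym} = 100\,\frac{|(c-h)\cdot u|}{a}\,,$$

the displacement of the core center *projected on the major axis*, as a
percent of the distance from the halo center to the nearer end of the major
axis. A centered core gives 0%; a core at an end of the major axis gives the
theoretical maximum of 100% (a halo growing from one side only, not seen in
practice). Displacement along the minor axis contributes nothing, matching
the observation that cores are offset along the major axis but not the minor
axis. The long-neurite orientation is the major-axis direction *away* from
the core displacement, since the core sits nearer the short-neurite side.
The index is invariant under rigid motions and uniform scaling (covered by
property tests).

Degenerate cases: contours with fewer than three vertices or collinear
vertices are errors; halos with axis ratio below 1.02 are measured but
flagged `low_confidence`, because the major-axis direction of a
near-circular ellipse is numerically unstable; a core center projecting
beyond the major-axis end is an error rather than an index above 100.

## The synthetic generator: what it emulates

`render_explant()` draws a bright core disk and radial neurites out to a
halo boundary; `render_dish()` lays out several explants in a dish, draws
their orientations from a von Mises distribution around a per-dish mean, and
flags the layout geometry (edge proximity, halo overlap) that the analysis
must exclude.

The halo boundary is an **offset ellipse**: semi-major
$\alpha = r_\mathrm{core} + L_0$ along the orientation axis, center
displaced by $\delta = a^\ast \alpha$ along that axis (where $a^\ast$ is the
`asymmetry_amplitude`), semi-minor $\alpha(1 - 0.45\,a^\ast)$. The core sits
at the neurite origin, i.e. offset from the halo-ellipse center along the
major axis only, so the ground-truth index is exactly
$100\,a^\ast$. To first order the implied neurite-length profile is the
cosine modulation $L(\theta) \approx L_0 (1 + a^\ast
\cos(\theta-\theta_0))$. The second-harmonic (elongation) component is
essential, not cosmetic: a pure first-harmonic boundary (a limaçon) has a
*near-circular* moment ellipse whose major axis is perpendicular to the
core offset, so the projection-based index would evaluate to roughly zero at
any amplitude. Real halos show elongation and core offset together along
the same axis, which is the geometry reproduced here.

Morphological cues are co-located with the short-neurite side: club-ending
disks are drawn only there, and density thinning (`density_contrast`)
removes neurites from the long side. Thinning uses a low-discrepancy
(golden-ratio) sequence so the dropped neurites are evenly interleaved:
independent Bernoulli thinning carves clustered gaps into the halo that no
plausible closing radius bridges, which is a rendering artifact rather than
a biological feature. Neurites are drawn with ~2 px caliber (two sub-pixel
strands), which also keeps the rasterized line 4-connected across diagonal
steps.

Default parameters (all lengths in pixels; the source images carry no
stated pixel scale, so synthetic dimensions are arbitrary and only ratios
matter): core radius 28, mean neurite length 90, 240 neurites, length
jitter CV 0.08, density contrast 0.5, club radius 2.5, read noise SD 0.01
on a 0.06 background. Amplitude defaults to 0.35, the most common value in
real cohorts. Dish-level co-orientation defaults to von Mises
$\kappa = 20$; $\kappa = 0$ yields uniform orientations. Each dish draws
its own mean orientation independently — co-orientation is a within-dish
phenomenon only.

What the generator does *not* emulate: individual growth-cone dynamics,
guidance cues or any mechanism of the asymmetry; non-neuronal (glial)
carpets; stain chemistry (noise is Gaussian read noise plus an optional
linear background gradient). Passing tests therefore demonstrate that the
measurement chain is correct on images with the stated geometry and cues,
not that it is robust to every artifact of real micrographs.

Reproducibility: a dish is a pure function of its configuration. The dish
seed drives layout and orientation draws; each explant renders under a
deterministic child seed (`seed * 48271 + 1103 * i mod 2^31 - 1`), so
identical configurations give bit-identical images and ground truth.

## Segmentation

The manual outlining step is automated as: normalize intensity and polarity
(silver-stain-like images are inverted; auto-detection calls the majority
phase the background), Otsu threshold (manual override available),
morphological closing with a disc (default diameter 19 px) to bridge the
gaps between neurites, hole filling, and connected-component labelling.
Components of at least `min_area` px² are halos; within each halo the core
is the largest component above a second Otsu threshold computed on the
halo's *foreground* intensities (computing it on all interior pixels would
split background from foreground instead of neurites from core). Contours
are traced along boundary pixel centers, so areas and radial extents carry
half-pixel granularity.

Exclusion flags mirror the analysis rules for real dishes: explants near
the dish edge (within `edge_margin`, when dish geometry is supplied),
touching the image border, lacking a detectable core, or sharing a halo
component with a neighbor (merged halos are excluded from quantification,
not measured). A threshold that splits the image roughly in half is treated
as "no figure/ground structure" and returns an empty result with a warning
rather than a spurious blob.

## The blinded orientation protocol

Morphological asymmetry is scored without knowledge of the true
orientation: each explant is cropped in a round field (eliminating
square-frame cues), rotated by its own uniform random angle (bilinear
interpolation; the disk mask is re-applied after rotation so no frame cues
leak), scored, and decoded by subtracting the applied rotation.
Orientations are treated as directions mod 360°, not axes mod 180°: the
protocol resolves the sense of the equatorial axis by asking which side is
the sparser one. An axial mode (angle doubling) remains available in
`rayleigh_test(axial = TRUE)` for sensitivity analyses.

The human observer is replaced by `morphology_orientation()`: around the
core center the halo annulus is profiled in 1° bins — radial extent from
the halo contour (the contour is continuous around the rim; per-bin
foreground pixels would leave holes in thinned sectors) and areal density
of stained pixels within each bin's own reach. For each candidate direction
on a 1° grid the annulus is split into two half-disks, and the direction
maximizing the combined contrast (greater extent *and* lower density ahead)
is returned. Below a relative-modulation floor (`min_contrast = 0.08`,
comfortably above the jitter noise floor of symmetric renders) the halo is
declared unoriented (`NA` sentinel). The 1° grid is far below
observer-level precision and costs little at these image sizes.
`simulated_observer()` adds von Mises noise around the measured angle to
exercise decoding and circular averaging at configurable observer
reliability; real inter-observer noise has no empirical anchor, so
`noise_kappa` is a free simulation parameter.

## Circular statistics

`rayleigh_test()` tests uniformity of directions via the mean resultant
length $r$: $Z = n r^2$ and the standard small-sample series

$$p = e^{-Z}\Big[1 + \frac{2Z - Z^2}{4n}
      - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\Big],$$

clamped into (0, 1]. The series is accurate to a few times $10^{-3}$ in the
regimes used here (it is guarded by a Monte-Carlo resampling oracle in the
tests) but undershoots zero for extreme concentration ($Z$ close to $n$),
where the clamp takes over; decisions there are unaffected because the
p-value is tiny on either route. Von Mises sampling uses Best–Fisher
rejection; concentration estimation inverts $A(\kappa) = I_1/I_0$ by
bisection on the exponentially scaled Bessel ratio, truncating to 0 below
$r = 10^{-8}$ and returning `Inf` at $r = 1$.

One ambiguity is documented rather than resolved: parametric p-values for
co-orientation could also be derived under a von Mises alternative. The
package defaults to the standard Rayleigh uniformity test (the axial-mode
flag covers the axis-vs-direction reading); a likelihood-ratio variant
would need assumptions the data cannot check at $n \le 8$ explants per
dish.

## Spectral anisotropy

Organized parallel neurites concentrate spectral power in the direction
perpendicular to the neurites; unorganized growth spreads power over all
spectral angles. `spectral_orientation()` mean-subtracts the field, applies
a radial raised-cosine taper (the sharp frame border would otherwise
imprint an axis-aligned cross on the spectrum), computes the 2D power
spectrum, and summarizes power within a radial band (default 0.05–0.45 of
Nyquist; low frequencies are excluded so the broad core blob and
illumination do not dominate) as an axial circular distribution: the
anisotropy score is the power-weighted mean resultant length of doubled
spectral angles, and the dominant neurite orientation is the dominant
spectral angle plus 90°.

Calibration has a subtlety: the score of pure white noise shrinks with
pixel count, but a field of $N$ discrete neurite segments has score of
order $1/\sqrt{N}$ *however isotropic the orientations are*. A
dissociated-neuron field is therefore never "as isotropic as" white noise
in this statistic. `anisotropy_threshold()` consequently offers two nulls:
`"white_noise"` for judging raw noise, and `"dissociated"` — an isotropic
random-segment field at the generator's default density — as the
unorganized-growth null. Scene classification (is this crop organized?)
uses the dissociated null at its 0.99 quantile; organized halo crops score
several-fold above it, so the margin does not depend on fine-tuning.

## Cohort reporting

`summarize_cohort()` bins the asymmetry index in 5-point bins (fine enough
to localize the distribution mode), reports the fraction of explants at or
above configurable thresholds (default 15%), and correlates asymmetry with
core and halo areas using Spearman rank correlation by default — the area
scattergrams are strongly non-Gaussian — with Pearson behind a flag.
Per-dish Rayleigh results are attached when orientations are supplied.
Analyses of asymmetry versus culture duration or growth-factor treatment
are deliberately out of scope: the summary table carries the columns any
stats package needs to run such models downstream.

`run_pipeline()` composes simulate → segment → measure → orient → test →
summarize, records per-stage failures as exclusions rather than aborting,
and persists a report bundle (CSV tables, JSON summary) that reruns
byte-identically under the same seed.

## Problem sizes and tolerances used by the test suite

The suite exercises the full chain at desk scale: single explants render at
~400 px, dish simulations use 6–8 explants with reduced explant sizes,
parameter recovery spans amplitudes 0.1–0.6 × 8 orientations on noise-free
renders (orientation RMS error under 10°, mean amplitude error under
5 points), Rayleigh calibration uses $10^4$ uniform samples at $n = 6$
(type-I error within 0.04–0.06) with power checked at $\kappa = 10$, and
the series p-value is cross-checked against $10^6$ uniform-null draws. The
oracles are independent routes: a direct least-squares conic fit against
the moment ellipse fit, pixel-count rasterization against shoelace areas,
and polar-moment integration of the exact halo boundary against the full
render-segment-measure chain.

## Known limitations

* The measured index runs ~3–5 points below the generator's ground truth on
  fully cue-laden renders: boundary jitter, club endings and thinning make
  the traced outline conservative on the long side, much as an irregular
  halo border challenges manual tracing. Noise-free, jitter-free renders
  recover the analytic oracle to well under a point.
* Segmentation assumes bright structures on a darker background after
  polarity normalization, a single global threshold, and halos that close
  under a disc of the configured diameter; densely merged cultures are
  flagged and excluded rather than split.
* The morphology scorer uses the same two cues the generator renders
  (extent and density). On real images with other morphological cues
  (neurite straightness, fasciculation) it is a surrogate, not a validated
  replacement for human scoring; the protocol machinery (crop, rotate,
  decode, average) is independent of the scorer.
* Per-neurite measurements (lengths, counts, tracing) are out of scope; the
  index is purely ellipse-geometric.
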