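---
title: "Models and methods behind axonmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axonmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmorph)
```

# The measurement problem

Coherent anti-Stokes Raman scattering (CARS) microscopy tuned to the
symmetric CH2 stretch (~2845 cm^-1) images the lipid-rich myelin sheath
directly: a myelinated fiber cross-section appears as a bright annulus
around a dark axon lumen, and unmyelinated axons are invisible. Given a
3-class semantic segmentation of such an image (background / myelin /
axon), axonmorph computes the standard morphometric description of the
fiber population:

* **inner (axon) diameter** `a`: the diameter of the circle with the same
  area as the axon pixel set, `a = 2 sqrt(N_axon * p^2 / pi)` for pixel
  pitch `p`;
* **outer diameter** `A`: the same area-equivalent diameter over the union
  of the axon and myelin pixels of one fiber;
* **myelin thickness** `m = (A - a) / 2` and **g-ratio**
  `g = a / A = a / (a + 2 m)`;
* **eccentricity** of the best-fit ellipse (normalized second central
  moments), `e = sqrt(1 - (minor/major)^2)`;
* **myelinated fiber density**: fibers per mm^2 of imaged area.

Instance separation precedes measurement: axon instances are 8-connected
components of the axon class, and each myelin pixel is assigned to its
nearest axon component by a watershed-style flood restricted to myelin
pixels (multi-source breadth-first growth, ties to the smallest label, so
results are platform-independent). Myelin with no reachable axon is
discarded and counted. For fiber populations whose annuli do not touch,
this growth can only reach a fiber's own lumen, so the separation is exact
by construction.

# Quality control

Automated segmentation produces artifacts, so records pass a multicriteria
screen before aggregation:

| rule | default | boundary semantics |
|------|---------|--------------------|
| g-ratio | `0 < g < 1` | exclusive: `g = 1` means zero myelin, implausible for a CARS-visible fiber |
| diameter | `a >= 0.335` um | the printed threshold is kept verbatim; at 0.166 um/px it corresponds to ~2 px, below which partial-volume effects dominate (note 2 x 0.166 = 0.332, not 0.335 — we follow the printed value) |
| eccentricity | `e <= 0.9` | the area-equivalence model assumes near-circular profiles |

Every removed record carries *all* the rules it violated. Screening is an
order-preserving partition, idempotent, and monotone in each threshold;
these properties are tested directly.

# Population statistics

Kept records are stratified into half-open diameter bins
`[0.335, 0.5), [0.5, 0.75), ..., [1.5, 1.75), [1.75, Inf)`. The first-bin
edge equals the QC floor and the 0.25-um laddering ends in an open-ended
bin. Summaries use arithmetic means and sample SDs (n-1); correlation
structure is reported as pairwise Pearson r with two-sided p-values, plus
ordinary-least-squares R^2 for thickness ~ diameter and g ~ diameter.
Two-region comparisons are descriptive per-bin tables (no hypothesis
test); empty bins are `NA`, never zero.

# The synthetic generator

No public CARS image corpus with ground truth exists at this geometry, so
the package ships a seeded generator whose defaults (`uf_reference_preset()`)
emulate the deep uncinate-fasciculus white-matter population that motivated
the pipeline: post-screening mean axon diameter 0.93 +/- 0.54 um with a
0.37 um floor, mean myelin thickness ~0.48 um, mean g-ratio ~0.47, and
myelinated fiber density 844.36 fibers/mm^2, rendered at 500 x 1000 px and
0.166 um/px, 8-bit.

**Diameter law.** Diameters are lognormal (right-skewed, positive support)
truncated below at the floor. Because the published mean +/- SD describes a
*screened* population, the lognormal parameters are solved numerically so
that the *post-truncation* moments match the requested mean and SD (with no
floor this reduces to the closed-form moment matching
`sigma^2 = log(1 + cv^2)`, `mu = log(mean) - sigma^2/2`). Sampling is by
inverse CDF on the truncated quantile range, so counts are exact and draws
are reproducible.

**Thickness and g-ratio.** Myelin thickness is modeled as linear in
diameter with Gaussian noise, `m = 0.3672 + 0.1243 d + N(0, 0.1371)` um,
clipped so the implied g stays in (0.05, 0.95); g then follows from the
identity `g = d / (d + 2m)` exactly. A g-linear model was considered and
rejected: matching the published mean thickness (0.48 um) together with the
published mean g (0.47) forces a g-vs-d slope so steep that systematic
thickness becomes non-monotone in diameter, destroying the expected
positive diameter-thickness correlation. The three thickness constants were
calibrated once against the published means and the qualitative correlation
structure (r(d, m) > 0, r(m, g) < 0, R^2(g ~ d) near 0.47) and then frozen;
at those constants the population attains mean g 0.4745, mean thickness
0.483 um, r(d, m) ~ +0.44, r(m, g) ~ -0.30 and R^2(g ~ d) ~ 0.43. The
implied population SD of g (~0.12) is somewhat above the published 0.094;
matching it as well is not possible under a linear-Gaussian model with the
constraints above.

**Geometry.** Fibers are concentric ellipses sharing an axis ratio (drawn
uniformly from [1.0, 1.7], eccentricities up to ~0.81, inside the 0.9
screen; `oblique_stress_preset()` exceeds it deliberately) and orientation.
The inner ellipse has area `pi (d/2)^2` and the outer `pi ((d+2m)/2)^2`, so
the *area-equivalent* inner and outer diameters equal `d` and `d + 2m`
exactly and measured g is unbiased for elliptical fibers; the ring is
consequently thinner along the minor axis, as oblique sections are.
Placement is rejection sampling with the circles circumscribing the outer
ellipses kept pairwise disjoint with a 1-px guard (a conservative
sufficient condition for disjoint envelopes); unplaceable fibers are
dropped and counted. Rasterization assigns a pixel to a region iff its
center lies inside the analytic boundary.

**Image formation.** Classes are painted at three mean intensities
(background 20, lumen 60, myelin 200 of 255 — CARS contrast is driven by
lipid CH2 density, so the sheath dominates), bright solid disks emulate
concurrent two-photon artifact spots (they corrupt the image only, never
the truth masks), then Gaussian PSF blur (sigma 1 px), additive Gaussian
noise (SD 8), clipping and 8-bit quantization. This is deliberately *not* a
physical CARS image-formation model: no coherent speckle, no nonlinear
intensity response, no depth effects. Passing tests on synthetic data
therefore validate the measurement pipeline, not any segmentation model's
performance on real tissue.

**Orientation and eccentricity defaults** are documented choices, not
published values — no orientation or eccentricity distribution is reported
for this tissue.

# Segmentation and its evaluation

The deep-learning segmenter whose outputs motivated this pipeline is out of
scope (its contribution is trained weights); the package instead (a) reads
externally produced masks in the common 0/127/255 PNG encoding, and (b)
provides a deterministic classical baseline (`baseline_segment()`):
Otsu or fixed thresholding for myelin, hole-filling for the axon class
(the myelin-first convention used by human annotators), suppression of
bright components with no interior hole (solid artifact spots), and
optional morphological opening/closing — off by default because sheaths
only 2-4 px thick do not survive even a 1-px opening. Dice and IoU
evaluators define the both-empty case as 1.0 and satisfy
`Dice = 2 IoU / (1 + IoU)` identically.

# sf-CARS optics

The optics module covers the spectral-focusing design arithmetic, all for
Gaussian pulses with time-bandwidth product 0.441 (sech^2 available via
the `tbp` argument):

* Raman shift `1e7 (1/lambda_p - 1/lambda_s)` cm^-1; the 805/1045 nm pair
  gives 2853 cm^-1, within 0.3% of the 2845 cm^-1 CH2 target.
* Transform-limited duration `tau = tbp / (c dlambda / lambda^2)`:
  9.0 nm at 805 nm gives ~106 fs.
* Glass-rod group delay dispersion `|phi2| = D lambda^2 L / (2 pi c)`,
  sign carried separately (the rod configuration is negatively chirped);
  103 ps/nm/km over 19.6 cm at 805 nm gives ~6.9e3 fs^2.
* Gaussian chirp law `tau_out = tau sqrt(1 + (4 ln2 phi2 / tau^2)^2)`.
  With the rod parameters above this stretches the pump ~2.0x. The
  published stretch for this configuration is 2.44x (250 fs); the standard
  law does not reproduce that number from the printed bandwidth, rod length
  and dispersion coefficient — possibly a different duration convention or
  unaccounted dispersive elements. The discrepancy is documented rather
  than tuned away, and the package's own validation treats only the ~105 fs
  transform limit as a target.
* Spectral FWHM with a linear baseline fitted to the flanks outside the
  analysis window (the CH region 2800-3100 cm^-1 by default) and
  half-maximum crossings found by linear interpolation.
* Delay-scan cross-correlation `I(tau) ~ integral I_p(t)^2 I_s(t - tau) dt`
  (two pump photons, one Stokes), trapezoid-integrated on a dense grid and
  checked against the closed-form Gaussian convolution.

# Numerical and design choices

* **Determinism.** Every stochastic step takes a seed; the RNG state is
  restored afterwards. Identical seeds give bit-identical images, masks and
  tables. Multi-image runs derive per-image seeds as `seed + 3 i`.
* **Connectivity.** 8-connectivity throughout (thin diagonal lumens);
  component labels are ordered by smallest pixel index.
* **Tie-breaks.** Watershed ties go to the smallest instance label.
* **Degenerate inputs.** Zero-area populations are empty tables, not
  errors; blank images segment to all-background; n < 2 summaries report
  `NA` spreads; records with non-finite metrics are screened out as
  `invalid`.
* **Eccentricity** is computed on the axon region by default (the lumen is
  the better-conditioned ellipse); `eccentricity_on = "fiber"` switches to
  the whole fiber. Border-touching fibers are measured and flagged but
  retained, and density counts all retained fibers.
* **Instance maps on disk** are 8-bit PNGs when there are at most 255
  instances per image (always true at the reference density of ~12 fibers
  per 500 x 1000 field) and plain TSV matrices otherwise.
* **Problem sizes.** The package's end-to-end validation uses 20 reference
  images (~235 kept fibers over 0.276 mm^2), the scale at which the
  published per-region population (n = 234) was characterized; generator
  moment tests use 5e3-2e4 draws.

# Known limitations

* The synthetic image model is geometric, not physical; segmentation
  scores on it say nothing about real-tissue performance.
* The thickness model is linear-Gaussian; real populations are not, and the
  generator cannot match every published second-order statistic at once
  (see the g-SD note above).
* Only 2-D cross-sections are modeled; no 3-D volumes, no unmyelinated
  axons, no pathology metrics (axonal swelling, sheath splitting).
* Density is computed post-QC over the full imaged area.
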