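---
title: "Methods: segmenting the cornea-scleral lens relationship in AS-OCT images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting the cornea-scleral lens relationship in AS-OCT images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(octvault)
```

## The problem

A scleral contact lens (SCL) rests on the sclera and vaults over the cornea;
the fluid-filled clearance between the lens's inner surface and the corneal
surface — the *vault* — is the quantity a fitter monitors to judge comfort
and avoid corneal touch. Anterior-segment OCT (AS-OCT) B-scans show the lens
as a thin bright band and the corneal tissue as a thicker, brighter band.
Depending on where the scan crosses the eye, three situations occur:

* **central** scans — the lens clears the cornea everywhere (three visible
  boundaries: lens outer limit, lens inner limit, corneal surface);
* **lateral** scans — the clearance closes progressively toward the limbus;
* **extreme** scans — the lens has landed on the tissue and merges with it
  optically (two-layer images).

`octvault` segments these boundaries fully automatically, classifies each
scan by its visible layer count, and measures the per-column clearance under
three point-correspondence paradigms. Every stage is testable without
clinical data through a synthetic phantom generator with exact analytic
ground truth.

## Pipeline

`oct_segment()` chains four phases.

**Preprocessing.** A `median_k` x `median_k` median filter, then
Perona-Malik anisotropic diffusion with exponential conduction
`g(d) = exp(-(d/kappa)^2)` on the 4-neighbour stencil. The antisymmetric
flux form with replicated (Neumann) boundaries preserves the global mean
exactly and is non-negativity preserving for `dt <= 0.25` (defaults:
15 iterations, `kappa = 30` gray levels, `dt = 0.2`). The dominant edge
orientation is then estimated and, when it exceeds a 5 degree dead-band,
the image is rotated to bring the layers horizontal (bilinear resampling on
an expanded canvas; `rotation_transform()` gives the exact point mapping
used to carry curves between frames). A white top-hat with a 21 px square
structuring element removes broad background and lifts the thin bands.

*Orientation estimate.* The gradient-orientation histogram is built with
squared-magnitude weights, but the majority direction is read off as the
circular resultant in doubled-angle space rather than as the histogram
mode. A uniformly curved band has slope density proportional to
`sec^2(theta)`, which peaks at the band's *steepest flanks*; the mode of
such a histogram therefore reports the flank angle, not the tilt, whereas
the doubled-angle resultant is exact for any slope distribution symmetric
about the tilt. On phantoms the estimate recovers tilts of 0-40 degrees
within about 2.5 degrees in all three scenarios.

**Preliminary localization.** Canny edges (Sobel aperture `canny_kernel`,
hysteresis thresholds `canny_low`/`canny_high` on the raw Sobel magnitude)
feed a per-row edge count profile. Rises of this profile mark rows where a
boundary accumulates; they are detected with a 3-row lagged forward
difference against an adaptive `mean + 2 sd` threshold — the lag absorbs
the +-2 rows over which speckle jitter spreads a boundary's edge pixels —
and accepted only when the edge support below the rise spans at least 20%
of the content width (rotation padding carries no evidence and is
excluded). The first three accepted areas, top to bottom, are the candidate
searching rows; the candidate whose band below shows the largest intensity
standard deviation (bright tissue plateau against dark background: "the
most significant variations") becomes the cornea row, the topmost remaining
one the lens outer limit.

Each limit is then traced pixel by pixel from a seed edge point, one column
at a time in both directions, with three criteria: (1) *artifact
rejection* — a candidate needs at least 3 edge pixels in its 5x5
neighbourhood and a local intensity maximum above the image's Otsu level;
(2) *smoothness* — among surviving candidates inside the
`loc_window_up`/`loc_window_down` window, the one closest to the
theoretical point extrapolated from a least-squares line over the last 10
traced columns wins; (3) *gap crossing* — unsupported columns continue
along the current orientation and are re-interpolated linearly once the far
side is found; more than `max_extrapolation_cols = 30` consecutive
unsupported columns terminate the trace (trailing unsupported columns are
trimmed).

The lens inner limit is recovered below the outer limit as the first
sufficiently negative vertical intensity change (threshold
`inner_grad_thresh = 10` gray/px, searched above the cornea when one is
traced); columns without a drop reuse the running median band width and are
flagged `extrapolated`. If the inner limit stays within `merge_dist_px = 2`
of the cornea over more than 80% of shared columns — or if almost no
genuine drop exists — the two are the same boundary and the image is a
two-layer scan. The fraction of columns with a *traced* inner limit more
than 2 px clear of the cornea is kept as a continuous confidence score; it
is the quantity behind the ROC analysis in `evaluate_results()`.

**Snake refinement.** Each curve becomes an open active contour with one
node per image column, rows continuous, end nodes free. The internal energy
is the discrete elasticity + rigidity functional
(`alpha * |first difference|^2 + beta * |second difference|^2`); the
external energy samples an image potential — the Gaussian-smoothed
(sigma = 2) Sobel gradient magnitude, negated and normalized to
**[-255, 0]**. The 0-255 scale (rather than a unit range) keeps the
published weights `alpha = 50`, `beta = 20`, `edge_weight = 1` mutually
consistent: against a unit-range potential those internal weights would
make the image force negligible and the contour would simply straighten.

Evolution is greedy: each node may move vertically by up to `move_radius =
2` px to the lowest local-energy position. Updates run in three interleaved
sweeps over nodes `i mod 3`; nodes three apart share no energy term, so
each sweep is exact coordinate descent and the total energy is
non-increasing by construction. Convergence is declared when fewer than 1%
of nodes moved, or after 400 iterations.

*A limitation worth knowing.* Greedy descent with integer moves does not
guarantee that a larger `beta` always yields a smaller final bending
energy. High rigidity produces an ill-conditioned, glassy discrete
landscape: an isolated spike can spread into a wide shoulder that is a true
local minimum (we verified end states against every single-node move).
Across random integer-valued starts the excess never exceeded two squared-
pixel units — the move quantum — and the aggregate trend is monotone; the
tests assert exactly that bounded form.

**Distances and visualization.** For every shared column of the innermost
available lens curve and the cornea, `distance_profile()` reports three
Euclidean distances: *vertical* (same column; fast but biased on leaning
regions — two parallel 45 degree lines at vertical offset `d` measure `d`
instead of the true `d/sqrt(2)`), *normal* (least-squares tangent over a
10 px window, exact ray-segment intersection with the opposite polyline —
no pixel stepping, so no quantization bias), and *nearest* (two-stage
search: a coarse scan every `coarse_step` points within +-50 columns of
the vertical projection, then exhaustive refinement around every coarse
sample within a Lipschitz bound of the coarse winner, which makes the
result provably equal to the brute-force discrete minimum; ties break
toward the smaller column). Since the normal ray can hit a segment
*interior* between stored points, the profile clamps `nearest` to be no
larger than the other two paradigms. `render_heatmap()` draws the lens
inner curve 3 px thick over the scan, red at the minimal distance, green at
the maximal, linear in between; `query_point()` returns the stored triple
at any column.

**Parameter tuning.** The ten tunable parameters (median width, tracing
windows, snake weights, Canny limits and aperture, top-hat kernel) can be
re-tuned by classic DE/rand/1/bin differential evolution on a discretized
space (`pipeline_bounds()`: odd grids for kernels, steps of 10 for Canny
limits, 0.1 for the edge weight). Defaults `F = 0.8`, `CR = 0.9`,
population 150, 200 generations, early stop after 30 stagnant generations;
the fitness is the mean per-image curve MAE plus a 100 px penalty per
misclassified layer count or failed image (the method's objective is
unspecified beyond "segmentation quality", and MAE is the quantity the
validation reports). The shipped defaults in `default_config()` are the
published optimum of that search.

## The phantom generator

`generate_phantom()` renders what the pipeline needs to see, with exact
analytic ground truth:

* The **cornea** is a parabola (`cornea_apex_row`, `cornea_curv`, default
  sagitta about 45 px over a 300 px width, matching the gentle dome of real
  B-scans) rendered as a sharp erf surface, a bright plateau
  (`cornea_thickness = 12` px at gray 230), and a gradual exponential
  signal decay below (`tissue_decay = 20` px). OCT tissue has no sharp
  lower boundary; an artificial bottom edge would be the strongest gradient
  in the image and hijack the row-profile analysis.
* The **lens** is a band of thickness 7 px at gray 140 whose lower edge
  sits `vault` px above the cornea at the apex; the clearance grows toward
  the edges for central scans (`gap_curv`) and closes linearly to zero on
  one side for lateral scans.
* Band cross-sections are box profiles convolved with a Gaussian of fixed
  width `edge_sigma = 1` px (erf edges). The half-maximum — and the
  vertical-gradient maximum — then sit exactly on the analytic boundary for
  any thickness, which a Gaussian-bump profile does not satisfy.
* In the **extreme** scenario lens and tissue are rendered optically
  merged and all ground-truth curves coincide at the contact curve. This is
  deliberate: with the shipped Canny thresholds two stacked intensity steps
  cannot both be detectable (each would need a ~115 gray step on an 8-bit
  scale), which is precisely why such scans are two-layer images.
* **Speckle** is multiplicative mean-one log-normal
  (`pixel * exp(N(-sigma^2/2, sigma))`, default `sigma = 0.25`), applied in
  the emitted frame and clipped to 8 bits; **lateral contrast decay**
  multiplies each column by `1 - contrast_decay * |col - centre|/100`
  (default 0.1); a global **tilt** of 0-45 degrees is applied by the same
  exact rotation used in preprocessing, with the ground truth transformed
  analytically — never rasterized.

`generate_dataset()` draws per-phantom vaults (18-35 px), apex rows,
curvatures, lens thicknesses (6-8 px) and tilts (lateral 8-35, extreme
10-40 degrees) from ranges chosen once as representative; every item is
reproducible from `base_seed`.

What the phantoms do *not* emulate: real speckle correlation, shadowing and
specular artifacts, intra-tissue layering, motion, or vendor-specific
aspect ratios. Passing the phantom suite therefore demonstrates the
*algorithmic* correctness of each stage under controlled degradation, not
clinical-grade accuracy on patient scans.

## A worked example

```{r example}
ph <- generate_phantom(phantom_spec(scenario = "central", vault = 25,
                                    speckle_sigma = 0.25, seed = 42))
seg <- oct_segment(ph$image)
summary(seg)
profile <- measure_vault(seg)
query_point(profile, 150)
```

```{r plots, fig.show = "hold"}
plot(seg)
plot(render_heatmap(ph$image, seg$layers, profile, "nearest"))
```

Against the analytic truth:

```{r residuals}
r <- residuals(seg, ph$truth)
tapply(abs(r$residual), r$layer, mean)
```

## Numerical choices and degenerate inputs

* Curves are 0.5-based continuous rows over 1-based integer columns; the
  centre of pixel `(row, col)` is at `(col - 0.5, row - 0.5)` in the
  rotation geometry, which makes the affine resampling and the analytic
  point mapping agree to well under a tenth of a pixel.
* Canny hysteresis needs 8-connectivity; the labeller available here is
  4-connected, so components are taken on the 3x3-dilated weak-or-strong
  mask and intersected back. This bridges weak pixels at Chebyshev
  distance 2 — a slightly generous hysteresis with no observed effect on
  the phantom suite.
* A constant image has no orientation signal (error), an empty initial-row
  set aborts localization with "no layers detected" (callers treat the
  image as two-layers-or-fewer), a degenerate snake start (under 5 points)
  errors, and a DE fitness failure counts as `+Inf` so the candidate is
  rejected rather than crashing the search.
* Distances are reported in pixels; when `pixel_size_um` is supplied the
  profile adds micrometre columns. The scanner's physical pixel pitch is
  deliberately not assumed.
* Problem sizes in the shipped tests — 300 x 220 phantoms, batches of
  60, DE benchmarks at N = 20, D = 5, 200 generations — were chosen as the
  smallest sizes at which every property is exercised meaningfully.

## Known limitations

* In extreme scans the lens-tissue interface is below any workable edge
  threshold, so the reported "cornea" is the merged contact boundary; the
  clearance there is by definition zero.
* The two/three-layer call rests on the distinct-inner-limit test; vaults
  under about 3 px across the whole scan would classify as two layers.
* The snake inherits the preliminary curve's column span; boundaries
  invisible for more than 30 consecutive columns are not hallucinated
  beyond the extrapolation bound.
* Greedy integer-move descent can leave single-quantum bending differences
  between rigidity settings (see above).
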