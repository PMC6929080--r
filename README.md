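# octvault

Automatic analysis of the cornea–scleral contact lens relationship in
anterior-segment OCT (AS-OCT) images.

A scleral contact lens (SCL) vaults over the cornea; the fluid gap between
the lens's inner surface and the corneal surface — the **vault** — is the
quantity clinicians monitor when fitting the lens. Measuring it by hand on
noisy B-scans is slow and limited to simple metrics. `octvault` does it
automatically:

1. **Preprocess** — median smoothing, Perona–Malik anisotropic diffusion
   (speckle-aware, edge-preserving), rotation of tilted scans to horizontal
   via the dominant gradient orientation, white top-hat enhancement.
2. **Localize** — Canny edges, identification of the initial searching rows
   from the rises of the per-row edge profile, pixel-by-pixel tracing of
   each layer limit with artifact rejection, smoothness-guided candidate
   selection and gap interpolation, and an intensity-derivative search for
   the lens inner limit. Scans are classified as showing three layers
   (central/lateral) or two (extreme, where the lens has landed on the
   tissue).
3. **Refine** — each boundary becomes an open active contour ("free
   snake") minimizing elasticity + rigidity plus an edge-attraction
   potential, by greedy neighbourhood descent with a provably
   non-increasing energy.
4. **Measure** — per-column cornea–lens distances under three paradigms:
   **vertical** (same column), **normal** (to the local tangent, 10 px
   window), and **nearest point** (two-stage coarse/fine search, exactly
   the discrete minimum), all with the Euclidean metric
   `ED(p,q) = sqrt(sum_i (q_i - p_i)^2)`; plus a red→green heatmap
   rendering and point queries.

Pipeline parameters (snake weights α, β, edge weight; Canny limits; kernel
sizes; tracing windows) ship at their published optima and can be re-tuned
by the built-in differential-evolution search
(`v = x_r1 + F (x_r2 − x_r3)`, binomial crossover, greedy selection)
against any ground-truthed image set.

A synthetic **phantom generator** renders AS-OCT-like scans (curved lens
band, corneal surface with depth decay, multiplicative speckle, lateral
contrast decay, global tilt) with exact analytic ground-truth curves, so
the whole pipeline is testable and benchmarkable without clinical data.

## Worked example

```r
library(octvault)

ph  <- generate_phantom(phantom_spec(scenario = "central", vault = 25,
                                     speckle_sigma = 0.25, seed = 42))
seg <- oct_segment(ph$image)
summary(seg)
#> AS-OCT segmentation of a 220x300 image
#>   region class : three_layers (3 visible layers, confidence 1.00)
#>   applied tilt : 0.00 deg
#>   scl_outer: cols 1..300, rows 88.0..118.0, 100% traced
#>   scl_inner: cols 1..300, rows 94.5..125.5, 100% traced
#>   cornea   : cols 1..300, rows 119.4..164.0, 99% traced

profile <- measure_vault(seg)
query_point(profile, 150)          # distances at the apex column, in px
#> vertical   normal  nearest
#> 25.50000 25.70570 24.82438
```

The phantom was built with a 25 px apex vault; all three paradigms recover
it within a pixel. Against the analytic ground truth the traced boundaries
are sub-pixel accurate:

```r
r <- residuals(seg, ph$truth)
tapply(abs(r$residual), r$layer, mean)   # per-curve MAE in px
#>    cornea scl_inner scl_outer
#>  0.967100  0.360419  0.307295
```

`plot(seg)` overlays the curves on the scan;
`render_heatmap(ph$image, seg$layers, profile, "nearest")` produces the
clinical red→green clearance map. `run_pipeline()` does all of the above
for an image file and writes curves (CSV/JSON), the distance profile, the
heatmap PNG and a run manifest.

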