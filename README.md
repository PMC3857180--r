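# colonyspot

Automated analysis of marked cells in embryonic stem cell (ESC) colony
images: where inside a colony does a gene of interest switch on?

ESC cultures are heterogeneous — subpopulations marked by genes such as
pluripotency or differentiation reporters occupy characteristic places
inside a colony (center, edge, or nowhere in particular), and that spatial
preference carries biological meaning.  `colonyspot` turns bright-field or
merged-fluorescence micrographs of colonies with stained (marked) cells
into a statistical verdict on that preference.  It is aimed at
image-analysis and stem-cell groups who want a reproducible, scriptable
alternative to eyeballing colony montages.

## What it computes

Given a set of colony images the pipeline runs four stages:

1. **Preprocessing** — rolling-ball top-hat background removal
   (`I - (I \circ B_{r,h})`), CLAHE contrast conditioning, and border
   enhancement `G_{\sigma} * (I + g \cdot I \cdot H(I - t))` with `H` the
   Heaviside step.
2. **Colony segmentation** — a two-phase region-competition level set
   (single contour, Chan–Vese-type).  With `\phi < 0` inside, the energy

   ```
   E(φ, c1, c2) = λ_in ∫ |I − c1|² H(−φ) + λ_out ∫ |I − c2|² H(φ) + μ ∫ |∇H(φ)|
   ```

   is minimized by explicit gradient descent with the arctan-regularized
   Heaviside/Dirac pair; the binary result is dilated, hole-filled,
   area-filtered, and split into individual colonies by a
   marker-controlled watershed on the Euclidean distance transform.
3. **Marked-cell detection** — Perona–Malik diffusion (exponential
   conductance, zero-flux boundaries) followed by an **Orientation
   Matching** transform: the normalized image gradient `n = ∇I / |∇I|` is
   correlated with annulus templates whose points carry outward radial
   weights `(dx, dy)/ρ²`; the per-pixel maximum over sub-annuli
   `[r, r+s] ⊂ [r1, r2]` peaks at centers of circular rims whose radius
   lies in the band.
4. **Location statistics** — each detection is mapped to a normalized
   centroid distance `δ_i = d_i / D_i ∈ [0, 1]` (distance to the colony
   centroid over the centroid-to-edge distance along the same ray) and to
   normalized mutual distances `m̂_ij = m_ij / M` (`M` = colony major
   axis).  A Monte-Carlo null repopulates each real colony mask with 10×
   uniformly random points (rejection sampling in the bounding box).  Two
   two-sample Kolmogorov–Smirnov tests at `α = 0.001` yield the labels
   **PREFERENTIAL / NON-PREFERENTIAL**, sub-label **INNER / OUTER** (by
   comparing mean δ against the null), and **CLUSTERED / NON-CLUSTERED**
   (significantly *smaller* mutual distances than the null).

A phantom generator (`phantom_spec()`, `make_colony_phantom()`,
`make_point_phantom()`) produces synthetic colony images and point
patterns with controllable spatial structure (uniform, inner-clustered,
edge-biased), so the whole pipeline is testable without microscope data.

## Worked example

```r
library(colonyspot)

spec <- phantom_spec(seed = 7, n_colonies = 3, n_spots_per_colony = 10,
                     placement = "inner_clustered",
                     placement_concentration = 5, noise_sd = 3)
ph <- make_colony_phantom(spec)

colonies   <- segment_colonies(preprocess_image(ph$image))
print(colonies[[1]])
#> <colony 1> area 10587 px, centroid (85.6, 169.6), major axis 147.8 px

detections <- detect_cells(ph$image, colonies, detect_params(polarity = "dark"))
head(detections, 3)
#>   colony_id   x   y radius_px    score
#> 1         3 514 368       8.5 7.112925
#> 2         3 523 389       8.5 7.112580
#> 3         3 499 439       8.5 7.112337

report <- analyze_locations(colonies, detections, alpha = 0.001, seed = 7)
print(report)
#> Intra-colony location report
#>   location: PREFERENTIAL (INNER)
#>   cluster:  CLUSTERED
#>   centroid-distance KS: D = 0.4159, p = 0.00055 (n = 25 real vs 209 null)
#>   mutual-distance KS:   D = 0.3349, p = 1.06e-11
#>   mean delta: real 0.434 vs null 0.644; alpha = 0.001
#>   note: only 25 pooled real observations; the KS test is reliable from a few hundred samples upward
```

The phantom placed its marked cells with an inner bias (sampling weight
`exp(-5 δ)`), and the report recovers exactly that: the real δ
distribution differs from the uniform null (`p < α`), its mean (0.434)
sits below the null mean (0.644) → **INNER**, and mutual distances are
significantly smaller than under the null → **CLUSTERED**.  The
reliability note reflects the deliberately small example.

For file-based runs use `run_pipeline(paths, out_dir, config)` (writes
`colonies.csv`, `detections.csv`, `locations.csv`, `mutual.csv`,
`report.json`, `pipeline.log`, optional overlay PNGs) or the CLI
launcher in `inst/cli/colonyspot` with subcommands `simulate`, `segment`,
`detect`, `analyze`, `evaluate`, `run`.  Per-marker parameter presets
(radius bands 6–9, 4–10, 10–25, 10–24 px) are available via
`preset_config()`.

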