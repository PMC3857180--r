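---
title: "colonyspot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colonyspot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(colonyspot)
```

This vignette is the package's own account of its science: the models
each stage implements, the assumptions they rest on, the tunable
parameters with their defaults and provenance, what the synthetic-data
generator does and does not emulate, and the numerical choices that were
genuinely open.  Every empirical statement here is one the test suite
computes; nothing is quoted from elsewhere.

## The question and the statistical frame

A stem-cell colony is a quasi-circular clump of cells; a staining or
fluorescence protocol marks the subset of cells expressing a gene of
interest.  The scientific question is whether those marked cells occupy
a *preferred* location inside the colony.  The frame is classical
hypothesis testing against a simulation null: if expression were
location-indifferent, marked-cell positions would look like uniform
draws over the colony mask.  We therefore compare two observable
summaries of the real detections against their distribution under
uniform repopulation of the *same* colony masks:

* the normalized centroid distance
  $\delta_i = d_i / D_i$, where $d_i = \lVert P_i - C\rVert$ is the
  cell's distance to the colony centroid $C$ and $D_i = \lVert b_i -
  C\rVert$ the distance from $C$ to the colony edge point $b_i$ on the
  same ray.  This maps any colony onto a unit disc: $\delta = 0$ at the
  centroid, $1$ at the edge, for any eccentricity or rotation.
* the normalized mutual distances $\hat m_{ij} = m_{ij} / M$ of all
  unordered cell pairs within a colony, with $M$ the colony's
  ellipse-equivalent major axis.

Both samples are pooled across all colonies of an image set and compared
to the pooled null samples with the two-sample Kolmogorov–Smirnov test.
The confidence level is deliberately stringent, $\alpha = 0.001$,
because biological variation is large and small real datasets will
always deviate somewhat from the null even without a true preference.
The labels follow mechanically:

* `PREFERENTIAL` iff the centroid-distance KS test rejects;
  sub-label `INNER`/`OUTER` by comparing the real and null mean
  $\delta$.
* `CLUSTERED` iff the mutual-distance KS test rejects **and** the real
  mean $\hat m$ is smaller than the null mean.  A significant difference
  with *larger* mutual distances would mean over-dispersion, a pattern
  outside the label vocabulary; it is reported `NON_CLUSTERED` with a
  diagnostic note rather than mislabeled.

The null is generated per colony by drawing uniform real-valued points
in the colony's bounding box and rejecting those falling outside the
mask, until $10\times$ the number of real detections are *retained*
(the multiplier counts accepted points, since discarded draws carry no
information).  Per-colony random streams are derived from the top-level
seed and the colony label by a fixed affine counter scheme
(`derive_seed`), so colony processing order cannot change any result.

### Numerical choices in the statistics

* **KS p-value.**  $D$ is the exact sup-difference of the two empirical
  CDFs over pooled sample points.  The p-value uses the asymptotic
  Kolmogorov series with the Stephens small-sample correction
  $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$,
  $n_e = n_a n_b/(n_a+n_b)$, truncated at 100 terms.  As
  $\lambda \to 0$ the truncated alternating series degenerates (its
  partial sums oscillate instead of approaching the limit 1), so for
  $\lambda < 0.05$ the p-value is set to its limit 1.  Tests verify
  $D$ against a brute-force ECDF scan to $10^{-12}$ and the p-value
  against `stats::ks.test` on random data.
* **Truncation.**  Segmentation tends to overshoot slightly beyond the
  true colony edge, inflating the apparent $D_i$ and piling unreliable
  observations at $\delta \approx 1$.  Deltas in $[0.95, 1]$ are
  therefore *removed* (not clamped) from both the real and the null
  samples — removal, because the motivation is unreliability of those
  observations, so they should enter neither ECDF.  The cut point is a
  config parameter (`lower_cut`); 0.95 is an implementation default,
  not a published value.
* **Cells exactly at the centroid** short-circuit to $\delta = 0$: the
  ray to the edge is undefined there.
* **Edge point selection.**  $b_i$ is the boundary pixel maximizing the
  cosine similarity with $P_i - C$; exact ties are broken toward the
  outermost candidate via a bias ($\sim 10^{-9}$ in cosine units) far
  below the boundary's angular resolution but above floating-point
  noise, which keeps the selection vectorizable.
* **Smoothing.**  Reported distribution curves are smoothed with a
  centered moving average of window 3 (shrinking at the edges); KS
  tests always run on the raw samples — smoothing is presentation only.
* **No multiple-testing correction** across the two tests: the single
  stringent $\alpha$ per test is the published analysis convention.

## Preprocessing

Rolling-ball top-hat removes slowly varying illumination: the image
minus its grayscale opening by a non-flat ball element of radius $r$
and height $h$ (profile $h\sqrt{1-\rho^2/r^2}$).  Out-of-image offsets
are ignored ("restricted window"), which makes the opening of a
constant image exactly constant and the top-hat exactly zero.  CLAHE
then equalizes contrast tile-wise; the clip limit is a multiple of the
mean bin count, `Inf` disables clipping, and the single-tile unclipped
configuration degenerates to textbook global histogram equalization
(the test oracle).  Border enhancement computes
$G_\sigma * (I + g\,I\,H(I-t))$: pixels strictly above threshold $t$
amplified by $1+g$, then a unit-sum Gaussian blur with reflect padding
(reflect, to avoid border darkening that would bias edge colonies).
The published rendering of the parameter table is illegible for the
ball radius/height and the threshold; defaults
($r=25, h=40, t=128, g=0.5$, CLAHE clip 2.5 on an $8\times 8$ grid)
were calibrated on phantoms and are flagged as non-published values.

## Colony segmentation

The segmenter is the simplified, single-contour, two-dimensional
variant of a region-interaction level-set model: two-phase region
competition with a length penalty,

$$E(\phi, c_1, c_2) = \lambda_{in}\!\int |I-c_1|^2 H(-\phi)
 + \lambda_{out}\!\int |I-c_2|^2 H(\phi) + \mu\!\int |\nabla H(\phi)|,$$

with $\phi<0$ inside, $c_1, c_2$ the regularized-Heaviside-weighted
inside/outside means recomputed every iteration, and the arctan
regularization $H_\varepsilon(z)=\tfrac12(1+\tfrac2\pi\arctan(z/\varepsilon))$,
$\delta_\varepsilon(z)=\varepsilon/(\pi(\varepsilon^2+z^2))$ with
$\varepsilon = 1$.  The arctan pair has global support, so every level
line feels the data force and the result is robust to initialization.
The descent update is explicit; curvature is
$\mathrm{div}(\nabla\phi/|\nabla\phi|)$ with the gradient magnitude
floored at $10^{-8}$.  Instead of periodic reinitialization, $\phi$ is
clipped to $[-50, 50]$ each step — simpler, and adequate at the
few-hundred-iteration scale used here.  Initialization is the signed
Euclidean distance to the Otsu foreground by default (a checkerboard
mode exists for initialization-robustness experiments).

The fidelity weights $\lambda_{in}=\lambda_{out}=1$ are the two legible
unit entries of the published parameter table; $\mu = 650$ (intensity²
units — a mild penalty relative to data terms of order $10^4$ on the
0–255 scale), $dt = 5\cdot10^{-4}$ and 200 iterations are phantom
calibrations at which two-level phantoms reach Dice 1.0 and the
discrete energy decreases monotonically.

Binary enhancement follows the published cascade: dilation by a flat
disk (radius 2), hole filling (a hole = background not 4-connected to
the image border), removal of components below `min_area_px` (500).
The mask is split into colonies by a marker-controlled watershed
flooding the Euclidean distance transform from the regional maxima that
survive h-maxima suppression of depth `h_merge` = 4 px — the
suppression is unstated in the source analysis and prevents
over-segmentation of single colonies with rough distance landscapes.
Colony descriptors: area centroid; boundary = mask pixels with a
background 4-neighbour (a discretization-consistent, testable reading
of "points on the edge"); major axis = ellipse-equivalent
$4\sqrt{\lambda_1}$ from second-order central moments (for a disc of
radius $R$ this is $2R$, consistent with the mutual-distance
normalization's intent).

## Marked-cell detection

Perona–Malik diffusion softens texture while preserving object borders:
explicit 4-neighbour flux updates with exponential conductance
$g(d)=e^{-(d/\kappa)^2}$ (chosen over the rational form for stronger
edge preservation) and zero-flux boundaries; the pairwise-antisymmetric
fluxes conserve the global mean to machine precision, a conservation
the tests assert at $10^{-9}$.  The default $\kappa = 50$ is a phantom
calibration with a specific rationale: at $\kappa \approx 10\!-\!15$
the scheme's backward-diffusion regime straightens the soft 1.5 px spot
rims into staircase steps whose lattice alignment displaces the
orientation-matching peak by up to $\sim$2.5 px, while $\kappa = 50$
leaves the amplitude-$\sim$110 rims intact
($g(110/50) \approx 0.008$) and still removes noise up to
$\sigma \approx 5$ almost completely.

Orientation Matching correlates the *normalized* gradient field with an
artificial annulus gradient: all integer offsets with
$r_1 \le \rho \le r_2$, each carrying the outward radial weight
$(dx,dy)/\rho^2$ (unit direction scaled by $1/\rho$, so every radius
shell contributes equally).  The radius band is scanned as sub-annuli
$[r, r+s]$ and the score map is the per-pixel **maximum** over the
bank, with `best_radius` the winning band's midpoint — maximum rather
than sum, because an extremum over the annulus bank preserves radius
selectivity (a sum would blur it).  Normalizing the gradient makes the
response contrast-invariant but undefined at zero gradient; magnitudes
below `gradient_floor` are therefore zeroed.  The floor default is
**1.0 intensity-unit/px**, not an epsilon: after diffusion, residual
noise gradients are small but not zero, and unit-normalizing them
manufactures coherent-looking orientation noise that can reach scores
of 4–5.6 — above any workable threshold.  A floor of 1.0 sits below
the 8-bit quantization contrast of a real edge, so no genuine rim is
suppressed, while flattened noise regions contribute nothing.

Sign convention: a *dark* spot on a brighter surround has an outward
rim gradient, so the outward-weighted template already scores dark
spots positively; bright polarity negates the response.  The two
polarities give exactly opposite per-band responses (the symmetry is
exact for a single band; under a multi-band maximum the winning band
may differ).  Peaks at or above the frozen threshold (4.0, calibrated
once on phantoms where true spots score $\ge 5.5$ and intra-colony
background $\le 2.9$) undergo greedy non-maximum suppression within
`min_separation_px` = $r_1$ (two real cells cannot overlap more than
their minimal radius), are discarded outside every colony mask, and
inherit their colony's label.

## The phantom generator: what a green test establishes

`make_colony_phantom()` renders the stated world the tests live in:
non-overlapping rotated ellipses (eccentricity capped at 0.6 so the
radial normalization stays meaningful) on a flat background, with
1.5 px linear rims — soft, so the gradient detector faces realistic
edges instead of trivially sharp ones; marked cells as soft-edged discs
of either polarity; an optional linear illumination tilt; Gaussian
pixel noise added last.  Spot placement draws the normalized radial
coordinate from the density $u\,w(u)$ with
$w = e^{-cu}$ (inner-clustered), $e^{-c(1-u)}$ (edge-biased) or $1$
(uniform), and keeps cells *resolvable*: centers at least
$r_i+r_j+6$ px apart (falling back gracefully at unrealistically high
densities) and $r+5$ px clear of the colony rim, because a detector
whose outer sub-annulus overlaps a neighbouring rim or the colony edge
is answering a different question than the one under test.
`make_point_phantom()` provides the same placement laws directly on a
mask, so the statistics can be exercised at scale without imaging.

Deliberate non-realism, hence limits of a green test: interiors are
untextured (the source imagery's interior texture is undescribed, so
texture realism is reduced to the noise/tilt model); there is no
multi-channel fluorescence simulation (a single merged-channel
grayscale image suffices); illumination is linear; colony shapes are
exact ellipses.  A green suite therefore establishes correctness of
the algorithms and the statistical machinery under controlled
conditions — not robustness to every microscope artifact.

Default scene parameters (480×640 px, semi-major axes 50–85 px, spot
radii 6–9 px, background/colony levels 40/160, noise σ = 3) represent a
quarter-scale version of the published acquisition setting
(2560×1920 px images resized to 25% for tractability, chromogenic
radius band 6–9 px); levels and noise are a scientist's-choice
realistic contrast, stated once here.

## Pipeline I/O conventions

All user-facing coordinates are 0-based with $x$ = column, $y$ = row.
Working-scale images are the originals downscaled by `resize_factor`
(default 0.25 — the published working resolution is not legible; the
resize is a performance device, not part of the model), and every
coordinate in the CSV outputs is rescaled back to the original
resolution; $\delta$ and $\hat m$ are scale-free.  Configurations are
strict YAML (unknown keys rejected) with per-marker presets carrying
the four published radius-band profiles; two of those profiles are
fluorescence-derived and use bright polarity.  TIFF support is a
package-internal uncompressed-baseline codec (no TIFF library exists in
the supported environment); PNG, JPEG and plain PGM/PPM are also
accepted.

## Known limitations

* Single-contour two-phase segmentation: colonies touching each other
  rely entirely on the watershed split; colonies touching the image
  border are not specially handled.
* Detection is 1 px-grid localization by design; sub-pixel refinement
  is out of scope, and the worst-case argmax displacement across random
  sub-pixel spot centers is ~1.5 px (a neighbouring pixel).
* The asymptotic KS p-value is approximate for very small samples; the
  report attaches a reliability note below 30 pooled real
  observations.
* The CLAHE tile blending interpolates between monotone per-tile maps;
  rank order is guaranteed by each tile's own map, not across blended
  neighbourhoods.
* Compressed TIFF inputs are not readable; convert to PNG or
  uncompressed TIFF first.
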