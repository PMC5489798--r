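---
title: "Measuring retinal vessel diameters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel diameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselcaliper)
```

`vesselcaliper` estimates the local caliber of retinal blood vessels in
fundus images. This vignette explains the measurement model stage by
stage, the tunable parameters and their defaults, what the synthetic
phantoms do and do not emulate, and the numerical and design choices
made where the method leaves them open.

## Coordinate convention

Images are numeric matrices indexed `[row, col]`, 1-based, origin at the
top-left, rows increasing downward. Every point in the package —
skeleton pixels, characteristic points, snake contour vertices — is a
`(row, col)` pair in this frame; subpixel positions are used wherever
the quantity is continuous. All lengths are in pixels; no micrometre
conversion is applied.

## Segmentation and thinning

Binarization is plain thresholding: with polarity `bright_vessels`
(hand-labeled vessel maps, bright vessels on dark background) a pixel is
foreground iff its intensity strictly exceeds the threshold `S`;
`dark_vessels` inverts the comparison for raw fundus photographs. The
strict inequalities leave `I == S` unassigned; the package maps ties to
background and documents that choice. `S` defaults to `"auto"`, Otsu's
criterion on the intensity histogram — deterministic and reproducible —
with a numeric override. For color photographs the green channel is the
default reduction (highest vessel/fundus contrast in fundus
photography); red, blue and Rec. 601 luminance are available.

Thinning is Zhang–Suen two-subiteration parallel erosion: each pass
peels the outer pixel layer wherever a pixel has 2–6 active neighbors,
exactly one 0→1 transition around its 8-neighbor ring, and the
subiteration's directional template, until no layer can be removed. Two
defects of the textbook scheme are handled explicitly:

* *vanishing components* — an isolated 2×2 block satisfies both
  templates at every pixel simultaneously, so parallel deletion can
  erase a small component entirely. Any component whose pixels are all
  scheduled for deletion in one subiteration is re-seeded with its
  top-left pixel, preserving the 8-connected component count.
* *diagonal staircases* — the parallel scheme leaves two-pixel staircase
  runs on diagonal vessels, which a neighbor-count classifier reads as
  spurious bifurcations. A sequential cleanup pass deletes any
  non-endpoint pixel whose foreground neighbors remain a single
  8-connected set without it (a simple point), reducing the skeleton to
  minimal 8-connected digital curves without moving endpoints or
  changing topology.

The resulting skeleton is a subset of the foreground, one pixel wide (no
full 2×2 block), with the component count of the input — all three
properties are asserted by the test suite on random blob masks.

## Skeleton points and branches

A 3×3 sliding mask classifies each skeleton pixel by its number of
active 8-neighbors: 1 → endpoint, 2 → inner point, >2 → bifurcation
point. Pixels with no active neighbor get an explicit `isolated` class —
the neighbor-count rule does not address them, and labeling them
explicitly keeps noise out of the measurements. Thinning often leaves
junctions as clusters of two or three mutually adjacent high-degree
pixels; adjacent bifurcation pixels are merged into one junction node
whose representative is the lowest-(row, col) pixel.

Branches are traced from terminal pixels (endpoints, junction pixels)
through runs of inner pixels, with a fixed row-major neighbor scan so
the traversal is deterministic; branches are reported ordered by their
terminal coordinates. Pure cycles with no terminal are emitted as closed
branches with a warning and excluded from measurement.

Before measurement, up to `junction_trim` pixels (default 5) are dropped
from any branch end that terminates at a bifurcation: the thinned
centerline bends through the junction bar, and a chord anchored there
cuts across the crotch between two daughter vessels rather than a
cross-section of either. On a Y-phantom with 5-px arms this trimming
reduces the worst arm error from above 1 px to below 0.1 px.

## Characteristic points (Douglas–Peucker)

Each branch polyline is reduced to characteristic points by the
Douglas–Peucker algorithm: connect the end nodes with a chord, find the
point with the largest perpendicular distance to it, and if that
distance exceeds the tolerance ε, keep the point and recurse on both
halves; otherwise eliminate the interior points. Distances are measured
to the infinite line through the chord (the classic construction); ties
for the farthest point split at the lower index for determinism. The
default ε is 1 pixel, a compromise between following vessel curvature
(small ε → short chords → diameters measured nearly perpendicular to
the local axis) and compression; useful values are 0.5–2.

The data compression ratio `DCR = 100·(N − n)/N` summarizes the
reduction (N input points, n kept). Straight phantom vessels compress to
DCR ≈ 97–98% at ε = 1; a sinusoidal vessel to ≈ 92%.

## Snake edge detection

The vessel edge is found by an active contour `v(s) = (row(s), col(s))`
minimizing

`E = Σᵢ α·|vᵢ − vᵢ₋₁|² + β·|vᵢ₋₁ − 2vᵢ + vᵢ₊₁|² + E_ext(vᵢ)`,

with external energy `E_ext = −γ·|∇(G_σ ∗ I)|²` — the negative squared
gradient magnitude of the Gaussian-smoothed image, so edges are energy
minima. The gradient uses central differences after smoothing; subpixel
contour positions read the field through bilinear interpolation. By
default `|∇|²` is normalized by its maximum, making `γ` comparable
across images of different contrast and to `α`/`β`.

Minimization is greedy discrete local search: every sweep visits each
point in order and moves it to the best position in its
`(2·search_radius + 1)²` neighborhood, accepting a move only if the
exact total-energy change over the terms it touches is negative. The
total energy is therefore non-increasing after every sweep — an
invariant the tests assert on every run. Evolution stops when no point
moves or after `max_iterations` sweeps.

Two practical refinements make the greedy scheme work from a realistic
initialization:

* *Coarse-to-fine scales.* A σ = 1 field attracts only within ~3 px of
  an edge; an initial contour placed a margin away (or a test contour
  10 px out) would never move, because the internal cost of a 1-px
  single-point displacement exceeds the external slope in the field's
  tails. The field is therefore evolved through
  `sigma_levels × sigma` (default 8, 4, 2, 1), each level resampling
  the contour to uniform spacing; the finest level appends subpixel
  refinement steps (0.5, 0.25 px). Energy traces are recorded per level
  and are monotone within each (the functional changes between levels).
* *Weak internal weights.* Defaults are `α = 0.01`, `β = 0.005`,
  `γ = 2`. The continuity/curvature terms only need to keep the contour
  smooth and evenly sampled; with O(1) weights they would dominate the
  normalized external term and freeze the contour. With these defaults
  a radius-30 circular contour converges onto a radius-20 disc edge to
  0.03 px mean radial error, and tube edges are localized to ~0.1 px.

The continuity term defaults to the raw squared first difference (the
textbook functional, which also provides the contraction pressure that
pulls an outside initialization onto the vessel); a mean-spacing form
`(d̄ − |vᵢ − vᵢ₋₁|)²` that resists point clustering without contraction
is available via `continuity = "mean_spacing"`, with `d̄` frozen at the
start of each level so the minimized functional is fixed.

The initial contour for a vessel is constructed from the segmentation:
the mask component containing the branch is dilated outward by `margin`
pixels (default 2, within the capture range of the finest scale), its
0.5-level boundary extracted as a closed subpixel loop, and the loop
resampled to `resample_spacing` (default 1.5 px). Disjoint vessels in
the same image are not enclosed. The snake runs on the grayscale
intensities by default (`E_ext` needs them); `snake_on = "mask"` runs it
on the binary segmentation instead when no usable intensity image
exists.

## Diametry

For each pair of consecutive characteristic points `N`, `P`, one contour
point is selected on each side of the chord (side = sign of the cross
product `(P − N) × (M − N)`). Among candidates whose perpendicular foot
falls within the segment, the one with the foot nearest the chord
midpoint is chosen per side — deterministic, and measuring the width
near the segment center where the chord best approximates the local
vessel axis; a side with no in-segment foot falls back to the candidate
whose foot is nearest the segment, and if a side has no candidates at
all the segment is skipped with a warning.

Each triangle `(N, P, M)` yields `a = |NP|`, `b = |MP|`, `c = |NM|`,
the area by Heron's formula `A = √(S(S−a)(S−b)(S−c))` with
`S = (a+b+c)/2`, and the height `h = 2A/a` — algebraically the
perpendicular distance from `M` to the line `NP`, an identity the tests
verify to 1e−9. The local diameter is the sum of the two opposite-side
heights. A radicand negative by less than 1e−9 (floating-point
near-degeneracy of an almost-collinear triangle) is clamped to zero;
grosser triangle-inequality violations are an error.

## Synthetic phantoms

`generate_phantom()` renders straight, sinusoidal, tapering and
Y-bifurcation tubes with exactly known centerline and width: a band of
half-width `w/2` around an analytic centerline, with coverage-fraction
anti-aliasing (intensity ramps linearly across one pixel at the edge) so
the true edge has a subpixel position for the snake to find; a
hard-edged binary rendering is available behind `antialias = FALSE`.
Defaults emulate a hand-labeled fundus map: vessel intensity 0.85,
background 0.15, image 160×160, no noise; Gaussian noise of any level
can be added under a fixed seed (bit-reproducible). Tube ends are cut
flat — a vessel crossing the field of view, not a capsule — so the mask
area matches width × length; bifurcation arms keep a round cap at the
junction so the three arms merge smoothly.

The phantoms emulate local geometry (width, orientation, curvature,
branching) and edge blur. They do **not** emulate the central light
reflex, illumination gradients, the optic disc, crossing vessels, or
pathology; passing the phantom-recovery tests demonstrates that the
geometry pipeline is unbiased on clean tubes, not that segmentation of
raw pathological photographs is solved.

## Evaluation statistics

`run_evaluation()` compares paired manual (`x`) and automated (`x̄`)
diameters per image: signed differences `x − x̄`, the mean absolute
difference `E_avg = Σ|x − x̄|/n`, and dispersion reported two ways —
the root-mean-square `√(Σ|x − x̄|²/n)` of the differences, and the
conventional sample standard deviation (divisor `n − 1`, absent for a
single pair). Both are reported because the RMS-style formula is the one
quoted alongside the reference tables bundled with the package, while
the sample SD is the conventional diagnostic; for the bundled tables
neither reproduces the tables' printed SD column, whose provenance is
unexplained, so that column is shipped as-is and not used as a check.

The bundled table (`reference_tables()`) carries one internal
inconsistency worth knowing about: for image `im0002.ah.jpg`, vessel 5,
the printed diameters subtract to −0.0747 while the printed difference
column says −0.0777, and the printed per-image `E_avg` follows the
difference column. The package ships the table exactly as printed and
computes statistics from the diameter columns; the tests pin down both
facts.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
inputs: 160×160 phantoms (25 straight tubes, one sinusoidal, one
bifurcation), a 101×101 disc, 50 random 40×40 blob masks, 200 random
short polylines and 1000 random triangles — sizes chosen so the full
chain is exercised in seconds while leaving recovery errors far from
their tolerances. The default pipeline is deterministic: same image,
same configuration → byte-identical outputs; the only randomness in the
package is phantom noise, which is seed-scoped.

## Known limitations

* Diameters are measured per characteristic-point chord; on strongly
  curved vessels with large ε the chord deviates from the local axis
  and overestimates slightly (the sinusoidal phantom bounds this at
  ~0.3 px for ε = 1, amplitude 5, period 80).
* Vessels thinner than ~2 px are at the resolution limit of the
  gradient-based edge model.
* The greedy snake finds local minima; an initialization enclosing two
  parallel vessels will not split.
* Junction calibers (within `junction_trim` of a bifurcation) are
  deliberately not reported.
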