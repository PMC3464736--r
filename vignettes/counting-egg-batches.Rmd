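---
title: "Counting mosquito egg batches from filter-paper images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mosquito egg batches from filter-paper images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovocount)
```

## The problem

Female *Anopheles* mosquitoes lay batches of dark, elongated eggs on wet
filter paper. Fecundity experiments photograph these papers and need the
egg count per batch — often thousands of eggs across hundreds of images.
`ovocount` automates the count for images in which eggs are clearly darker
than the (white or semi-white) paper. A camera of 5 megapixels or more,
low ISO, and no post-hoc resizing give the contrast and scale the method
expects.

## Pipeline and assumptions

The pipeline is: luminance conversion, capped entropic thresholding,
8-connected component extraction, single-egg size estimation, debris
rejection on the original color image, noise removal, and area-division
counting. Its core assumptions are:

* eggs are dark on a bright background, so one global threshold separates
  them;
* a *single* egg is an elongated ellipse, so its moment eccentricity is
  high, while piles of overlapping eggs are more circular;
* debris is betrayed by the yellow-brown chromatic halo around it, while
  eggs and paper are nearly achromatic;
* thresholding noise (grid-line fragments, speckles) is small relative to
  an egg.

### Luminance and thresholding

Luminance is the Rec. 601 weighted sum `0.299 R + 0.587 G + 0.114 B`. (A
blue weight of 0.144 circulates in some descriptions of this conversion;
the canonical Rec. 601 triple sums to one and is used here. The weights
are a parameter, so either choice can be configured.)

The threshold maximizes the entropic-correlation (Yen) criterion
`C_B(T) + C_F(T)` with `C_B(T) = -log Σ_{g≤T} (p(g)/P(T))²` and
`C_F(T) = -log Σ_{g>T} (p(g)/(1−P(T)))²`, i.e. both class distributions
should be as spread out as possible after normalization. The search is
restricted to `T` below a cap `T″` (default 170 on the 8-bit scale, the
midpoint of the useful 160–180 band): flash glare can push parts of the
paper very bright, and an uncapped criterion can then try to "segment"
the glare rather than the eggs. Levels at which one class would be empty
are inadmissible; ties break toward the smaller threshold for
determinism. A histogram whose admissible range is empty (a uniform or
blank image) raises a classed degenerate-image condition;
`analyze_image()` converts it to an empty result with a warning, so a
blank paper reports zero eggs rather than an error, while the condition
class still lets callers distinguish the case.

Pixels strictly below the threshold are foreground. Note the asymmetric
boundary: the criterion assigns the level `T` itself to the dark class,
binarization assigns it to the background. On photographic histograms
(smooth, many occupied levels) the single boundary level is immaterial.

### Shape statistics

Components are 8-connected (diagonal contact joins), labeled in
raster-scan order; the labeling is a two-pass union-find in C++ (the
4-connected labeler in EBImage does not implement the required
adjacency). Per component we accumulate raw second central moments
`μ₂₀, μ₀₂, μ₁₁` about the pixel-center centroid and form
`e = sqrt(1 − λ₁/λ₂)` from the eigenvalues of the moment matrix. The
convention is 0 for a disk and 1 for a line; that is the only orientation
of the scale under which an eccentricity window of 0.95–0.99 selects
elongated single eggs. Degenerate shapes are defined explicitly: a single
pixel has `e = 0`, a one-pixel-thick straight segment `e = 1`. Because
`e` depends only on the eigenvalue ratio, normalizing moments by area
would change nothing (asserted by test). Moments use pixel centers;
border-touching components are kept.

### Egg size, debris, noise, counts

The single-egg area `S` is the mode of the areas of components inside the
eccentricity window. Areas are near-continuous, so an exact integer mode
would be brittle; instead areas are binned geometrically with 10%
relative width, the fullest bin wins (ties to the smaller-area bin), and
the bin's median area is returned. With no candidate in the window the
estimation stops with an instructive error — the window bounds are the
sensitivity control to widen.

Debris detection runs on the original color image, before noise removal:
a component with at least `X = 10` pixels of chroma above `C_E = 0.15`
within Chebyshev radius `r = 5` px of any of its pixels is debris
(defaults; all three are parameters). The dilation-based neighborhood
covers the component itself plus a band around it, which is where the
halo lives. Eggs that lie *inside* a chromatic halo are knowingly
misflagged — that is the method's documented failure mode, and no rescue
heuristic is attempted.

Components smaller than `S/2` are noise (strictly smaller; `S/2` exactly
survives). Survivors are counted by `N = round(A/S)` for `A ≤ 2S`, else
`N = round(A·C/S)` with the accumulative ratio `C = 0.9 < 1`: in
photographs the shadowed overlap regions of stacked eggs join the pile's
silhouette, so its area overstates `n·S` and is discounted. Rounding is
half-away-from-zero (the round convention is otherwise ambiguous at
ties), and a surviving object counts at least one egg — an object big
enough to pass noise removal cannot round to zero eggs.

## The synthetic scene generator

There is no public corpus of annotated egg-batch photographs, so the
package ships a generator whose output plays the role of ground truth.
`generate_scene()` renders, deterministically per seed:

* near-white paper (0.95) with dashed grid lines whose per-dash darkness
  varies over 0.35–0.55 — dark enough that at least the darker dashes
  binarize into small fragments the noise rule must discard, as grid
  lines do in photographs;
* single eggs as filled rotated ellipses, default semi-axes `a = 16`,
  `b = 4` px at intensity 0.15. The 4:1 elongation gives
  `e ≈ 0.968`, inside the default window. (A 3:1 ellipse has
  `e ≈ 0.943` and would fall *below* the default window — elongation is
  the one generator property the defaults genuinely constrain.) Axes
  jitter by ±5% in scale and ±7.5% in ratio, keeping `e` within roughly
  0.96–0.97;
* piles of 2–5 member ellipses sharing an orientation, each offset from
  the previous by 0.5–1.0 minor-axis lengths roughly perpendicular to the
  major axis, so unions are visibly more circular than singles. The union
  is dilated by one pixel and that fringe drawn dark, emulating the
  shadowed overlaps that enlarge real piles — the very effect the
  accumulative ratio exists to discount. Without the fringe a rendered
  union *under*-represents `n·S` and the discount would double-penalize;
* debris as round-ish dark blobs wrapped in a 4-px halo of RGB
  (0.85, 0.72, 0.55): chroma 0.30 (chromatic, above `C_E`), luminance
  0.725 (bright, stays background). Eggs keep ≥ 8 px clearance from
  halos so the radius-5 debris rule cannot reach them — the generator
  deliberately does not reproduce the known egg-inside-halo failure mode;
* sub-egg speckles (1–4 px), and uniform per-pixel intensity jitter
  (±0.02) on all dark features so histograms are smooth, as sensor noise
  makes them.

Placement is rejection sampling against an occupancy mask with a 2-px
margin, so distinct objects never merge. Ground truth records each
object's kind, true egg count and footprint, and the median rendered
single-egg area.

What passing on these scenes does *not* show: robustness to uneven
illumination, focus blur, JPEG artifacts, or eggs adjacent to debris —
real photographs can present all of these, and the interactive
sensitivity controls (the eccentricity window, chroma cutoff, threshold
cap) exist precisely because fully automatic operation sometimes needs a
nudge. Grid dashes that happen to lie inside a debris halo are flagged as
debris; they would have been zero-count noise anyway, so totals are
unaffected.

## Validation and problem sizes

The test suite checks each stage against an independent oracle:
brute-force criterion scans for the threshold (200 random histograms),
flood fill for the labeling and double-loop summation for moments (50
random 64×64 masks), closed-form eccentricity for rasterized ellipses
(axis ratios 1–10 at semi-major 50 px, tolerance 0.02), generator ground
truth for size recovery (egg areas 60/150/400 px, tolerance 10%), debris
discrimination (exact), and end-to-end counts. The standard validation
suite (`validation_suite()`) is twenty 1024×1024 scenes of 20–700 eggs,
up to 30% in piles of 2–3, with grid, speckles and 0–3 debris; the
acceptance bands are ≤ 5% count error per scene and ≤ 2% mean — the
package's stand-in for the high-90s precision such a pipeline should
reach on clean photographs. These sizes keep a full run in the order of
a minute; `scripts/acceptance.R` reruns all of it from one seed and
writes the measured numbers as JSON.

## Known limitations

* One global threshold: strong illumination gradients will clip eggs or
  swallow background; the cap only handles bright glare.
* Pile counts rest on the area model `A ≈ n·S/C`; tall stacks (4+) and
  tight clumps violate it first.
* Eggs inside chromatic halos are lost to the debris rule by design.
* The egg-size estimate needs a few isolated eggs in the image; a photo
  of only piles stops with the no-candidates error.
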