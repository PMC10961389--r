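---
title: "Quantifying seed and seed-coat cell shape from silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed and seed-coat cell shape from silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(seedshape)
```

## The problem

Seed shape in *Silene* (and in seed morphometrics generally) is compared
across genotypes — ploidy levels, sexes, reciprocal hybrid crosses — from
binary silhouette images. Three complementary quantifications are in
standard use, and `seedshape` implements all three over a single outline
carrier:

1. **General morphological descriptors (GMDs)** — area, perimeter, length,
   width, circularity, aspect ratio, roundness and solidity — the scalar
   summaries of classical particle analysis.
2. **Similarity to geometric models (J index)** — the percentage of area a
   silhouette shares with a parametric reference curve (cardioid-derived
   models for the lateral view, modified ellipses for the dorsal view).
3. **Elliptic Fourier analysis (EFA)** — the outline as a truncated
   trigonometric series whose per-harmonic coefficient quadruples
   $(A_n, B_n, C_n, D_n)$ preserve all shape information, supporting both
   multivariate comparison and a bilateral symmetry coefficient.

A statistical layer (PCA with group centroids, one-way ANOVA with Tukey
letters, Wilks MANOVA, two-sample Kolmogorov–Smirnov, Levene and
Shapiro–Wilk checks) turns these into genotype contrasts, and a
deterministic synthetic generator emulates the study designs so that every
stage is testable without image downloads.

## Outlines from images

Images are binarized (fixed midpoint threshold by default — inputs are
expected to be binary already — with Otsu as an option), foreground
components are labelled with 8-connectivity, and each component's outer
boundary is traced as the 0.5 isoline of its mask (marching squares).
Tracing the inter-pixel isoline rather than pixel centres makes the
polygon area agree with the foreground pixel count to within half a
perimeter, which the tests verify on rasterized disks and rectangles.
Interior holes are discarded: the analysis concerns silhouettes. Objects
touching the image border are flagged (`border = TRUE`) and excluded by the
pipeline by default, since partial silhouettes corrupt every descriptor.

Raw traced boundaries carry a pixel staircase whose *absolute* amplitude
(a fraction of a pixel) does not scale with the object. Left in place, it
biases shape descriptors in a size-dependent way: the same shape
rasterized at 90 px and 117 px would differ systematically in circularity
and solidity, which is fatal when the scientific question is precisely
"does shape differ between a small and a large group?". `extract_outlines`
therefore applies one Chaikin corner-cutting pass followed by a Fourier
low-pass (default 24 harmonics, enough to keep 12-lobed cell outlines
intact). Truncation error depends only on the shape, not on the pixel
scale, so it cancels in group comparisons; on test shapes the residual
circularity bias between the two scenario sizes is about $3\times10^{-5}$,
and circularity of an extracted model outline matches its analytic value
to four decimals.

All coordinates are y-up (x = column, y counted from the bottom row), so
image-derived and analytic geometry share one frame, and all contours are
stored counterclockwise.

## Descriptors

All descriptors are computed exactly on the polygon — no rasterization:

* area by the shoelace formula; perimeter as polygonal arc length;
* length and width as the maximum and minimum caliper (Feret) diameters,
  exact on the convex hull;
* circularity $4\pi A / P^2$, clamped at 1 (digital contours can exceed
  the isoperimetric bound by discretization);
* aspect ratio and roundness $4A/(\pi\,\mathrm{major}^2)$ from the ellipse
  with the same second central area moments, computed from closed-form
  polygon moments;
* solidity $A / A_{\mathrm{hull}}$.

Length/width follow the caliper convention of particle-analysis software;
the aspect ratio deliberately uses the moments ellipse, which diverges
from the Feret ratio for lobed shapes — users comparing against
bounding-box conventions should know the two differ.

## Geometric models and the J index

The lateral models LM1/LM2 derive from the cardioid
$r = a(1+\cos\theta)$, optionally scaled by $k$ along the symmetry axis;
the dorsal models DM2/DM3 from an ellipse with the symmetric radial
modification $r \to r(1 + m\cos 2t)$. The published reference curves are
defined in external sources, so the registry ships plausible defaults
(LM1: $k=1$; LM2: $k=1.2$; DM2: $a/b=1.5, m=0.10$; DM3: $a/b=1.7,
m=0.15$), all overridable — reproducing a particular published curve is a
matter of supplying its parameters, not of editing code.

The J index is $100 \cdot A(S \cap M) / A(S \cup M)$ after superposition.
Two readings of "total area" exist; the union makes J symmetric and
bounded by 100 and is the default, with `denominator = "model"` available.
Superposition is similarity alignment: centroids matched, areas equalized,
principal (moment) axes aligned. The principal axis leaves a four-fold
ambiguity (180° flip × mirror), and all four branches are scored, keeping
the J-maximizing one; a brute-force rotation search over 0.5° steps agrees
with this alignment to within one J point in the tests. Intersection areas
use exact polygon clipping (a signed triangle-fan decomposition with
convex clipping, validated against an independent computational-geometry
library to eight decimals on random blobs), with a pixel-counting raster
fallback if clipping ever fails on degenerate geometry; polygon and raster
routes agree to well under one J point.

```{r}
m <- get_model("LM2")$contour
seed <- contour(m$points %*% matrix(c(0, 1, -1, 0), 2, 2) * 3, id = "seed")
j_index(seed, m)  # rotated, scaled copy: J = 100 up to numerical error
```

## Elliptic Fourier analysis

Coefficients follow the closed-form chain integrals of the piecewise-linear
arc-length parameterization. One point deserves emphasis because folklore
gets it wrong: the arc-length EFA of the 2:1 ellipse $x = 2\cos t$,
$y = \sin t$ is **not** $(2, 0, 0, 1)$ at harmonic 1 with nothing above —
constant-speed traversal of an eccentric ellipse is not sinusoidal in
either coordinate, and an independent quadrature oracle (dense trapezoid
integration of the defining integrals) gives harmonic 1 =
$(1.8284, 0, 0, 1.0730)$ with a genuine harmonic 3 of
$(0.1289, 0, 0, 0.0893)$. The implementation reproduces those values to
five decimals; $(2,0,0,1)$ would only arise if the angular parameter were
used as the Fourier parameter.

Normalization uses the standard first-harmonic procedure (starting point
moved to the semi-major axis, outline rotated so that axis lies along x,
optional size removal), after which $A_1 = 1$, $B_1 = C_1 = 0$. Two
numerical choices matter:

* the phase angle is determined only up to quarter turns, and for shapes
  whose first-harmonic ellipse is nearly circular the textbook formula can
  land on the semi-*minor* axis; all four quarter-turn candidates are
  evaluated and the major-axis pair kept;
* the residual 180° ambiguity is resolved by choosing the candidate whose
  higher-harmonic vector is lexicographically largest — a deterministic
  rule that is invariant because the candidate *set* is invariant. With
  it, normalized coefficients are stable to $10^{-15}$ under random
  rotation, translation, scaling and starting-point shifts.

**Harmonic selection.** The number of harmonics retaining more than 99 %
of cumulative power is computed as one `N` per analysis set (the mean
cumulative fraction across specimens; per-contour maxima would be
noise-driven), with a cap of 64. Two conventions exist for the power
fraction. Including harmonic 1 — the fitting ellipse, which carries
> 99.8 % of total power for any seed-like outline — makes the rule select
`N = 1` for near-elliptic populations; excluding it (the convention of
standard outline software, and the only one under which realistic
analyses settle on tens of harmonics) measures how much *residual* shape
detail is kept. `select_harmonic_count` exposes both through
`drop_first`; the pipeline uses `drop_first = TRUE`.

**Symmetry coefficient.** For a normalized outline mirror-symmetric about
its first-harmonic axis, $B_n = C_n = 0$; the AD/amp ratio
$\left(\sum|A_n| + \sum|D_n|\right) / \sum(|A_n|+|B_n|+|C_n|+|D_n|)$
is therefore 1 for symmetric outlines and decreases as asymmetry moves
power into the B/C columns. It must be computed on *normalized*
coefficients — on raw ones an arbitrary rotation shuffles power between
the columns and the ratio is meaningless. One subtlety: a bilateral
symmetry axis can be either of the two first-harmonic axes (for the plain
cardioid it is the short one), so the ratio is evaluated with the outline
aligned to each axis in turn and the larger value returned; without this a
perfectly symmetric cardioid would score 0.91 rather than 1. For density
plots across genotypes, `normalize_index_distribution` rescales each
group's values onto $[-1.5, 1.5]$.

```{r}
cd <- cardioid_contour(1, 1, 360)
symmetry_index(normalize_efd(efd_from_contour(cd, 20)))$sym
```

## Statistics

The statistical layer wraps the standard machinery (`aov`, `TukeyHSD`,
`ks.test`, `shapiro.test`, `car::leveneTest` with median centering —
the Brown–Forsythe variant, for robustness — and `prcomp`), adding:

* compact-letter displays assembled by insert-and-absorb from the Tukey
  pairwise p-values, re-verified against the pairwise matrix on every
  call;
* Wilks' $\Lambda$ MANOVA with Rao's F approximation, implemented directly
  so that the univariate case reduces *exactly* to the one-way ANOVA F
  (`stats::manova` refuses single responses); it is cross-checked against
  `summary.manova` in the tests, and Pillai's trace is available as an
  option;
* PCA with a fixed sign convention (largest-magnitude loading positive),
  group centroids, and per-PC variable contributions.

"PCA of the mean value" style figures overlay group centroids on specimen
scores rather than running PCA on the tiny matrix of group means; the
centroids are computed from the specimen scores.

Type-I error calibration is part of the test suite: the Tukey family-wise
error over 1000 null replicates and the MANOVA level over 500 stay within
two Monte-Carlo standard errors of 0.05.

## The synthetic generator

`population_spec` describes one genotype-like group; `generate_population`
draws it reproducibly (Mersenne–Twister, per-group seeds) and optionally
rasterizes each outline into a 512² 8-bit PNG with a ground-truth CSV.
Specimens are built from a registry base model by:

* a lognormal size draw (positivity; CV 0.08 by default);
* a truncated-normal elongation multiplier along the symmetry axis;
* a **lateral skew**: $x \to x + \delta^* (y/h)^2$ on the unit-size,
  axis-vertical outline. A skew, rather than independent vertex noise, is
  what produces a coherent B/C-column EFD signal — the thing the symmetry
  coefficient measures. The sign $\delta^*$ encodes the asymmetry regime:
  directional ($+\delta$ always; negative $\delta$ for left-directional),
  antisymmetric ($\pm\delta$ with equal probability, giving the bimodal
  signed distribution), fluctuating ($N(0, \delta/3)$), or none;
* radial roughness over harmonics 2–16. The spectrum deliberately reaches
  tubercle-scale frequencies: seed coats are not convex, and roughness
  confined to low harmonics would leave solidity degenerate at 1 — a point
  mass on which ANOVA is meaningless. With the default `noise_sd = 0.01`,
  solidity sits near 0.9985 with genuine within-group spread;
* a small placement tilt (SD 2°), mimicking manual seed positioning under
  the stereoscope rather than fully random orientation.

Cell outlines replace the skew by sinusoidal lobes
$r \to r(1 + a\sin(kt + \phi))$; solidity decreases monotonically with
lobe amplitude.

`signed_asymmetry` recovers the skew from an outline as the standardized
third central moment across the principal axis, with the 180° frame
ambiguity resolved by the along-axis skewness — robust for cardioid-like
(single-pointed) outlines, which is why the symmetry scenario uses the
lateral cardioid base; for outlines with two identical ends the *sign* is
unidentifiable in principle, though the magnitude is not.

Four presets encode the study designs, with group sizes defaulting to the
study's (100/80 seeds for the ploidy contrast, 31/80/34 for the symmetry
regimes, 16–20 per hybrid cross, 40 cells per group):

* `ploidy` — identical shape parameters, sizes 90 px vs 117 px (×1.3):
  size descriptors separate, shape descriptors must not. (90 px rather
  than something larger keeps a 4.5-σ lognormal tail inside the 512 px
  canvas; the generator refuses to shrink outlines silently.)
* `sex_symmetry` — directional-left ("male"), directional-right
  ("tetraploid") and antisymmetric ("female") groups at $\delta = 0.12$.
* `hybrid_maternal` — four reciprocal-cross groups whose elongation (and,
  secondarily, size) follows the maternal label.
* `cells` — smooth vs rugose lobe amplitudes.

What the generator does *not* emulate: imaging artifacts (uneven
illumination, soft focus, touching seeds), natural between-plant variance
structure, allometry, and any genuine genetic architecture. Passing the
scenario tests therefore shows the *pipeline* recovers the patterns it is
pointed at — not that real data will show them.

## Numerical choices and degenerate inputs

* Contours need ≥ 3 distinct vertices and nonzero area; clockwise input is
  flipped; duplicate consecutive vertices dropped.
* Resampling is chord-length interpolation. It is not exactly idempotent —
  equally spaced vertices on the old polygon are not equally spaced in the
  new polygon's chord metric — but re-application contracts by about two
  orders of magnitude per pass, which the tests assert.
* `j_index` falls back from polygon clipping to the raster method with a
  warning rather than failing.
* MANOVA refuses singular within-group covariance with advice to reduce
  dimension; the pipeline caps the EFD feature dimension below the
  residual degrees of freedom before calling it.
* Group labels may not be distinguishable inside Tukey pair names; levels
  are recoded internally and decoded afterwards, so labels containing
  hyphens are safe.

## Problem sizes

The test suite and the acceptance script run the scenarios at 40 specimens
per group (rasterized at 512², extracted, and analyzed end to end), the
Tukey calibration at 1000 null replicates and the MANOVA calibration at
500 — sizes chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well below the tolerances asserted.

## Limitations

* Only binary silhouettes are segmented; trainable segmentation, focus
  stacking and skeletonization of cell-wall images are out of scope — the
  package starts where a binary mask exists.
* Registry model parameters are placeholders for the published LM/DM
  curves; J-index values against the defaults are internally consistent
  but not comparable to values computed against the original curves.
* The symmetry coefficient folds all asymmetry into one number; it cannot
  distinguish directional from fluctuating asymmetry by itself — that
  distinction comes from the signed-asymmetry distribution.
* Mixed models with a per-seed random effect for cell outlines (several
  cells per seed) are not implemented; cells are treated as independent,
  which overstates the effective n when cells share a seed.
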