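---
title: "Models and methods in lineprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lineprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices behind
them, and what the synthetic-data validation does and does not
demonstrate.

## 1. The measurement: transverse profiles of filaments

A hollow, cylindrically labeled filament imaged side-on produces a
double-peaked transverse intensity profile.  The distance between the two
sidewall maxima — the peak-to-peak distance — is the quantitative readout
used throughout the package: it reports the labeled diameter of the
structure and, for physically expanded specimens, the molecular expansion
factor.

The tracing pipeline (`trace_filaments()`) follows the conventional
recipe for automated filament analysis in rendered localization images:

1. Gaussian blur (`blur_sigma`, default 20 nm) to bridge shot noise and
   labeling gaps in the rendered image;
2. automatic thresholding (Otsu by default; Li and a fixed threshold are
   selectable) to a binary mask;
3. hole filling (sparsely sampled tubes otherwise contain enclosed holes
   that become loops in the skeleton);
4. iterative thinning to a one-pixel-wide skeleton;
5. pruning of short side spurs (`spur_length`, default 300 nm) thrown off
   the centerline by boundary noise on thick tubes;
6. splitting at branch points, discarding of short chains
   (`min_length`, default 500 nm);
7. a cubic smoothing spline per chain, whose first derivative supplies
   the local tangent.

Perpendicular to the tangent, line profiles are sampled by bilinear
interpolation every `step` (default 25 nm) along the spline and averaged
into one profile per filament (`extract_profiles()`).

### Numerical choices in the tracing stage

*Thinning.*  The two-subiteration parallel thinning algorithm leaves
double-pixel staircases on diagonal runs; a deterministic simple-point
cleanup removes every redundant pixel whose eight-neighborhood forms a
single connected arc.  On rare adversarial inputs (an even-width X
crossing) no pixel is individually removable without locally splitting an
arm; the one-pixel-width guarantee is then enforced by removing one block
pixel deterministically.  One-pixel width is the contract the line
extraction relies on, so it wins over strict topology preservation in
that corner case.

*Branch points.*  A skeleton pixel is a branch point when its crossing
number — half the number of value changes around its eight-neighborhood
ring — is at least three.  This distinguishes true junctions from corner
pixels (three mutually touching neighbors, crossing number two), which
fragmented chains when a simple neighbor count was used.  Branch pixels
are dropped; every remaining pixel belongs to at most one path.

*Splines.*  Chains are parameterized by normalized chord length and each
coordinate is fitted by `stats::smooth.spline` with an explicit roughness
penalty (`smoothing`; `trace_filaments()` scales a base penalty of 1e-7
per path pixel).  Zero smoothing gives an interpolating natural cubic
spline.  The penalized fit guarantees that integrated squared curvature
is non-increasing in the penalty, which the test suite checks.

## 2. Cross-section models

`fit_profile()` fits five models by Levenberg–Marquardt least squares
(`minpack.lm`), all evaluated by `eval_model()`:

* Gaussian `h·exp(-(x-c)²/2w²) + b` — single unresolved profiles;
* bi-Gaussian (two components + offset) — the standard sidewall model;
  peak-to-peak distance is `|c2 − c1|`;
* tri-Gaussian — sidewalls plus a broad central background component;
  peak-to-peak uses the two outermost centers;
* cylinder — the exact projection of a uniform annulus with inner/outer
  radii `r1 < r2`; the piecewise condition is evaluated on `|x − c|` so
  the model is translation invariant;
* multi-cylinder — three concentric annuli tied to the 25 nm microtubule
  geometry through a shell-thickness parameter `a` and an expansion
  factor `e_x`, leaving fewer degrees of freedom.  For the cylinder
  models the peak-to-peak distance is the distance between the two maxima
  of the fitted curve, located numerically on a fine grid.

### Initialization and optimum selection

Fits of overlapping peaks depend strongly on their starting values, so
initialization is deterministic and explicit: candidate centers come from
the two highest local maxima of the lightly smoothed profile, with
half-maximum-based fallbacks; candidate widths are separation-scaled
(the conventional seeding for sidewall fits), per-peak half-maximum
widths, and a narrow "spike" width.  Every candidate is optimized.

Converged fits are screened for plausibility (centers inside the window,
widths at most half the window, nonnegative amplitudes).  Among plausible
fits whose residual lies within 30% of the best, the one with the
**smallest peak separation** is returned.  This tie-break does two jobs:
for merged profiles it keeps the conventional optimum that describes the
whole wall cross-section, and as the sidewalls sharpen it hands over
continuously to the sharp-peak optimum, keeping the predicted
peak-to-peak distance monotone in the expansion factor.  The tolerance of
30% was chosen so that the handover happens at the crossing point of the
two optima rather than abruptly.

Degenerate outcomes (collapsed widths, `r1 ≈ r2`) raise errors instead of
returning meaningless parameters.

### Window sensitivity

An overlapping-peak fit is mildly sensitive to how much flat background
the window contains, because the broad-component tails trade off against
the offset.  Two consequences:

* the forward model evaluates every profile on a standard window of
  `r_out + 5·sigma_loc + 25 nm` half-width with a **fixed number of grid
  points** (801), so the window — and with it the fitted peak-to-peak
  distance — varies continuously with the expansion factor; a fixed grid
  step would append points in discrete jumps and make the inversion
  jitter at the 1e-3 level;
* measured profiles should be extracted with a `half_width` comparable to
  that window when they are compared against predictions (the worked
  example in the README does this).

## 3. The cylindrical forward model

`predict_profile()` builds the transverse profile of a labeled,
optionally expanded microtubule in three steps:

1. place the fluorophores on a cylindrical shell around the 12.5 nm
   structure radius;
2. project the shell onto the transverse axis,
   `P(x) = 2 ∫ rho(r) r / sqrt(r² − x²) dr` (`project_shell()`;
   a uniform density gives the classic hollow-cylinder shape, a thin ring
   gives the arcsine projection, integrated exactly over each grid bin);
3. blur with the localization precision `sigma_loc`
   (`apply_precision()`).

`predict_p2p()` then fits the same bi-Gaussian used for measured
profiles.  Because the blurred shell projection has its maxima strictly
inside the outer shell radius, fits whose separation exceeds
`2·(r_out − sigma_loc/2)` are rejected as spurious; this physical bound
is what keeps the prediction monotone at high expansion, where an
unconstrained least-squares optimum drifts outside the shell.

### Labeling geometries

A `labeling_geometry` holds the structure radius (12.5 nm), the antibody
linker (17.5 nm for a primary + secondary IgG stack), an optional DNA
linker in bases, the conformation of the linker, and per-geometry
localization precision.  The two expansion flags encode the central
distinction between labeling routes: pre-expansion labels are embedded in
the gel and dilate with it (`expands_linker = TRUE`), post-expansion
labels keep their physical size.

The conformation field selects the effective fluorophore shell:

* **free** — unexpanded, unanchored label: averaging over label
  orientations pulls the effective fluorophore ring inward, to
  `structure_radius + orientation_factor × linker`.  The orientation
  factors (0.65 for IgG, 0.60 for DNA-modified IgG) are calibrated
  constants of the catalogue: they reproduce the unexpanded reference
  distances (≈32 nm for IgG, ≈41.5 nm for 42-base DNA antibodies)
  predicted by the simulation parameter set shipped with the package.
* **extended** — gel-anchored label: the linker is taut, the ring sits at
  the full radial extent; dsDNA contributes 0.34 nm per base (B-DNA
  rise; 42 bases ≈ 14.3 nm).
* **coiled** — single-stranded DNA that coiled during gelation: the DNA
  contribution is the worm-like-chain end-to-end distance
  `sqrt(2 × persistence × contour)` with 0.6 nm of contour per base and
  a persistence length of 2.5 nm (≈11.2 nm at 42 bases).  The
  persistence value is at the upper end of the ssDNA literature range,
  consistent with partial stretching of the strand inside the gel; it is
  a pinned catalogue constant.

Why a thin ring rather than a diffuse shell for the anchored geometries?
Empirically, a smooth annulus plus Gaussian blur is nearly
scale-invariant under bi-Gaussian fitting: the fitted peak-to-peak
distance scales linearly with the expansion factor and cannot reproduce
the observed strong nonlinearity between the unexpanded (~32 nm) and
expanded (~44 nm per expansion unit) regimes of IgG-labeled
microtubules.  A taut outer ring for gel-anchored labels, with the
orientation-averaged (pulled-in) ring for free labels, reproduces the
whole set of reference distances with two per-dye blur values
(`sigma_loc` = 6 nm for the rhodamine-class data sets, 9 nm for the
DNA/cyanine-class sets).  All of these constants live in
`inst/extdata/geometries.yaml` and are deliberately not hard-coded.

### Superposition and inversion

`superpose()` forms `ratio × pre + post` (renormalized) for specimens
carrying both pre- and post-expansion label; the shipped `pre_post_mix`
preset uses ratio 0.1, the expected ~10-fold dilution of pre-expansion
signal at ~3.2x expansion (the 2D projection dilutes with the square of
the linear factor).

`infer_expansion_factor()` inverts `predict_p2p()` by bracketed root
finding on [1, 10] (tolerance 1e-9).  The prediction is strictly
increasing on that range for every shipped preset (grid-checked at steps
of 0.5 in the test suite), so the root is unique; round-trip tests
recover the expansion factor to better than 1e-6.  Results are reported
at full precision and rounded to one decimal, the conventional reporting
precision for expansion factors.

## 4. Synthetic data

The generator emulates the statistical structure the analysis assumes:
smooth, well-separated, quasi-parallel filament stretches in a field of
view (default 20 × 20 µm); fluorophores placed on the geometry's
cylindrical shell at uniform arc position and azimuth; isotropic Gaussian
localization noise; uniform background.  Defaults — 600 localizations per
µm of filament, 2 background localizations per µm², curvature amplitude
0.005 (microtubule persistence lengths are millimeters, so filaments are
nearly straight at this scale) — were chosen once as realistic rendering
conditions for dSTORM-class data.

What the generator does **not** emulate: blinking kinetics and repeated
localizations of one fluorophore, detection-efficiency variation along
filaments (labeling gaps), filament crossings, drift or registration
artifacts, and astigmatic 3D localization errors (axial noise is
isotropic here).  Passing the end-to-end tests therefore demonstrates
that the pipeline is unbiased under its own model assumptions — not that
it is robust to every artifact of real specimens.

End-to-end closure: fixtures at expansions {1, 2, 3.2, 4} (two filaments
in an 8 × 8 µm field, counts-mode rendering at 5–10 nm pixels) are
traced, profiled and fitted, and the per-fixture mean peak-to-peak
distance agrees with `predict_p2p()` within 5%.  The residual deficit of
1–3% grows with tube width and stems from curvature-induced smearing of
the averaged profile — a bias real measurements share.

## 5. Known limitations

* Between the 0.5-step grid points of the monotonicity check, the
  predicted peak-to-peak distance of the 9 nm-blur presets can dip by a
  few percent in a narrow window around the optimum handover
  (expansion ≈ 4–6), outside the calibrated range of the catalogue.
  Inversion is therefore most trustworthy for the IgG presets and for
  expansions up to ~4, which covers the practical range.
* The bi-Gaussian readout is window-dependent at the few-percent level
  (Section 2); comparisons must use matched windows.
* Rendered-image tracing assumes filaments are at least ~3 pixels wide
  after blurring; the default 10 nm render pixel is chosen so the
  narrowest analyzed structure (~32 nm) satisfies this.
* The xz projection assumes the trace from the lateral projection is
  valid in every z plane, i.e. filaments lie roughly in the lateral
  plane.
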