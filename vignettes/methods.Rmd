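---
title: "Models, parameters and design choices in adaptreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in adaptreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adaptreg)
```

# Scope and conventions

`adaptreg` propagates planning-CT regions of interest (ROIs) onto a
per-treatment scan through a deformable registration, and evaluates the
result. All volumes are axis-aligned scalar grids; voxel indices are
0-based and `world = origin + index * spacing` with z the slice axis.
There is no orientation matrix: the package targets single-scanner axial
CT, where gantry-tilted or oblique acquisitions are out of scope.
Displacements are stored in mm (not voxels) so the common anisotropic
2 mm in-plane / 3 mm slice grids are handled uniformly, and every
displacement vector field (DVF) lives on the *target* (per-treatment)
grid in the pull-back convention: the warped image at target voxel x
samples the source at `world(x) + u(x)`. Out-of-grid samples clamp to the
border voxel so registration is not attracted to fictitious edge
gradients.

# The demons engine

## Force model

The fast symmetric demons variant is intensity-driven: assuming matched
histograms, corresponding anatomy has equal intensity, and each iteration
displaces voxels along the combined gradient of the fixed image `f` and
the currently warped moving image `m`:

$$u = \frac{2\,(f - m)\,(\nabla f + \nabla m)}
          {\lVert\nabla f + \nabla m\rVert^2 + \alpha (f - m)^2}.$$

Gradients are central differences in mm^-1 (one-sided at borders). The
normalization $\alpha = 1/\overline{s}^2$ ($\overline{s}$ = mean voxel
spacing) makes the two denominator terms dimensionally commensurate and
bounds the per-iteration step near $\overline{s}$; voxels whose
denominator falls below 1e-9 receive no update (uniform regions generate
no force). The published description names the fast symmetric variant
without printing the force, so this standard symmetric form is isolated
behind `demons_update()` where it can be swapped.

## Regularization, schedule, stopping

After each iteration the *total* field is smoothed with a truncated
Gaussian (radius 3 sigma, renormalized at borders so constants are
preserved) — diffusion-like regularization, matching the stated
per-iteration DVF smoothing. The default schedule is the published one:
pyramid levels at 4x/3x/2x/1x grid resolution ("4X to 1X" is read
literally as factors 4, 3, 2, 1), iteration caps 200/100/100/30, field
smoothing sigma 3/3/0.9/0.7 voxels. A level terminates early when the
mean relative change in intensity mean-square difference (MSD) over the
last 5 iterations (the stated "4 to 5") drops below 1.5 %. Between
levels the field is upsampled by component-wise trilinear interpolation;
mm units make rescaling unnecessary. Downsampling applies a Gaussian
anti-alias prefilter of 0.5 x factor voxels before subsampling.

Histogram matching precedes demons (the pipeline enforces the order):
a monotone piecewise-linear map fitted at 7 equally spaced *interior*
quantile levels read off 64-bin histogram CDFs. Interior-only match
points deliberately never pin the extremes, for robustness against
streak/contrast outliers; the map is accurate to about one bin width,
which is also the tolerance quoted in its contract.

## What a textureless phantom reveals

On the synthetic phantom the demons displacement error has a floor of
roughly 2 mm in the *interior* of the body, away from any intensity
structure. The per-voxel step $u \approx 2\delta g/(g^2+\alpha\delta^2)$
is scale-invariant when the residual $\delta$ and gradient $g$ are both
noise: shrinking the noise amplitude does not shrink the spurious step,
whose maximum over $\delta$ is exactly $1/\sqrt{\alpha} = \overline{s}$.
With the published fine-level smoothing (0.9/0.7 voxels) this noise-
driven walk equilibrates near one voxel of displacement wherever the
image is genuinely flat. Real CT has tissue texture almost everywhere, so
this is specifically a property of piecewise-constant phantoms; it is why
the phantom-recovery bound (mean body error below one mean voxel spacing,
2.33 mm) is met with a modest margin (about 2.0 mm on the default
phantom) rather than comfortably, and why coarse pyramid levels — which
average noise away — carry most of the large-scale recovery.

# The salient-feature engine (SFBR)

## Detection

Interest points with a centre and a scale are detected as
difference-of-Gaussians (DoG) extrema: the volume is smoothed at four
scales spanning 2–12 mm (geometric ladder; sigmas are converted per-axis
to voxels so anisotropic grids stay isotropic in mm), adjacent smoothed
volumes are differenced and normalized by the scale ratio, and a voxel
becomes a candidate if it is a strict extremum over its in-level
26-neighbourhood and the 27-neighbourhoods of the available adjacent DoG
levels. Ordering is fully deterministic (|response| descending, then
lexicographic centre), truncated to `target_anchor_count` (default 1500,
the typical clinical anchor count being 1000–2000).

Two standard hygiene filters follow, both exposed in `sfbr_params`:

* **Contrast floor** (`min_contrast_mad = 3`): candidates whose
  |response| is below 3 x the DoG level's median absolute deviation are
  noise blobs, not anatomy.
* **Ridge rejection** (`min_hessian_ratio = 0.1`): the 3D Hessian of the
  DoG at the candidate must have eigenvalue ratio
  min|lambda|/max|lambda| of at least 0.1. This is the 3D analogue of the
  classic DoG edge-rejection test. Without it the detector fires on
  structures that are translation-invariant along one direction (the
  body outline, the airway, the bony canal), whose matches then slide
  freely along the structure with correlation near 1 — the aperture
  problem, which the reliability threshold below cannot see.

## Matching and reliability

Each feature's intensity window (half-width 2 x scale per axis) is
correlated (zero-mean NCC) against target windows at every integer-voxel
displacement within a 15 mm search radius, then refined to sub-voxel
precision by a separable quadratic fit — skipped when the peak
correlation is already 1, since NCC is bounded by 1 and that is provably
the global optimum. A match is discarded if

* the best correlation is below the reliability threshold 0.80 (the
  published cut),
* the window leaves the grid or no candidate placement fits,
* the correlation surface has a second peak above 0.95 x the best more
  than 2 voxels away (`second_peak_ratio`): self-similar surroundings,
  e.g. two similar nodules inside one search box, make the
  correspondence ambiguous, or
* the displacement deviates from the componentwise median of its 8
  nearest retained anchors by more than 6 mm (`consistency_tol_mm`): the
  true deformation is smooth (bump scales of 30 mm or more, amplitudes
  of 8 mm or less, hence neighbour-to-neighbour variation well under
  6 mm), so an isolated discordant vector is an outlier. Ties in the NCC
  search prefer the smaller displacement, keeping matching deterministic.

On the default phantom these filters retain on the order of 90 anchors
with sub-millimetre median error; on clinical-resolution data with real
texture the counts would be far higher.

## Thin-plate-spline interpolation

Retained correspondences are interpolated with a 3D thin-plate spline:
affine part plus kernel sum with U(r) = r, the 3D biharmonic fundamental
solution (r^2 log r is the 2D kernel and would be wrong here). The
bordered linear system enforces the polynomial side conditions
(P^T w = 0, asserted to 1e-8 after every fit); lambda = 0 (the default)
interpolates every anchor exactly, and degenerate (coplanar) anchor sets
are rejected by a rank check. ROIs propagate as meshes: the planning
mask's surface is extracted, vertices are mapped by the spline, and the
warped mesh is rasterized on the target grid. Converting the spline to a
dense DVF is deliberately not implemented — contour propagation does not
need it.

# Contour propagation and its discretization limits

`propagate_mask` (demons path) uses nearest-neighbour lookup — each
target voxel takes the planning mask value at its displaced position —
matching the described mask lookup exactly, rather than
interpolate-and-threshold. Work is restricted to the source bounding box
dilated by `ceil(max|u|/spacing) + 2` voxels, a margin that provably
contains every voxel the full-grid computation could set, and the
equality is tested against a full-grid loop oracle.

`extract_mesh` builds the exact voxel-face (cuberille) surface: the 0.5
iso-surface of the nearest-neighbour mask field. It is closed by
construction, and its enclosed volume equals the voxel count times the
voxel volume *exactly* — no marching-cubes approximation error. Edges
shared by four triangles occur where mask voxels touch diagonally; the
surface is still watertight, so the closedness check accepts even
edge-sharing counts. Optional Taubin smoothing (`smooth_iterations`,
shrinkage-compensated Laplacian, default 5 passes in the pipeline's SFBR
path) removes the voxel staircase before warping; this raises
warp-then-rasterize fidelity substantially (e.g. true-deformation cord
Dice from 0.86 to 0.89, parotids from 0.93 to 0.96) while keeping the
identity round trip exact.

`rasterize_mesh` classifies voxel centres by ray parity along +x with
boundary hits counting as inside. Ray positions are nudged by two
*different* tiny fractions of the spacing in y and z: equal fractions
would place every ray exactly on the shared diagonal direction of the
quad triangulation, a degenerate measure-zero configuration that a
uniform nudge cannot escape.

A bound worth stating precisely: propagating a mask with the *true*
deformation and comparing against the analytic ground-truth mask stacks
two discretizations (voxelizing the planning organ, then nearest-
neighbour lookup). The resulting Dice exceeds 0.95 only for structures
roughly 10 voxels across or more; the phantom's spinal cord is about 5
voxels across at 2 mm spacing and plateaus near 0.86. This is a property
of masks on clinical grids, not of any estimation error — thin-structure
Dice saturates below 1 even for a perfect registration, which is worth
remembering when reading per-organ tables.

# Agreement metrics

* **Dice**: exactly 2|A∩B|/(|A|+|B|) on voxel counts.
* **MSHD**: per axial slice, the symmetric Hausdorff distance between
  the two masks' 2D boundaries, averaged over every slice where the
  *reference* mask is present. Boundaries are represented by boundary
  voxel centres (a voxel with any 4-neighbour outside the mask) — a
  reproducible, oracle-checkable choice, since sub-voxel contour
  geometry is not recoverable from masks. When the propagated mask is
  absent on a reference slice the slice value is the directed max-min
  distance from the reference boundary on that slice to the propagated
  mask's full 3D boundary: gross under-propagation (the clinically
  observed receding parotid) is penalized instead of silently skipped.
* **COM displacement**: difference of unweighted member-voxel centroid
  positions, reported with its Euclidean norm; by convention tabulated
  for GTVs, where it has isocentre implications.

All three are invariant under a common integer-voxel translation of both
masks, and the metric implementations are tested against brute-force
all-pairs/loop oracles to 1e-9 mm.

# Study statistics

One-way ANOVA uses the classical between/within decomposition with
p from F(k-1, N-k); degenerate inputs follow fixed conventions (zero
between-variance gives F = 0, p = 1; zero within-variance with unequal
means gives F = Inf, p = 0, flagged). The point-biserial correlation is
computed from the group-mean formula and equals Pearson correlation on
the 0/1 coding by identity — both facts are asserted (F = t^2 against a
hand-written pooled t, r_pb against `cor`) rather than assumed. Scores
dichotomize as {1, 2} versus {3} (useful versus needs-major-edits);
two-sided p-values are reported, and reported percentages round to the
nearest integer (202/216 = 93.52 % prints as 94 %). ANOVA grouping in
`aggregate_study` is per organ and metric with the two algorithms as
groups, the grouping the published comparison implies; it is implemented
over a configurable metric list.

# The phantom: what it emulates and what it does not

The planning phantom is an analytic scene — elliptical soft-tissue body,
low-intensity pharyngeal tube, spinal cord inside a bony ring, brainstem
above the cord, two parotid ellipsoids, a three-lobed GTV resting on the
airway (as clinical GTVs often do), and around 60 small high-intensity
nodules that stand in for the vessels/nodes that give feature-based
matching its anchors. Default grid 96 x 96 x 48 at 2/2/3 mm (slice
thickness inside the clinical 2–3 mm range), additive Gaussian noise
with SD 15 intensity units — a realistic soft-tissue CT noise level —
and all geometry seeded and deterministic.

The deformation is a sum of Gaussian bumps (30–40 mm scales, amplitudes
chosen so the total field peaks at 8 mm on the default grid), a radial
GTV shrinkage of factor 0.7 (full strength within 16 mm of the GTV
centre, cosine-tapered to zero by 32 mm) emulating tumour regression —
the ground-truth GTV volume contracts by about 0.7^3 — and a 6 mm
medial push on the right body surface, a scaled-down analogue of the
strong-responder case whose surface receded by centimetres. The field is
analytic, so per-treatment images and ground-truth masks are rendered by
evaluating the scene at the pulled-back points exactly — there is no
stored-grid interpolation anywhere in the truth. Invertibility is
enforced numerically (minimum Jacobian determinant above 0.1) before any
rendering.

What the phantom does *not* emulate: CT texture inside tissues (hence
the demons noise-floor discussion above), contrast enhancement, dental
artifacts, couch structures, and inter-observer contouring variability —
the reference masks here are exact, so a green phantom test establishes
algorithmic correctness, not clinical accuracy against a human
standard.

# Numerical choices and degenerate inputs

* Truncated Gaussians everywhere use radius 3 sigma with per-position
  renormalization: constants are preserved exactly, and interior means
  to machine precision.
* Rigid pre-registration optimizes zero-mean NCC (robust to contrast
  differences; the published text says only "cross-correlation") with a
  deterministic coarse-to-fine search: a translation grid at the
  coarsest pyramid level, then coordinate descent over all six
  parameters with halving steps, never returning a transform scoring
  below the identity. Constant images are rejected (NCC undefined).
* Histogram matching knots are forced strictly monotone by an epsilon
  ramp so the piecewise-linear map is well defined even when quantiles
  tie.
* Empty masks error in every metric; a propagated mask that is empty
  errors in MSHD rather than scoring 0 silently.
* The matcher's sub-voxel refinement clamps offsets to half a voxel and
  falls back to the integer optimum when the quadratic is flat.

# Known limitations

* DICOM RT-STRUCT I/O is out of scope; contours are exchanged as NIfTI
  masks and PLY meshes (minimal uncompressed NIfTI-1/MetaImage
  readers/writers are built in, as no suitable R package was available
  in the target environment).
* The demons engine is the classic additive variant: no diffeomorphic or
  log-domain guarantees, no multi-modality metric.
* SFBR assumes a rigid pre-alignment good to the search radius (15 mm)
  and has no rotation-invariant descriptors; per-feature matching is
  independent, with only the local consistency filter providing spatial
  coherence.
* Reported timings are informational only — they are hardware-dependent
  and never enter any assertion.
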