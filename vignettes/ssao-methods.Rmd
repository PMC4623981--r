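---
title: "Multi-scale screen-space ambient occlusion: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale screen-space ambient occlusion: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molssao)
```

## The model

Ambient occlusion treats the sky as a uniform hemispherical light source.
For a surface point $p$ with unit normal $n_p$, the occluded fraction is

$$A_p \;=\; \int_\Omega \rho\!\left(L(p,u)\right)\, (n_p \cdot u)\, du,$$

with $L(p,u)$ the distance to the nearest obstacle in direction $u$ and
$\rho$ the blocking function. We take $\rho$ binary — a ray either hits
geometry within a finite range or it does not. A distance-weighted falloff
would be a plausible refinement, but since no particular falloff is
canonical we prefer the parameter-free choice; the occlusion range (half
the sampling-sphere diameter) already provides the locality control that a
falloff would otherwise supply.

The screen-space approximation never evaluates this integral directly. It
works on the rendered image: each pixel stores a color and the *linear
eye-space distance* (in Å) of the nearest surface. Around a pixel's
back-projected 3D position a sampling sphere of diameter $D$ is placed,
and the depth buffer decides which parts of the sphere lie behind known
geometry. The hidden fraction $r$ estimates how enclosed the point is
*at the scale $D$*: small spheres see crevices and pockets, large spheres
see basins and channels. This scale-selectivity is the purpose of the
method.

### From hidden fraction to occlusion coefficient

Half of any sphere lies behind the tangent plane of an open flat surface,
so $r = 1/2$ carries no information about concavity. We therefore store

$$A \;=\; \mathrm{clamp}\!\left(2\,(r - \tfrac12),\, 0,\, 1\right),$$

which maps open flat geometry to $A = 0$ (rendered unchanged), a
half-space-blocked point (a wall) to $\approx 1/2$, and full enclosure to
$1$. Convexity ($r < 1/2$) clamps to $0$ rather than brightening. The
final image is $\text{color} \times (1 - \text{intensity}\cdot A)$ per
channel. Without this renormalization every surface would be uniformly
dimmed by the $1/2$ baseline and the intensity slider would conflate
brightness with contrast.

## Point sampling

`ao_point()` draws $n$ offsets uniformly in the unit ball, scales them by
$D/2$, projects each sample to the image and compares its depth with the
depth buffer at the pixel it lands in (nearest-pixel lookup — interpolated
depth across silhouettes would invent geometry). Samples landing
off-image or on background count as visible, as do samples more than
`range_factor * diameter` behind the stored surface (the *range check*,
on by default): without it a foreground molecule casts a spurious dark
halo onto unrelated distant geometry.

Two deliberate refinements of the naive estimator:

* **Depth-stratified kernel.** Half the kernel offsets lie in the front
  half-ball, half in the back (independent draws; the ball marginal is
  unchanged). On an open screen-parallel surface exactly half the samples
  are then hidden, so $r = 1/2$ *exactly* and flat geometry renders
  bit-for-bit unchanged. An unstratified kernel leaves binomial noise of
  s.d. $\tfrac12/\sqrt{n}$ which the clamp rectifies into a persistent
  brightness bias of roughly $2\sigma/\sqrt{2\pi} \approx 0.05$ at
  $n = 64$ — visible as a grey veil that no amount of blurring removes,
  because it is a bias, not noise.
* **Per-pixel randomization about the view axis.** A fixed kernel
  produces banding: neighboring pixels cross sampling thresholds
  coherently. We decorrelate pixels by rotating the kernel about the view
  axis by a hashed angle and mirroring it with probability $1/2$, both
  derived deterministically from `(seed, pixel x, pixel y)`. Restricting
  the randomization to view-axis rotations (rather than arbitrary 3D
  rotations) preserves each offset's depth component and hence the exact
  flat-surface balance above; on non-flat geometry the depth-buffer
  lookups differ per rotation, so the randomization still converts
  banding into high-frequency noise.

That noise is then removed by a separable box blur (default $7\times7$,
clamp-to-edge at the borders), applied to the coefficient map before
modulation. The separable two-pass form equals the direct 2D convolution
exactly on interior pixels.

## Line sampling

`ao_line()` replaces random points with view-aligned chords. A chord at
disk offset $o$ ($|o| < 1$) has half-length $h = \sqrt{1-|o|^2}$ and spans
eye depths $[d - hR,\, d + hR]$ ($R = D/2$, $d$ the pixel's depth). The
depth buffer value $z$ at the chord's pixel clips it; the hidden fraction
is the max–min expression
$f = \mathrm{clamp}\!\big((z_{far} - \max(z_{near}, z)) / (z_{far} -
z_{near}),\,0,\,1\big)$, which we evaluate in the equivalent signed form
$f = \tfrac12 + \mathrm{clamp}\!\big((d - z)/(2hR),\, -\tfrac12,
\tfrac12\big)$ so that a flat surface ($z = d$ everywhere) accumulates an
excess of exactly zero with no floating-point residue. Chords are laid
out on a deterministic sunflower spiral including the disk center and
weighted by their chord length (their share of the sphere's volume);
the low-discrepancy layout needs no per-pixel randomization and no blur.
Off-image, background and range-rejected chords fall back to the flat
baseline $f = 1/2$ so image borders neither brighten nor darken.

Line sampling yields continuous values where point sampling is quantized
to $\{0, 1/n, \dots, 1\}$ — at equal $n$ it produces far more distinct
levels (measured: 7–8× on a step edge seen at a slight tilt), which is
why it is the package default.

## Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `mode` | — | `line` | point or line sampling |
| `diameter` | Å or px | 8 | sampling-sphere diameter; the feature scale emphasized |
| `diameter_unit` | — | `angstrom` | object-space (scale-true) or screen-space (zoom-dependent) |
| `intensity` | — | 1 | darkening strength in $[0,2]$ |
| `n_samples` | count | 64 / 32 | points or chords per pixel |
| `seed` | — | 1 | drives kernel and per-pixel randomization |
| `range_check`, `range_factor` | —, ×D | on, 1 | suppress false halos from distant geometry |
| `blur_width` | px | 7 | box blur width (point mode; 1 disables) |

The Å diameter is the scientifically meaningful mode: a 4 Å sphere
highlights binding-pocket-sized features regardless of zoom, which is the
regime shown in the worked examples. The pixel mode reproduces the
qualitative zoom-dependent slider behavior of interactive viewers.

## Rendering front end

The rasterizer exists to produce exact inputs for the post-process.
Spheres are drawn as analytic per-pixel impostors (ray–sphere
intersection at every covered pixel center), so silhouettes and depths
carry no tessellation error and can be checked against closed forms.
Triangle meshes use a top-left fill rule (shared edges written exactly
once), barycentric depth (perspective-correct under a perspective
camera) and per-pixel Phong shading on interpolated normals. The depth
test is strict less-than with ties broken toward the lower primitive
index, which makes rendering independent of primitive submission order.
Depth is always linear eye-space distance in Å — not a hyperbolic device
coordinate — so depth differences are scene distances and the sampling
sphere has its nominal size everywhere. Pixel $(i,j)$ covers
$[i,i+1)\times[j,j+1)$ with center $(i{+}0.5, j{+}0.5)$, origin top-left,
$y$ downward.

Isosurfaces are extracted by marching tetrahedra: each grid cube is split
into six tetrahedra sharing the main diagonal, with a face-consistent
decomposition across neighboring cubes, so the mesh is watertight by
construction and has no ambiguous configurations; vertices are linearly
interpolated (exact on linear fields) and normals come from the negated
central-difference density gradient. We chose marching tetrahedra over
the classic 15-case cube table deliberately: the handful of tetrahedral
cases can be derived and audited by hand, and watertightness — which the
cube table only achieves with extra disambiguation — is what the mesh
consumers here actually rely on. The cost, more triangles and a mild
(few-percent) surface-area overestimate at coarse voxels, is irrelevant
to occlusion testing.

## The oracle and the reference scenes

`brute_force_ao()` evaluates the hemisphere integral by Monte Carlo with
cosine-weighted directions (unit-disk mapping, so the $n_p\cdot u$ factor
is absorbed into the sampling density; standard error $\sim 1/\sqrt{n}$).
Closed forms anchor it: an open plane gives $0$; the bottom of a
hemispherical pit gives $\tfrac12$ (rays steeper than $45^\circ$ exit the
bowl, and the cosine-weighted measure of the rest is
$\cos^2 45^\circ = \tfrac12$); a point on the edge of a right-angle
corner with an infinite wall also gives $\tfrac12$.

When the oracle is compared against SSAO its range is capped at $D/2$,
because the screen-space estimate cannot see farther than its sampling
sphere. This cap shapes the reference-scene geometry: a hemispherical pit
of radius $\rho$ keeps its full closed-form value $\tfrac12$ only if the
range is at least $2\rho$ (the longest wall chord from the bottom), so
the bridge uses a pit of radius half the dominant feature width; and a
point at the very base of a wall is half-blocked regardless of range, so
the corner sample sits half a radius out from the wall, where the wall
blocks a substantial but clearly sub-half fraction ($\approx 0.34$).
These placements, derived from the closed forms before any screen-space
comparison, give the strict oracle ordering pit > corner > flat = convex
with comfortable margins, which both SSAO modes reproduce with Spearman
$\rho = 1.0$ (values are quantized to $0.05$ before ranking so that the
two genuinely-zero scenes tie in both rankings rather than being ordered
by noise).

## Synthetic fixtures

All test inputs are generated: stacked atom rings forming an open channel
(the pore-versus-outer-surface contrast), random van der Waals clusters,
an idealized α-helix, pseudo-EM maps built as sums of atom-centered
Gaussians with $\sigma = \text{resolution}/(\pi\sqrt{2})$ on a grid
padded by $3\sigma$, and a two-scale analytic cavity field — a 40 Å
basin, 8 Å deep, whose floor carries a 3×3 grid of 4 Å pits, 2 Å deep,
with disjoint region masks. On that scene the pit/basin contrast is
higher at $D = 4$ Å than at $D = 40$ Å while the basin-wide mean
occlusion is higher at 40 Å: the two scales are picked apart by the
diameter alone.

What the fixtures do *not* emulate: real molecular surfaces' roughness
statistics and self-occlusion at many simultaneous scales, solvent or
map noise, and any geometry outside the view frustum. Passing tests
demonstrate the estimator's geometric response, not photometric realism
on arbitrary structures.

## Numerical choices

* Background depth is $+\infty$, so any finite sample depth classifies
  as "in front of background" without a far-plane constant.
* Before the post-process runs inside `render`, the framebuffer is
  quantized to its serialized precision (8-bit color, 32-bit float
  depth). This makes `ao-apply` on saved buffers reproduce the in-process
  pipeline bit-exactly — the factorization claim is testable as byte
  equality, not approximate agreement.
* Blur borders use clamp-to-edge replication; degenerate isosurface
  triangles (area $\le 10^{-12}$ Å²) are dropped and duplicate
  edge-vertices merged by exact grid-edge identity, not coordinate
  rounding.
* All stochastic components (kernel, per-pixel hash, oracle rays,
  jittered fixtures) are pure functions of an integer seed; repeated
  calls never consume or perturb the caller's RNG state.

Test problem sizes were chosen for tight oracle comparisons at
interactive cost: images of 96–256 px, $10^5$ oracle rays for closed
forms, 256 samples/pixel for bridge comparisons, scenes of ≤ 10,000
primitives for the complexity-independence check.

## Known limitations

A single depth layer means occluders hidden behind the front surface are
invisible to the estimate, and geometry outside the image contributes
nothing — zoomed-in crops lose occlusion from clipped structure. There
is no transparency, no multi-layer depth peeling, no temporal filtering,
and no directional (bent-normal) occlusion. The estimator is a shading
heuristic calibrated against the hemisphere integral on analytic scenes;
it is not an illumination solver.
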