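---
title: "Methods: inferring 3D cell shape statistics from 2D slices"
author: "cellslice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring 3D cell shape statistics from 2D slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellslice)
```

# The inference problem

In a confluent tissue, cells tile space without gaps. Vertex-like models
predict that the dimensionless 3D shape index
$$p^{3D} = S / V^{2/3}$$
(surface area over volume to the two-thirds) controls whether such a tissue
behaves as a fluid or a solid. Measuring $p^{3D}$ directly requires full 3D
segmentation, which is fragile and often impossible (histological sections,
deep tissue, fast neighbor exchanges). `cellslice` instead infers the *mean*
$p^{3D}$ from the distribution of 2D shape descriptors measured in thin,
randomly oriented slices — a stereological approach: simulate the 3D
ensemble once, tabulate what its slices look like, then match experimental
slice statistics against that reference.

The observable in 2D is the shape index of each cell cross-section,
$$p^{2D} = L / \sqrt{a},$$
with perimeter $L$ and area $a$, bounded below by $2\sqrt{\pi} \approx 3.545$
(the circle). An alternative bounded descriptor is the anisotropy index $m$:
the polygon's central second-area-moment tensor
$G = \int v \otimes v \, dA$ has eigenvalues $\lambda_{1,2}$, and
$m = (\lambda_{\max}-\lambda_{\min})/(\lambda_{\max}+\lambda_{\min})$.

# The 3D Voronoi model

Cells are the Voronoi regions of $N$ center points in a fully periodic box;
centers move to minimize

$$E = k_S \sum_i (S_i - S_{0i})^2 + k_V \sum_i (V_i - V_{0i})^2,$$

with per-cell target surface areas $S_{0i}$ and volumes $V_{0i}$, and
$k_S = k_V = 1$ (their values are immaterial in the fluid regime, where the
targets are attained exactly and $E \approx 0$). The box volume is fixed at
$\sum_i V_{0i}$; homogeneous targets use $V_0 = 1$, $S_0 = p_0$, so lengths
are measured in units of the mean cell diameter. Homogeneous targets are
attainable for $p_0 \gtrsim 5.41$; below that floor the packing is *pinned*:
energy stays positive and the realized mean shape index stops near 5.4,
because more compact disordered packings do not exist. Above about 6.4,
near-degenerate (multifold) vertices proliferate and minimization becomes
unreliable, so target shape indices are restricted to $[5.4, 6.4]$.

## Tessellation

Each Voronoi cell is built by incremental half-space clipping of a seed cube
against the perpendicular bisectors of the 27 periodic images of all other
centers, processed nearest-first with the standard closure bound (a
generator at distance $d$ cannot cut the cell once $d/2$ exceeds the current
farthest vertex). Volumes come from the divergence theorem over
fan-triangulated faces, areas from the triangle sum; cells tile the box to
near machine precision, which the test suite asserts at $10^{-8}$ relative.
Centers closer than $10^{-9}$ box lengths are rejected as degenerate.

## Energy gradient

The paper-level description of the model does not prescribe a derivative, so
both routes are implemented.

* **Analytic (default).** Every Voronoi vertex is the circumcenter of its
  four generators; by the implicit function theorem its Jacobian with
  respect to generator $g$ is rank-one, e.g.
  $\partial v/\partial g_m = (A^{-1} e_m)(g_m - v)^T$ where the rows of $A$
  are $g_k - g_0$. Chaining these with the per-vertex gradients of each
  cell's $V$ and $S$ gives $\mathrm{d}E/\mathrm{d}(\text{centers})$ at the
  cost of roughly one tessellation.
* **Central finite differences** over full re-tessellations, step
  $h = 10^{-5}$ box units: unambiguous but $\sim 6N$ times slower; it serves
  as the reference in tests, which require agreement within $10^{-4}$
  relative. The analytic route is the default because the
  packing-generation-heavy studies would otherwise take hours instead of
  minutes.

At configurations where more than three faces meet in a vertex the energy
landscape has kinks and neither derivative is well defined; FIRE treats the
resulting force as approximate and such states are handled by protocol (next
section) rather than by derivative heroics.

## Minimization protocol

FIRE (fast inertial relaxation engine) with the standard published
constants: $\mathrm{d}t_0 = 0.01$, $\mathrm{d}t_{\max} = 0.1$, $f_{inc} =
1.1$, $f_{dec} = 0.5$, $\alpha_0 = 0.1$, $f_\alpha = 0.99$, $N_{\min} = 5$;
convergence at force infinity-norm $10^{-4}$, budget 5000 steps (2000 for
bulk library generation, where target attainment is checked explicitly).
These are recorded choices, not values inherited from the reference method,
which reports none.

Two protocol details matter in practice:

* **Target ramp.** For $p_0 > 6.2$, direct minimization from random centers
  frequently lands in cusp-like local minima (stuck at $E = O(1)$ with
  conflicting one-sided gradients). Relaxing first at $p_0 = 6.2$ and then
  re-relaxing while stepping the target up by 0.05 reaches $E \approx 0$
  reliably — a quasi-static ramp through fluid states.
* **Extension before reseeding.** States that end the step budget with tiny
  energy but a few cells marginally off target are continued rather than
  regenerated; truly stuck states are restarted from a fresh seed (up to 10
  attempts).

`generate_packing()` verifies fluid-regime fidelity (at most 1% of cells
missing $p_0$ by more than 0.02) for homogeneous targets above the pinning
floor, and applies accept/reject on the realized mean and s.d. of the
achieved shape index (tolerances 0.02 / 0.03, as generation parameters) for
Gaussian heterogeneous targets, whose draws are truncated to $[5.4, 6.4]$.

# Slicing

Slices are infinitesimally thin planes (a `thickness` extension hook exists
conceptually but only thickness zero is implemented; finite optical sections
are out of scope). Planes are drawn isotropically — normal uniform on the
sphere, offset uniform over the box support — and intersected *exactly* with
every periodic image of every convex cell, producing convex polygons with
closed-form perimeter, area, centroid and moment tensor. Replacing the
rendering-plus-segmentation route of the reference method with exact
geometry removes pixelization as an error source entirely.

Two boundary rules are provided:

* `"centroid"` (default, used for all reference statistics): a cross-section
  polygon is kept, whole, iff its area centroid lies inside the box
  cross-section. This associated-point rule is the standard unbiased
  stereological sampling rule; it produces no boundary-truncated fragments,
  which would otherwise contaminate the $p^{2D}$ distribution (a plane
  section of a periodic box is not itself periodic, so fragments cannot be
  reassembled by wrapping).
* `"clip"`: polygons clipped to the box section tile it exactly (areas sum
  to the section area at $10^{-8}$ relative), which is the invariant the
  tests use; clipped fragments are flagged.

A cell cut more than once by one plane (via different periodic images)
contributes each piece separately, as an image would show it.

# Reference libraries

A library holds, for each value of the 3D descriptor ($p^{3D}$, or the
inscribed-sphere volume fraction $f_R$ computed exactly as the Chebyshev
center of the cell's face half-spaces), the raw sorted sample set of the 2D
descriptor with paired areas. Raw samples — not histograms — are stored
because the K-S statistic needs the empirical distribution function
exactly, and binning would discard information.

The reference scale of the original study is 20 grid values, 30,000 sliced
cells per value, packings of roughly 40 cells. The scaled-down defaults here
keep the full 0.05 grid spacing from 5.4 to 6.4 (21 points; needed to
resolve the ~1% errors the studies quantify) but about 2,000 sliced cells
per point from 48-cell packings, with 40 random planes per packing. Slices
of one packing reuse the same few dozen 3D cells, so samples are correlated;
many independent packings per grid point and many plane orientations keep
this mild, and the acceptance checks pass at this scale. Building at full
scale is a parameter change (`cells_per_point`, `n_cells`), not a code
change.

Peak location $\bar p^{2D}$ and half-width at half maximum are extracted
from a Gaussian-kernel KDE (Silverman's bandwidth, overridable); these
summaries are used instead of mean/variance because slices nearly parallel
to a polyhedral edge produce arbitrarily elongated cross-sections — a
divergent tail that carries almost no information about $p^{3D}$. Competing
modes within 5% of the peak height trigger a warning and the global mode is
returned.

# Kolmogorov–Smirnov estimation

The K-S distance between data $\{X_i\}$ and a reference member is
$D = \max_x |C_{emp}(x) - C(x)|$, the exact supremum over the step
discontinuities of both empirical distribution functions (the reference CDF
is the EDF of its stored samples; no smoothing inside the statistic). The
estimate is the grid value minimizing $D$ — grid-valued, no inter-grid
interpolation, matching the discrete estimates of the reference method; exact
ties resolve to the lower value with a warning. The goodness-of-fit statistic
$\sqrt{N} D$ is reported for comparison with standard K-S tables.

## Measurement-error models

Three tracing-error models transform the *reference* distributions by
default (the data stay untouched), with a `direction = "data"` flag for
error-propagation studies that corrupt synthetic data against a clean
library:

* systematic perimeter overestimate $\Delta L$: samples scaled by
  $1 + \Delta L$, the exact change of variables
  $P(p^{2D}) \to P(p^{2D}/(1+\Delta L))/(1+\Delta L)$;
* random perimeter error $\sigma_L$: each sample multiplied by an
  independent $1 + \mathcal N(0, \sigma_L)$ factor (a multiplicative
  Gaussian convolution), seeded as part of the call contract;
* small-area cutoff $a_m$: entries with $a < a_m \bar a$ removed, using the
  paired areas stored in the library.

Independent error sources combine approximately: systematic shifts add,
random errors add in quadrature.

## Mixtures and heterogeneity

For a tissue of subpopulations $\beta$ with volume fractions $f^V_\beta$
and mean cross-section areas $\langle a\rangle_\beta$, the slice-abundance
weights are
$$f_\beta = \frac{f^V_\beta / \langle a\rangle_\beta}
                 {\sum_\alpha f^V_\alpha / \langle a\rangle_\alpha},$$
(larger cells are cut more often), and the predicted 2D distribution is the
$f_\beta$-weighted superposition of the member distributions. The pooled
sample set is drawn deterministically by quantiles, so the construction is
reproducible without an RNG. Off-grid component values are quantile-wise
interpolations between bracketing members, with a warning.

## Sensitivity

$\mathrm{d}D/\mathrm{d}\delta$ — the K-S distance between members $\delta$
apart, over $\delta$ — quantifies how sharply the 2D distribution responds
to the 3D descriptor. When a member at $\delta/2$ exists, linearity is
checked by halving and deviations beyond 20% attach a warning. Reliable
values need large members ($n \ge 10^4$), because the sampling noise floor
of $D$ adds to the true separation. For the volume-heterogeneity comparison,
the reference text reports a ratio ("about 10%") whose normalization is
ambiguous; it is not used as a quantitative target here.

# Direct 3D measurement of labeled volumes

For experimentally segmented tissue, `measure_labels_3d()` measures each
label of an integer voxel image: volume as voxel count times voxel volume,
surface from an iso-surface at level 0.5 of the binary mask, triangulated by
marching tetrahedra (six-tetrahedra Kuhn decomposition per voxel cube; no
case-table ambiguities). On raw binary data any midpoint iso-surface
overestimates area by tens of percent (staircase bias), so the mask is first
smoothed with a small Gaussian; wide kernels instead round off polyhedral
edges. The default $\sigma = 0.7$ voxels balances the two biases, keeping
$p^{3D}$ within about 2% for both digitized spheres and rasterized Voronoi
cells at 30+ voxels per cell diameter — the internal cross-validation that
stands in for external segmented data, which is out of scope. For true
refinement studies the smoothing length should shrink in physical units as
resolution grows ($\sigma \propto \sqrt{\text{scale}}$ in voxel units), and
for exactly rectilinear objects $\sigma = 0$ is appropriate. `f_R` of a
label uses the exact Euclidean distance transform. 2D label slices are
traced with marching squares under the same smoothing rule, avoiding the
perimeter inflation of pixel counting. Labels touching the image border are
measured but flagged `boundary_clipped`. Volumes are (de)serialized through
a plain-text CSV + JSON format; standard binary image stacks would need an
image I/O package, which this environment does not provide.

# What the synthetic world does and does not establish

The generator *is* the stated world of the method: isotropic, confluent,
space-tiling convex cells from one energy model, sliced by ideal
infinitely-thin planes with exact geometry. Green tests establish that the
estimator recovers the 3D descriptor of tissues *drawn from this model*, at
the stated sample sizes and error levels. They do not establish robustness
to anisotropic architectures, non-convex or non-Voronoi cell shapes, finite
optical thickness, or real segmentation artifacts beyond the three modeled
error channels. The reference method's own demonstration on plant-root
segmentation suggests tolerance to moderate violations, but that dataset is
external and intentionally not reproduced here.

# Numerical choices

* Clipping tolerance $10^{-10}$ box lengths for vertex classification;
  crossing vertices are cached per edge so shared face edges stay
  watertight.
* Chebyshev center LP solved exactly by active-constraint vertex
  enumeration (active-set loop above 24 faces).
* KDE: Gaussian kernel, `bw.nrd0`, 2048 grid points; HWHM by linear
  interpolation to the half-height crossings.
* Sub-seeds for nested stochastic stages derived by a fixed integer
  recurrence below $2^{31}$, so every packing, plane and noise draw is
  reproducible from one user seed.
* Degenerate inputs fail loudly: coincident centers, non-watertight
  polyhedra, zero-area polygons, empty samples, filters removing more than
  90% of a set.

# Known limitations

* Estimates are grid-valued; resolution below half a grid step (0.025 in
  $p^{3D}$) is not claimed.
* A *systematic* perimeter overestimate $\Delta L$ propagates strongly:
  scaling every $p^{2D}$ by $1+\Delta L$ shifts the distribution peak by
  $\Delta L\,\bar p^{2D}$, which the K-S fit follows because the reference
  family is nearly translation-like near its peak. The resulting bias is
  $\Delta p^{3D}/p^{3D} \approx \Delta L\,\bar p^{2D}/(0.44\,p^{3D})
  \approx 1.8\,\Delta L$ — keeping it below 1% requires perimeter accuracy
  better than about 0.6%, noticeably stricter than earlier, more optimistic
  assessments. Random perimeter noise ($\sigma_L \le 0.05$) and small-area
  dropout ($a_m \le 0.1$) bias the estimate by under about 1%, as the
  acceptance tests verify.
* Exact geometric slicing keeps every sliver cross-section, however small;
  3–7% of pieces fall below 5% of the mean area (more for elongated,
  high-$p^{3D}$ cells). Quantities sensitive to the small-area end of the
  distribution — notably the volume-calibration coefficient
  $c_1 = \langle V\rangle/\langle a\rangle^{3/2}$ — therefore come out a few
  percent higher than pipelines that rasterize and segment images, which
  cannot resolve sub-pixel pieces. When comparing against pixel-based
  measurements, apply a matching small-area cutoff to the library first
  (`apply_area_filter()`).
* The analytic gradient is undefined exactly at multifold vertices; the
  ramp protocol avoids, rather than resolves, those configurations.
* Library samples from the same packing are correlated; the effective
  sample size per grid point is smaller than the row count, which mildly
  inflates K-S noise floors at the scaled-down defaults.
* Only thickness-zero slices; anisotropic tissues violate the isotropy
  assumption and would need orientation-resolved references.
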