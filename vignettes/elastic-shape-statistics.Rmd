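---
title: "Elastic shape statistics of tap-root-like 3D shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic shape statistics of tap-root-like 3D shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(elastroot)
```

## The problem

Storage roots such as sugar beets vary in shape between cultivars — dull
versus long apices, single versus multiple branch tips, slim versus bulky
bodies — and this variation carries breeding-relevant information that
scalar traits (length, width, surface, volume) capture poorly. `elastroot`
implements a purely shape-based statistics pipeline for ensembles of such
3D objects: each root is represented as a characteristic function on the
unit cube, an elastic shape average summarizes each group, a Gram-matrix
PCA of stress-induced surface displacements extracts the principal modes of
shape variation with their variances, and unseen shapes are assigned to
groups by an extended Mahalanobis distance built on those modes. Because
real scan ensembles of this kind are rarely public, the package ships a
seeded parametric generator of labeled tap-root meshes that stands in for a
scanned data set; every end-to-end number the package reports is computed
on that synthetic material.

This vignette explains the model, the numerical choices, and their
limitations; the reference for each exported function documents its exact
contract.

## From a mesh to a characteristic function

A closed triangle mesh inside $[0,1]^3$ is voxelized on a regular grid of
$n^3$ nodes (spacing $h = 1/(n-1)$) in three steps.

**Signed distance.** The Eikonal equation $|\nabla d| = 1$, $d = 0$ on the
surface, is solved by initializing exact point–triangle distances on a
2-voxel near band and propagating outward with a fast-marching solver. The
sign (positive inside by default; a single global flag flips the
convention, which affects nothing downstream) is determined for the whole
grid by ray parity with one jittered axis ray per grid line. The
first-order fast-marching error stays well below the $2h$ envelope we test
against an analytic sphere.

**Sign regularization.** Scanned surfaces are often imperfectly closed, so
the raw signed distance can carry wrong signs at some nodes. Following the
variational repair idea, we minimize
$$\sum_i \big(|d_i|_\epsilon - |x_i|_\epsilon\big)^2
  + \sigma\, x^\top K x, \qquad |t|_\epsilon = \sqrt{t^2 + \epsilon^2},$$
over nodal fields $x$, where $K$ is the multilinear finite-element
stiffness matrix in voxel units, $\sigma = 0.01$ and $\epsilon = 10^{-4}$.
Two properties of this functional dictated the discretization and the
solver, and they are worth spelling out because they are easy to get
wrong:

* the data term is *sign-blind* (it compares smoothed magnitudes), so the
  globally one-signed smoothed field has lower energy than any correctly
  signed field. If the two terms are balanced per unit volume on the unit
  cube, the minimizer erodes the interface entirely — at $\sigma = 0.01$
  the effective smoothing length $\sqrt{\sigma} = 0.1$ exceeds the feature
  size of a root. We therefore normalize per voxel (data summed per node,
  gradients per voxel spacing), which makes $\sigma$ a mild,
  resolution-independent smoothing weight with a per-node
  smoothness-to-data ratio of about $0.03$;
* an isolated wrong-signed node sits behind a one-dimensional energy
  barrier (its magnitude is locally correct), which monotone gradient
  descent — including a trust-region Newton method — cannot cross. The
  solver therefore performs multi-color Gauss–Seidel sweeps that minimize
  each nodal value *globally* in its own coordinate, examining both sign
  branches. Sign outliers snap to the branch their neighborhood favors for
  any $\sigma > 0$, while the collective shell-by-shell interface erosion
  cannot be expressed by single-coordinate moves. Coordinate-wise exact
  minimization also makes the objective non-increasing by construction,
  which we assert in tests.

**Thresholding and normalization.** The characteristic function is 1 on
interior nodes of the regularized field. A clean Eikonal distance to the
thresholded interface is re-extracted and attached to the field; all
downstream smoothing, resampling and surface normals use it. Every shape
is also uniformly rescaled to a common volume (the ensemble median by
default), removing overall size as a — otherwise dominant — mode of
variation. The pipeline performs this normalization on the *surface*,
before voxelization (`rescale_mesh_to_volume()`): rescaling an already
voxelized small specimen cannot recover thin features (apex tips) that
fell below the grid scale, whereas the mesh-level rescale voxelizes every
shape at its final size. A voxel-level `rescale_to_volume()` is available
for shapes that only exist as occupancy fields.

## The elastic matching functional

Shape dissimilarity is the energy of the cheapest hyperelastic deformation
$\phi$ carrying one body onto another,
$$\int_{O} W(D\phi)\,dx
  + \gamma \int_{[0,1]^3} \big(\chi_{O} - \chi_{O'} \circ \phi\big)^2 dx,$$
with the polyconvex density
$$W(F) = \tfrac{\mu}{2}\|F\|^2 + \tfrac{\lambda}{4}(\det F)^2
 - \big(\mu + \tfrac{\lambda}{2}\big)\log \det F
 - \tfrac{3\mu}{2} - \tfrac{\lambda}{4},$$
$\mu = \lambda = 1$, $\gamma = 50$. $W$ is zero exactly at rigid motions
and diverges as $\det F \to 0^+$, so interpenetration is penalized by a
built-in barrier; $\|\cdot\|$ is the Frobenius norm. Deformations are
trilinear per cell; the elastic term uses one cell-center quadrature point
weighted by the cell-averaged occupancy of the reference body, and the
mismatch term uses mass-lumped nodal quadrature of mollified masks
($\chi_s = \mathrm{clamp}(\tfrac12 + d/(2w), 0, 1)$ with band
$w = 1.5h$ — a binary mask composed with $\phi$ is not differentiable, so
any gradient method needs this surrogate; hard masks remain available for
volume and trait queries).

Minimization is limited-memory BFGS with Armijo backtracking inside a
three-level coarse-to-fine cascade (nested grid halvings, trilinear
prolongation); steps that would drive $\det D\phi \le 0$ on an occupied
cell are rejected by the line search, and a prolonged coarse solution is
scaled back toward the identity if cells that only the finer mask resolves
start infeasible. Per level we stop at a relative objective decrease of
$10^{-6}$ or 300 iterations. Warm-started matches (inside the averaging
alternation) skip the cascade.

One honest caveat about this functional: the elastic integral lives on the
*moving* body only, so deforming exterior space is free and expansion onto
a larger target can concentrate its stretch in a thin boundary layer
rather than distributing it volumetrically. Matching a sphere onto a
slightly larger concentric sphere therefore yields a total objective at or
below that of the uniform dilation — we test the bound, not an assumed
affine form of the minimizer. The averaging alternation is nonetheless
well-behaved because the average is updated by a pulled-back vote (below),
not by energy descent in the average shape itself.

## Elastic averaging

The group average minimizes the summed matching energies over the average
occupancy and all deformations $\phi_i : O_i \to \bar O$ jointly. Since
the functional only defines the average up to rigid motion, inputs are
centroid-aligned first and the average centroid is pinned to the domain
center; no rotational gauge is applied because both the synthetic
generator and typical scanning protocols produce upright roots. We
alternate:

1. update every $\phi_i$ by a (warm-started) match against the current
   average;
2. update the average from the inputs pulled back through the current
   deformations ($\phi_i^{-1}$ approximated by fixed-point iteration on
   the displacement): the pulled-back signed distances are averaged and
   their zero level re-extracted — the classical signed-distance shape
   average, which unlike a clamped-occupancy vote keeps sub-voxel
   boundaries intact under repeated resampling. Two details make this
   update well-posed. First, the pullback is evaluated in the gauge of the
   *mean* deformation ($\bar\phi(z) = z + \bar u(z)$): pulling back
   through $\phi_i$ alone is a fixed point wherever the matches already
   fit — the mismatch term cannot prefer the zero-deformation
   representative — so common deformation content would never move into
   the average; in the mean gauge it does, and for identical inputs the
   update returns the input exactly. Second, re-centering ignores shifts
   below a quarter voxel: the centroid gauge is only defined to that
   accuracy, and every sub-voxel resample flips a few boundary nodes.

Initialization is the voxelwise mean of the aligned smoothed inputs,
thresholded at a *sub-majority* level of 0.35 with identity deformations.
The threshold matters more than it looks: at 0.5, thin shared structures —
apex tips, which jitter by a voxel or two across samples — fall below the
mean and vanish from the initial average, and the alternation can never
regrow structure outside the current average because the matches have
already folded every input's tip into the tipless blob (a genuine local
minimum of the joint functional: on such data the update loop stalls at
its first iterate with a rising objective). Starting slightly "fat" keeps
shared structure alive; subsequent alternations prune whatever the
ensemble does not support, and with the 0.35 level the objective trace
decreases over the alternations as intended. The loop stops when the total objective
decreases by less than $10^{-4}$ relatively, after at most 20 alternations;
an alternation that fails to decrease the total is rolled back, so the
reported objective trace is non-increasing by construction.

## Principal modes of shape variation

The nonlinear deformations cannot enter a linear PCA directly; each
$\phi_i$ is replaced by its linear representative, the boundary traction
$$\sigma_i
 = W'\big((D\phi_i^{-1})^{-1}\big)\,\det\!\big(D\phi_i^{-1}\big)\,
   (D\phi_i^{-1})^{-\top} \nu
 = \tfrac{1}{\det F}\, W'(F)\, F^{\top} \nu, \quad F = D\phi_i(x),$$
evaluated at surface samples $y$ of the average with preimages
$x = \phi_i^{-1}(y)$ (fixed-point inversion of the displacement; no global
inverse is built). Surface samples are interface-cell centers, normals come
from the signed-distance gradient, and each sample carries the area weight
$|\nabla \chi_s| h^3$ of the interface delta approximation. The gradient is
evaluated half a voxel inside the surface so the preimage sits in interior
cells where the det barrier was enforced. Interpolated gradients adjacent
to partially occupied boundary cells can still be unreliable (the barrier
holds at cell centers only) and the stress formula amplifies them
violently — a single runaway sample can inject a spurious rank-one
dominant mode into the PCA. Two robustness layers address this: truly
degenerate gradients (signed principal stretches outside $[0.05, 20]$ or
orientation-reversing) are repaired through a signed SVD that leaves the
rotation factors untouched, and the resulting traction magnitudes are
winsorized at ten times their per-shape median. The computation aborts if
more than half of the samples need gradient repair.

Applying $\sigma_i$ as a boundary load on the average yields the
displacement $u_i$: we assemble the Hessian of the elastic energy at the
identity over the occupied region — the classical linearized-elasticity
form $\int_{\bar O} 2\mu\,\varepsilon(u):\varepsilon(v)
+ \lambda\,\mathrm{div}\,u\,\mathrm{div}\,v\,dx$, discretized with
trilinear elements and full $2^3$ Gauss quadrature (single-point
quadrature would admit hourglass modes) — and solve the equilibrium with
the six-dimensional infinitesimal-rigid-motion kernel projected out of
load and solution (sparse Cholesky with a relative $10^{-10}$ ridge).

The same Hessian induces the natural scalar product
$g(u, v) = u^\top H v$ on displacements. After centering (the mean
displacement is subtracted, mirroring the centered data matrix of
vector-space PCA; centering also makes the smallest Gram eigenvalue
exactly zero, which we assert), the $m \times m$ Gram matrix
$C = \tfrac{1}{m}(g(u_i, u_j))_{ij}$ is eigendecomposed,
$C = Q \Lambda Q^\top$, giving variances $\lambda_j$ and modes
$w_j \propto \sum_i q_j^i u_i$. The literal mode formula yields
$g(w_j, w_j) = m$ under this Gram normalization, so modes are rescaled to
be $g$-orthonormal — the unique convention under which the classifier
identity $m_j^2(w_k) = 1/\lambda_k$ below holds exactly. Modes with
$\lambda_j < 10^{-12}\lambda_1$ are dropped.

## Classification

Each group $j$ contributes a trained model: its average $\bar S_j$, metric
$g_j$, modes $w^j_k$, variances $\lambda^j_k$ and the training
displacements spanning $U_j$. A shape to be classified is embedded as a
displacement $u$ relative to each class average by the *same path that
produced the training displacements*: match the shape onto the class
average (the training direction $O_i \to \bar O$), evaluate the boundary
stress, solve for the displacement, subtract the class's training mean. We
deliberately embed in the training direction rather than average-to-shape:
it reuses one code path, and a training sample then embeds onto
(approximately) its own training displacement, which we verify at a 10%
relative $g$-distance. For the same reason the training tractions are
computed from matches *re-run cold* against the final average rather than
from the warm-started matches of the averaging alternation: train and test
displacements must come from the identical optimization protocol, or
protocol-basin differences masquerade as shape variation along the weakest
modes — exactly where the Mahalanobis weighting amplifies them most.

The truncated Mahalanobis distance
$m_j^2(u) = \sum_{k \le M_j} g_j(u, w^j_k)^2 / \lambda^j_k$ penalizes
deviations along dominant class modes least, but vanishes on the
$g$-orthogonal complement of the retained modes, so it is extended by a
regularized residual:
$$d_j^2(u) = m_j^2(P_j u)
 + \tfrac{1}{\beta}\, g_j(u - P_j u,\, u - P_j u),$$
with $P_j$ the $g$-orthogonal projection onto $U_j$ (computed through the
training Gram system with a $10^{-10}$ pseudo-inverse cutoff), $\beta =
10^{-5}$ and $M_j = 13$ by default (both exposed, since the sensitivity of
the rule to $M_j$ is a known open point). The shape is assigned to the
class with minimal $d_j^2$; exact ties go to the lowest class index so
batch runs are deterministic. Distances are compared across classes as raw
numbers even though each $g_j$ lives on a different average — no
renormalization is applied, as none is part of the rule.

Two baselines are included: the *average-only* distance (the converged
total matching objective against each class average, ignoring the modes)
and a Euclidean PCA on five scalar traits — length, width, surface,
volume, complexity = surface/volume — with nearest-centroid assignment in
the leading two components. Traits are standardized before the PCA
because they carry incommensurate units; the trait baseline operates on
the original meshes, before volume normalization.

## The synthetic generator and the benchmark conditions

`generate_root()` builds a tap-root as a radial graph over a subdivided
icosahedron: along each ray from an interior center, the outermost
crossing of an implicit union — a rounded crown, a body of revolution with
profile $r(z) = r_{\max}(1 - z/L)^{\tau}$, and $k$ tapered apex cones
attached to the lower body — is located by bisection. A radial graph is
embedded by construction, so every mesh is watertight, consistently
oriented and self-intersection free; we chose this over a boolean union of
tube meshes precisely because those guarantees are structural rather than
numerical. Multiple apices appear as smooth downward lobes rather than
fully separated cylinders — a known simplification; strongly non-convex
branch geometries are outside what the generator (and a $33^3$ grid)
resolves. Band-limited radial roughness (six seeded plane waves) emulates
surface furrows, and an independent isotropic size factor (12% linear
coefficient of variation in the benchmark classes) emulates the
environmental size variation of field-grown plants, which is largely
independent of shape type and much larger than any single shape spread —
so that, as in real ensembles, uniform scaling is the dominant mode of the
raw data and disappears under volume normalization. All randomness flows
from integer seeds through a Lehmer hash, so ensembles are pure functions
of their specification.

The default benchmark defines four classes in the shape vocabulary of
cultivar variation — `multiapex` (two apex lobes on average), `longapex`
(a long, slim tip), `dull` (strong taper, short tip), `slim` (elongated
narrow body) — with 35 samples each, 5 held out per class, on a $33^3$
grid. Spreads were chosen once so that classes overlap in raw size traits
(making the five-trait baseline genuinely hard) while differing in apex
structure and taper; the body/radius spreads also give each class a
volume spread, so that the rescaling-stability comparison below is
non-trivial. What passing this benchmark shows is that the pipeline
separates *structural* shape classes at desk scale; it does not show
cultivar-level performance on real scanned beets, whose roughness,
soil-damage artifacts and scan noise the generator does not emulate.

The production profile runs the identical pipeline at $129^3$; the test
profile at $33^3$ with a 150-iteration cap per matching level keeps the
full benchmark within desk-scale budgets (grid resolution and the cap are
pure accuracy/cost trade-offs; the objective decrease beyond the cap is
orders of magnitude below the class separation scale).

## Rescaling stability of the variance spectrum

With raw (non-normalized) inputs the dominant PCA mode is uniform scaling;
after volume normalization it disappears. The package reports how well the
*ratios* of consecutive variances agree between the two runs — scaled
$\lambda_{k-1}/\lambda_k$ against unscaled
$\tilde\lambda_{k-1}/\tilde\lambda_k$ with the index shifted by one to
skip the scaling mode — over the leading modes of each class. Agreement
within 15% on the benchmark is asserted in the acceptance tests.

## Numerical choices, degenerate inputs, limitations

* Degenerate inputs fail loudly: empty or full threshold results, fields
  without sign change, volume targets that push a shape outside the
  domain, meshes outside the unit cube, grids below $9^3$ or of even size.
* Non-watertight meshes are accepted with a warning — the sign
  regularization exists to cope with them — and degenerate faces are
  dropped on load.
* The det-barrier makes the matching objective $+\infty$ on inverted
  occupied cells; the optimizer treats that as a rejected step, and
  `deformation_energy()` reports `Inf` with a barrier flag.
* Mesh I/O covers OBJ, ASCII/binary-little-endian PLY and ASCII STL;
  fields and models persist as RDS with optional NIfTI export of voxel
  volumes.
* Isosurface rendering of modes uses marching tetrahedra with shared edge
  vertices; amplitudes beyond about three voxel spacings of displacement
  trigger a self-intersection warning but still render.
* The equilibrium solve and metric ignore everything outside the occupied
  region; displacements are only meaningful up to the rigid-motion kernel,
  which is projected out everywhere it matters.
* Elastic distances are asymmetric in principle (moving versus fixed); the
  package consistently uses the input-onto-average direction everywhere.
* The matching problem is non-convex and its mollified objective has
  interpolation kinks, so the optimizer is deterministic but not
  basin-stable: formally equivalent problems (e.g. exact voxel translates,
  which merely reorder floating-point summations) can converge to
  different local minima. The discretized functional itself is exactly
  invariant under such translations, and repeated solves of the identical
  problem are bit-reproducible.
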