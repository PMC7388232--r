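# elastroot

Elastic shape statistics and cultivar classification for tap-root-like 3D
shapes.

Storage roots (the motivating case is the sugar-beet tap root) vary between
cultivars in ways that scalar traits — length, width, surface, volume —
capture poorly: dull versus long apices, single versus multiple branch
tips, slim versus bulky bodies. `elastroot` implements a purely shape-based
statistics pipeline for ensembles of such objects:

1. **Voxelization.** A closed triangle mesh becomes a characteristic
   function χ on a regular grid of the unit cube via a signed distance
   field (Eikonal equation |∇d| = 1, exact near-band + fast marching), a
   variational sign regularization
   ∫(|d|ε − |d_new|ε)² + σ∫|∇d_new|² that repairs wrong signs from
   imperfectly closed surfaces, thresholding, and uniform rescaling of all
   shapes to a common volume.
2. **Elastic averaging.** The group average minimizes
   Σᵢ ∫_{Oᵢ} W(Dφᵢ) dx + γ∫(χᵢ − χ̄∘φᵢ)² dx over the average occupancy
   and all matching deformations, with the polyconvex density
   W(F) = μ/2‖F‖² + λ/4 det²F − (μ+λ/2)log det F − 3μ/2 − λ/4
   (μ = λ = 1, γ = 50); W vanishes exactly at rigid motions and blows up
   as det F → 0⁺.
3. **Elastic PCA.** Each nonlinear deformation is replaced by its linear
   representative — the boundary traction σᵢ = det(F)⁻¹ W′(F) Fᵀ ν on the
   average surface — converted to a displacement uᵢ by a linearized
   elastic equilibrium solve, and the Gram matrix
   C = (1/m)(g(uᵢ, uⱼ)) under the energy-Hessian metric g is
   eigendecomposed into g-orthonormal principal modes wⱼ with variances
   λⱼ.
4. **Classification.** A shape is assigned to the cultivar minimizing the
   extended Mahalanobis distance
   d_j²(u) = Σ_{k≤M} g(P_j u, w_k)²/λ_k + (1/β) g(u−P_j u, u−P_j u)
   (M = 13, β = 10⁻⁵), with an average-only matching distance and a
   five-trait Euclidean PCA as baselines.

Real scanned ensembles of this kind are rarely public, so the package
includes a seeded parametric generator of labeled synthetic tap-root
meshes (watertight by construction) and a four-class benchmark that
exercises the whole pipeline end to end.

## Worked example

```r
library(elastroot)

# four labeled root classes, 35 samples each, 5 held out per class
cfg <- pipeline_config(seed = 1)        # test profile: 33^3 grid
report <- run_pipeline(cfg)
print(report)
```

```
<pipeline_report>
  extended-Mahalanobis accuracy: 0.800
  average-only baseline:        0.750
  trait-PCA baseline:           0.400
  one-sided binomial p (vs 0.25): 3.865e-07
  confusion (rows = truth):
            multiapex longapex dull slim
  multiapex         5        0    0    0
  longapex          0        3    2    0
  dull              0        1    4    0
  slim              1        0    0    4
```

The accuracy line is the fraction of the 20 held-out shapes assigned to
their true class by the extended Mahalanobis rule (chance level 0.25); the
baselines show the same holdouts classified by raw matching distance to
each class average and by nearest centroid in two-component trait-PCA
space. `report$variances` holds the per-class variance spectra of the
elastic PCA, and `report$variance_ratio_agreement` measures how stable the
consecutive variance ratios are when the pipeline is re-run without volume
normalization (the dominant unscaled mode is uniform scaling).

Individual stages are available as ordinary functions — `generate_root()`,
`voxelize_mesh()`, `match_shapes()`, `elastic_average()`, `elastic_pca()`,
`cultivar_model()`, `classify_shape()`, `compute_traits()` — and a thin
command-line driver with the same stages ships in `inst/cli/elastroot`.
Principal modes can be rendered as displaced surface meshes with
`render_mode()` and exported to PLY/OBJ for inspection.

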