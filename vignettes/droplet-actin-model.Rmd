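---
title: "Actin networks in deformable protein droplets: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actin networks in deformable protein droplets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The physical picture

Phase-separated droplets of actin-binding proteins concentrate actin and its
crosslinkers inside a liquid boundary that has its own surface tension.
Growing filaments accumulate bending energy against the confinement; when
that energy competes with the surface energy of the droplet, the droplet
deforms, and the interplay between crosslinker kinetics and boundary
mechanics selects the emergent network morphology: tightly bundled, nearly
two-dimensional *rings*; thicker, weakly bundled equatorial *discs*; or
filaments spread over the whole surface as *shells* (loose or tight).

`dropletActin` implements a minimal agent-based model of this system
together with the analysis used to characterize it: gyration-tensor shape
descriptors, actin-covered surface fraction, length distributions,
PCA/K-means morphology classification, power-law fitting, and an
equipartition mode model that links bundle thickness to droplet radius.

# Model components

## Filaments

A filament is a chain of inextensible segments of length
`L_seg = 0.1` µm joined at hinge points.  Only the plus end grows, and it
grows deterministically at `k_grow` while uncapped; with the default
`k_grow = 0.0103` µm/s a filament starting at one segment reaches the
circumference of an R = 1 µm droplet (2π µm) over a 600 s simulation.
Capping protein is represented implicitly: the plus end switches between
capped (growth arrested) and uncapped states at rates `k_cap` and
`k_uncap`, a two-state telegraph process whose stationary uncapped fraction
is `k_uncap / (k_cap + k_uncap)`.

Bending is penalized with the discrete hinge energy

$$E_{\mathrm{bend}} = \frac{k_\mathrm{bend}}{L_\mathrm{seg}}
   \sum_i \bigl(1 - \cos\theta_i\bigr),$$

which converges to the worm-like-chain form
$(k_\mathrm{bend}/2)\int \kappa^2\,ds$ as the discretization refines; on a
circular arc of radius 1 µm it is within 2% of $k_\mathrm{bend} L / (2R^2)$
at the default segment length.  The default
`k_bend = 0.075` pN·µm² corresponds to a persistence length of ~18 µm at
`k_BT = 0.0042` pN·µm, the standard value for actin.  The hinge adjacent to
the partially grown tip segment is weighted by `(partial/L_seg)^2`: a fresh
tip segment would otherwise either rotate freely (no stiffness) or, once
engaged, produce forces inversely proportional to its near-zero length.
The quadratic ramp keeps the hinge's displacement stiffness bounded by a
constant, which is the condition explicit integration needs.

## Crosslinkers

Crosslinkers are diffusing 30-nm spheres.  *Tetramer* mode represents
stable tetravalent bundlers (four actin-binding sites, five occupancy
states 0–4).  *Monomer* mode represents dynamically multimerizing proteins:
one actin site plus two partner sites, so monomers chain into dimers,
trimers and longer multimers (six states: 0/1/2 partners × actin
bound/free).  The partner graph is constrained to simple paths — events
that would create a degree-3 node or close a cycle are rejected.

Binding: any filament segment with material within the binding distance
(30 nm) of a linker center is a candidate; the total binding propensity is
`k_bind` per candidate, and the per-step binding probability is the exact
first-event form `1 − exp(−k_bind · n · dt)`.  Unbinding and multimer
splitting follow Bell's slip-bond law, `k_off = k0 · exp(F/F0)`, with the
instantaneous spring tension `F`.  Engaged links are Hookean springs
(default 100 pN/µm) between the linker center and the attachment abscissa
on the filament, with the filament-side force shared by the flanking
vertices.  `F0` defaults to 6 pN; both values are config-exposed
reconstructions, as is every mechanical constant not fixed by the study
conditions.

Steric repulsion acts between linkers and filaments only (soft Hookean
overlap penalty, 100 pN/µm); filament–filament sterics are off.

## The deformable boundary

The droplet is an axis-aligned ellipsoid with semi-axes $(a, b, c)$.
Agents that escape are pulled back to their closest surface point by a
confinement spring (100 pN/µm), and the reaction forces load the boundary.
Along each axis the generalized force is

$$F_i = \sum_{\mathrm{loads}} f_i \frac{x_i}{a_i}
  \;-\; \sigma \frac{\partial A}{\partial a_i}
  \;+\; P \frac{\partial V}{\partial a_i},$$

the three terms being the virtual work of the point loads at fixed
normalized surface coordinates, the surface-tension pseudoforce, and a
pressure term in which $P$ is a Lagrange multiplier chosen **each step** by
a scalar Newton iteration so that the updated axes conserve the reference
volume exactly (relative residual below 1e−10; post-step volume error is at
machine precision over 1e5 steps).  Axis motion is damped by the effective
viscosity `mu_effective`, which sets the deformation timescale without
changing the equilibrium shape — halving it doubles the per-step axis
change but leaves the long-time axes unchanged to 1e−3.  On a sphere with
no loads, surface tension and pressure balance exactly (the Laplace
condition), so a free droplet is stationary rather than slowly drifting.

The surface area and its axis gradient are evaluated by Gauss–Legendre
quadrature over the first octant of the standard parametrization (48×48
nodes for the user-facing functions, accurate to far better than 1e−6;
20×20 inside the stepping loop).  Closest-point projection solves the
one-dimensional Lagrange condition with a safeguarded Newton iteration; a
point at the exact center deterministically projects along the shortest
axis (smallest index on ties).

## Time integration

All mobile points follow overdamped Langevin dynamics,
$dx = \mu f\,dt + \sqrt{2 \mu k_B T\,dt}\,\xi$, with Stokes mobilities
(spheres of radius `L_seg/2` for filament vertices, 30 nm for linkers, in
the droplet medium viscosity 0.5 pN·s/µm²).  The fixed event order within a
step is growth → capping → binding kinetics → forces → move → constraint
projection → boundary update, and a single seeded RNG stream makes a
trajectory bit-reproducible from its configuration and seed.

Three numerical guards matter:

* **Adaptive mechanics sub-stepping.**  Explicit integration of a spring of
  stiffness $k$ on an agent of mobility $\mu$ is stable only for
  $\mu k\,dt < 2$.  The stiffest interactions here are the alternating
  bending mode (bounded by $16 k_\mathrm{bend} / L_\mathrm{seg}^3$) and the
  sum of link springs sharing one vertex, which changes as linkers bind.
  Each step the engine counts the worst per-vertex link multiplicity and
  subdivides `dt` so that $\mu k h \le 1$ for the stiffest term.  The
  nominal `dt = 0.005` s is therefore a bookkeeping step; the effective
  mechanics step is typically 2–5·10⁻⁴ s.
* **Constraint projection.**  After each move, segment lengths are restored
  (to 1e−6 µm) by a Newton iteration on the chain constraints whose Gram
  matrix is tridiagonal — an O(n) Thomas solve per iteration with quadratic
  convergence.  Noise is applied before projection, the standard choice for
  constrained Langevin schemes.
* **Boundary sub-stepping.**  The explicit axis update is itself stabilized
  against the tension + pressure restoring rate (~`sigma*(8*pi/3)/mu_eff`
  on a near-sphere) and against axis changes larger than 10% per sub-step,
  so even very stiff interfaces relax monotonically instead of ringing.

A displacement larger than `L_seg` in one sub-step aborts the run with an
instability diagnostic rather than producing silent nonsense.

# Shape analysis

* **Gyration spans.**  The gyration tensor of the monomer-level filament
  point cloud has eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$;
  spans are $\sqrt{5\lambda_i}$ (the uniform-solid-ellipsoid relation; the
  proportionality constant is a convention — the alignment angle and all
  ratios are invariant to it).
* **Alignment angle** $\theta = \arctan(\mathrm{span}_c/\mathrm{span}_a)$,
  0° for a flat (ring-like) network and 45° for an isotropic (shell-like)
  one.  The defining endpoints force the arctan-of-ratio reading; the
  literal angle between two orthogonal axes would always be 90°.
* **Surface fraction.**  The droplet surface is triangulated as an
  icosphere (subdivision 3, 1280 triangles) stretched onto the current
  ellipsoid; filament points within 0.1 µm of the surface are assigned to
  their nearest triangle centroid, and the fraction of occupied triangles
  is reported.  Changing the subdivision by one level moves the fixture
  fractions by only a few percent.
* **Length PDFs.**  Filament lengths are histogrammed into 130 bins of
  width 0.05 µm; the distribution is smoothed over time by *pooling
  samples* across the ±5 neighbouring snapshots (the alternative — averaging
  counts — is exposed via the histogram component) and a Gaussian KDE
  (Scott's-rule bandwidth) gives the density.
* **Ring thickness** is the full width at half maximum of a Gaussian fit to
  a radial intensity profile minus the diffraction limit, floored at zero.
* **Power laws** $y = a x^b$ are fitted by ordinary least squares on
  log-transformed data after two filters that mirror the study design:
  only rows with final aspect ratio in [1.5, 2.0] enter, and distinct x
  values with fewer than 10 surviving rows are dropped.

# Morphology classification

Feature rows (surface fraction + the five tetramer state fractions, one of
which is redundant by the simplex constraint) are z-scored, decomposed by
PCA, and clustered by K-means on the first three principal components with
50 restarts per k; the cluster count k ∈ 2..8 is chosen by the largest mean
silhouette width.  A varimax rotation of the leading three loadings is
reported for interpretability; being orthogonal it preserves the explained
variance of the rotated block.  When four clusters emerge they are named by
ordering cluster-mean `span_c`: lowest = rings, next = discs, and the two
highest are the shells, with the higher surface fraction of the two labeled
*tight*.

# Desk-scale study protocol

The full study conditions (R = 1 µm droplet, 30 filaments, 1000 tetramers,
σ = 7 pN/µm, 600 s, ten replicates per condition over large kinetic grids)
are cluster-scale.  The package's reduced protocol, used by the test suite
and fixed once:

* **Time compression ×10**: all chemical rates (`k_grow`, capping, binding,
  unbinding, multimerization) are multiplied by 10 and the duration and
  boundary damping divided by 10 (`time_scaled_config()`).  Deterministic
  dynamics traverse the same states; thermal exploration per unit growth is
  reduced, which weakens diffusion-limited rearrangement (bundles zipper
  closer to where they first form than at full scale).
* **System size**: 10 filaments and 330 tetramers, preserving the 30:1000
  ratio; 3 replicates per condition; kinetic grid
  `k_bind, k_unbind ∈ {0.001, 0.1, 10}` s⁻¹.
* Features for classification are taken from the last 5 snapshots of each
  replicate; state-fraction reporting uses the last 30.

What passing at this scale shows: the mechanochemical pipeline — kinetics,
mechanics, boundary feedback, descriptors, classification — reproduces the
qualitative structure of the morphology space and the orderings (trapped
high-f4 states vs. unbound high-f0 states, coverage contrasts, deformation
onset after the filament length exceeds the droplet diameter).  What it
does not show: quantitative agreement with full-scale runs (aspect-ratio
magnitudes are smaller with a third of the filaments, and ring formation is
rarer under compression), hydrodynamic effects (not modeled), or trajectory-level agreement
with other simulators of this model class (per-vertex drag and
integration-order details differ between implementations).

# The synthetic-data generators

`gen_morphology_cloud()` emulates the four archetypes as point clouds
(great-circle band, oblate slab, thin/thick spherical shells) with
controlled noise; `gen_powerlaw_dataset()` produces lognormal-noise power
laws with aspect-ratio columns for filter testing;
`gen_intensity_profile()` convolves a top-hat ring with a Gaussian PSF
analytically; `gen_two_state_series()` is an exact Gillespie telegraph
process used as the capping oracle.  All are deterministic under their
seeds and carry ground-truth metadata.  They emulate geometry and noise,
not simulation dynamics: fixtures validate the analysis and classification
stages independently of the engine.

# The equipartition mode model

Writing the radial fluctuation of a circumferential bundle of length
$L$ and rigidity $k_b = L_p k_B T$ as a cosine series, the energy above the
circular baseline ($k_b L / 2R^2$) carried by mode $m$ is
$(k_b/2)(2 + m^4)(L/R^4)u_m^2$.  Equipartition assigns each mode
$k_B T/2$, so

$$u_m = \sqrt{\frac{k_B T\, R^4}{k_b (2+m^4) L}}
   \;\xrightarrow{L = 2\pi R}\; u_m \propto \frac{R^{1.5}}{\sqrt{L_p}},$$

i.e. the thermal bundle thickness grows with droplet radius with a log-log
slope of exactly 1.5 (2.0 if the bundle length is held fixed instead of
tracking the circumference).  Only the exponent is asserted; the
proportionality between $u_m$ and a measured ring thickness is not fixed.

# Known limitations

* No hydrodynamic coupling between filaments and the droplet interior.
* No filament–filament sterics (bundles can interpenetrate), matching the
  modeling choice of the study conditions.
* The ellipsoid stays axis-aligned; network and droplet principal axes are
  compared through sorted spans only.
* Explicit (not implicit) integration: cost grows with crosslink
  multiplicity; heavily zippered systems are the slow corner.
* Time compression trades Brownian exploration for speed; morphology-space
  boundaries shift accordingly at desk scale.
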