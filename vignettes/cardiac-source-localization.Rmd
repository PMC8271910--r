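---
title: "Cardiac source localization: model, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac source localization: model, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During a heartbeat, the electrical activation of the myocardium behaves, at
any instant, approximately like a concentrated current source: a small region
of tissue drives current through the torso, and the resulting potential
differences are what a 12-lead ECG records at nine physical electrode sites
(the precordial electrodes V1–V6 and the limb electrodes RA, LA, LL). This
package solves the inverse problem in its simplest well-posed form: given the
nine surface potentials, estimate **where** in the heart the dominant source
sits and **which direction** its current flows, then stabilize the estimate
over time with a motion model.

The pipeline has four stages, each exposed as a package module:

1. **Volume conductor model** — a voxelized body with per-tissue
   conductivities (`voxel_model()`, `tissue_table()`).
2. **Forward problem** — the potentials a known source produces at the
   surface (`spfd_system()`, `solve_spfd()`).
3. **Inverse problem** — a lead field dictionary plus sparse recovery
   (`build_lfm()`, `omp_localize()`).
4. **Tracking** — a constant-conduction-velocity Kalman filter over the
   time series of estimates (`track_source()`).

## The volume conductor and its discretization

At cardiac signal frequencies the quasi-static approximation holds: capacitive
and inductive effects are negligible and the body behaves as a purely
resistive volume conductor. The body is represented as a regular grid of cubic
voxels (2 mm pitch in the reference configuration), each carrying an integer
tissue label mapped to a conductivity in S/m. The conductivities that matter
most here are blood (0.70), heart muscle (0.05), lung (0.20), skeletal muscle
(0.20) and skin (fixed at 0.1, a wet/dry-skin value appropriate for
surface-potential modelling). Air is exactly zero and no current crosses the
body surface.

The forward problem is discretized with the scalar-potential
finite-difference (SPFD) scheme: unknown potentials live at voxel corners
(nodes), and every grid edge becomes a resistor whose conductance is the mean
conductivity of the up-to-four voxels sharing the edge, times the pitch
(cross-section `pitch^2` over length `pitch`). Kirchhoff's current law at
each node yields a sparse, symmetric, 7-point-stencil system `A phi = b`
whose rows sum to zero — the discrete pure-Neumann Poisson operator. The
right-hand side injects `+I` at a source (anode) node and `-I` at a
grid-adjacent cathode node: a current dipole one voxel edge long. Because
only potential differences are observable, the solution is gauge-fixed to
zero mean over conducting nodes.

One sign convention is worth stating explicitly: a `"+x"` dipole has its
cathode on the `+x` side of the anode, so the equivalent far-field point
dipole moment points from the cathode toward the anode (along `-x`). All
package components share this convention consistently; it only matters when
comparing against analytic formulas.

### Solvers

Three back-ends solve the singular system:

* **direct** — sparse Cholesky of the conducting subsystem with one node
  pinned. The factorization is computed once and reused, which makes this the
  method of choice whenever one conductor is solved for many right-hand
  sides (building a lead field matrix is exactly that).
* **sor** — plain successive over-relaxation (`omega = 1.5`), kept mostly as
  a reference smoother.
* **multigrid** — the default for single large solves: a stationary
  iteration whose error correction is a geometric multigrid V-cycle with
  SOR smoothing (two sweeps per level), iterated until the relative residual
  drops below `1e-6`, with up to six levels.

The multigrid hierarchy deliberately deviates from pure geometric coarsening
of the conductance network: coarse levels are built by factor-2 node
coarsening with trilinear interpolation assembled as a Kronecker product of
1-D operators, restricted to conducting nodes, and coarse operators are the
Galerkin products `Ac = t(P) %*% A %*% P`. This is algebraically equivalent
to re-aggregating conductances in the grid interior but handles irregular
air/tissue boundaries without special-casing, and it guarantees that every
coarse operator stays symmetric positive semidefinite with the same constant
null space — which the coarsest level then absorbs exactly with a dense
pseudoinverse. The outer iteration projects the constant mode out after
every cycle.

On the default 40^3 phantom the multigrid solver reaches a relative residual
of `1e-6` in under ten V-cycles and agrees with the direct factorization to
a few times `1e-6` relative error.

## The lead field matrix

The source space is a lattice of candidate points inside the cardiac tissue:
a voxel qualifies only if all six face-neighbours are cardiac too (sources
are never placed on a tissue interface), and the eligible voxels are
subsampled at 6 mm spacing by default — on a 2 mm whole-body model this
yields on the order of 900 points; on the desk-scale phantom, a few dozen.

For each of the `N` points and each base direction, one forward solve yields
the electrode potentials of a unit-direction dipole. The column stored in
the lead field matrix `L` (`M x 3N`, `M = 9` electrodes) is that potential
vector divided by the anode current density of the solve (branch current
through the source edge over the voxel cross-section), so the arbitrary
injected current cancels and `L %*% j = Phi` maps current-density amplitudes
to potentials. Columns are blocked `[x | y | z]`.

The matrix is persisted as full-precision CSV plus a JSON sidecar carrying
the source grid, electrodes and provenance — including a content hash of the
conductor model, so `load_lfm()` refuses a dictionary that was built for a
different body unless explicitly forced. (An HDF5 container would be the
natural choice for larger matrices; CSV + JSON was chosen because it is
dependency-free and text-only, and the matrices here are small.)

## Localization by orthogonal matching pursuit

Localization treats the observed potential vector `Phi` as a 1-sparse signal
over the dictionary: the normalized correlation `|Phi . L_i| / (||Phi||
||L_i||)` is computed for all `3N` columns, the winning column's grid point
becomes the location estimate, and the current-density vector is recovered by
applying the pseudoinverse of the point's three-column support to `Phi`. The
absolute value lets an anti-aligned source still select its location (the
pseudoinverse recovers the sign); ties break toward the lowest point index.

### A limitation worth knowing about

With only nine electrodes and closely spaced source points the dictionary is
extremely coherent: adjacent columns have cosines around 0.999. A noise-free
source **on** the grid but with an oblique orientation is a mixture of three
columns of one point, and that mixture can correlate better with a single
column of a *neighbouring* point than with any single column of its own
triplet. The per-column selection rule therefore does not guarantee exact
recovery even in the noise-free, on-grid case — on the desk-scale phantom it
picks the exact point for roughly 20–40% of random orientations (and for
100% of axis-aligned ones, where the signal *is* a dictionary atom). The
acceptance suite contains a deliberately strict exact-recovery test that
documents this behaviour.

`omp_localize(selection = "subspace")` offers the remedy as an explicit
variant: each point is scored by the projection of `Phi` onto the span of
its three columns. Because the true point's subspace contains the noise-free
signal entirely, this rule recovers every on-grid source exactly regardless
of orientation. It is not the default because the per-column rule is the
printed matching-pursuit construction this implementation follows.

## Accuracy protocols

Two stochastic drivers reproduce the standard accuracy protocols:

* `run_dipole_study()` — `n` dipoles (default 100) at random positions in
  the cardiac tissue with uniform random orientations; forward-solve, add
  white Gaussian noise at a target SNR, localize, and score localization
  error (LE, mm) and direction error (DE, degrees).
* `run_snr_sweep()` — a fixed dipole set evaluated across the SNR grid
  `{0, 10, 20, 30, Inf}` dB with 1000 independent noise patterns per level
  (the correlation step is vectorized across patterns).

Both derive per-trial seeds as `seed + f(trial)` and restore the caller's
RNG state, so any individual trial can be reproduced in isolation.

`transform_heart()` supports the sensitivity protocol: rotating (nominally
-10..10 degrees about the body axis) or isotropically scaling (90–110%) the
cardiac tissue inside the conductor while the dictionary stays fixed, with
vacated volume filled by lung tissue.

## Tracking with a conduction-velocity motion model

Over a beat, the activation source moves through the myocardium at roughly
the ventricular conduction speed, `v = 1.9 m/s`. The tracker models the
position as advancing each millisecond by `v * dt` along the *estimated
current direction* (the OMP `j_hat`, normalized — its magnitude cancels),
and treats the OMP location as a noisy observation of the true position.
With diagonal covariances the filter decouples into three scalar Kalman
recursions per axis:

```
x- = x + u * dt        P- = P + dt^2 * Q
K  = P- / (P- + R)
x  = x- + K * (r - x-) P  = (1 - K) * P-
```

initialized at the AV-node position with `P(0) = Q`. The calibration
helpers follow the source protocol: `estimate_Q()` takes the process noise
from the per-axis variance of a dipole study's localization errors (the
static method's own accuracy), and `estimate_R()` measures the observation
noise as the spread of localizations across random sub-dictionaries of the
lead field (ten subsets of 500 points at full scale).

## Phantom versus anatomical scale

Everything in this package runs on a synthetic block-torso phantom: a muscle
body in an air margin, two lung blocks flanking a cardiac block with a
high-conductivity blood core, and nine surface electrodes in the standard
roles. The phantom preserves the *structure* of the problem — tissue
contrasts, insulating boundary, electrode geometry, dictionary coherence —
but not anatomical realism: real torsos produce stronger lead-field
asymmetries and their published headline accuracies are computed on
request-only anatomical voxel models that cannot be redistributed here. The
`inst/configs/fullscale_*.yaml` runner configurations reproduce the
full-scale protocols when such a model is supplied by the user
(`?save_model` documents the exchange format).

Problem sizes used throughout the documentation and tests: 24^3 voxels for
fast unit tests, 40^3 (2 mm pitch) as the default study phantom, up to 60^3
in the solver-refinement checks.

```{r example}
library(cardiosource)

spec <- phantom_spec()
model <- make_block_torso(spec)
lfm <- build_lfm(model, phantom_electrodes(spec))
study <- run_dipole_study(model, lfm, n_dipoles = 100, snr_db = 20)
glance(study)
autoplot(study)
```
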