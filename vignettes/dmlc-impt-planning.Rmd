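---
title: "Dynamic MLC planning for intensity-modulated proton therapy: models and methods"
author: "protonDMLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic MLC planning for IMPT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

protonDMLC is a desk-scale treatment-planning toolkit for proton pencil
beam scanning (PBS) with a dynamic multi-leaf collimator (dMLC): leaf
positions are refit at every energy layer. It implements two leaf
strategies — a target-enclosing *cover* mode and an organ-at-risk (OAR)
shielding *block* mode — embedded in a complete planning chain: synthetic
phantom, beam/energy model, water-equivalent ray tracing, leaf sequencing,
hexagonal spot placement, an aperture-aware analytic dose engine,
worst-case robust spot-weight optimization, scenario/DVH evaluation and 2D
gamma verification. This vignette documents the models, the numerical
choices, and the limits of what the synthetic-phantom experiments can show.

## The machine model

The modeled delivery system is a synchrotron PBS machine with an upstream
54-pair MLC and a downstream range shifter (RS):

* **Energy library.** 92 energies from 70.7 to 235.0 MeV, corresponding to
  water-equivalent ranges of 40–340 mm. Only the count and the two
  endpoints are specified by the hardware description, so the library is
  synthesized with *uniform spacing in range* (about 3.3 mm per layer),
  which matches clinical layer-spacing practice and makes layer selection
  regular. The range–energy law is the two-point power-law fit
  $R = \alpha E^{p}$ through the anchors (70.7 MeV, 40 mm) and
  (235.0 MeV, 340 mm).
* **In-air spot size.** The sigma of the lateral Gaussian at the isocenter
  plane is 3.2 mm at maximum and 9.9 mm at minimum energy; intermediate
  energies interpolate log-log between the anchors (the interpolation shape
  is a package choice; the anchors are reproduced exactly). Inserting the
  RS adds a scatter term in quadrature,
  $\sigma_{RS} = \theta_{RS}\,(g + d_0)$ with effective angle
  $\theta_{RS} = 25$ mrad, air gap $g$ (30 mm default) and a fixed standoff
  $d_0 = 40$ mm — a deliberately simple drift model, configurable in
  `default_machine()`.
* **In-medium spot size.** $\sigma(z)^2 = \sigma_{air}^2 +
  \sigma_{MCS}(z)^2$ with a two-parameter multiple-Coulomb-scattering power
  law $\sigma_{MCS}(z; R) = a R^{b} (z/R)^{q}$, $a = 0.0374$ mm$^{1-b}$,
  $b = 0.896$ (the classical water fit, converted to millimetre units) and
  growth exponent $q = 1.7$; the maximum is reached at the Bragg depth
  $z = R$.
* **Depth dose.** An analytic Bortfeld-style Bragg curve: the power-law
  form $17.93\,(R-z)^{-0.435} + (0.444 + 31.7\,\epsilon/R)(R-z)^{0.565}$
  (in cm), bin-averaged analytically over the tabulation step so the
  integrable singularity at $z = R$ is handled exactly, then convolved
  numerically with a Gaussian range-straggling kernel
  $\sigma_R = 0.0139\,R^{0.935}$ mm (evaluated at the pre-RS range, since
  straggling accumulates over the full path) and normalized to 1 at the
  peak. The peak falls within 3 mm of the nominal range and essentially no
  dose remains 10 mm beyond it.
* **Range shifter.** Modeled purely as a 60 mm WEL shift plus the sigma
  broadening above; it is engaged whenever the proximal target edge is
  shallower than 40 mm WEL. No additional distal-falloff widening beyond
  the configurable straggling term.

## Geometry and water-equivalent conversion

Coordinates are a right-handed patient frame (x = left–right,
y = anterior–posterior, z = cranial–caudal, millimetres); the grid origin
is the corner of voxel (1,1,1) with voxel centers at
origin + (i − 0.5)·spacing. Beams use *parallel-ray* geometry: scanning
systems have a large virtual source distance, and at the field sizes
involved the divergence error is far below the voxel size. The
beam's-eye-view (BEV) frame is collimator-rotated, u along leaf travel and
v along the leaf stack, rasterized at 1 mm (finer than the 2 mm dose grid
so that 3.75 mm leaves and half-sigma margins are resolved).

Cumulative water-equivalent path length (WEPL) is traced once per beam on
the full BEV raster with 0.5 mm midpoint sampling of the relative stopping
power (nearest voxel); per-voxel WEPL comes from trilinear interpolation of
that table and agrees with a dense 0.1 mm single-ray integrator to better
than 0.5 mm on 2 mm grids.

The per-layer *target cross-section* marks the BEV pixels whose ray has the
structure present at the depth where the cumulative WEPL equals the layer's
residual range. `layer_cross_section()` defaults to this exact membership;
the planner additionally passes a *depth tolerance band* of half a layer
spacing (`depth_band_mm`), marking pixels whose ray meets the structure
anywhere in $[R - \Delta/2, R + \Delta/2]$. The band reflects that one
energy layer treats a slab of depths, and without it target voxels at the
proximal/distal surface whose Bragg layer misses their WEL interval by a
fraction of a millimetre are silently dropped from every aperture,
producing artificial cold rims.

The *OAR block shadow* marks pixels whose ray enters the OAR at a WEL depth
no deeper than the layer's range — i.e. rays whose Bragg peak would land in
the OAR or its distal region. The proximal-entry convention follows from
the goal of shielding "the OAR and everything behind it"; shadows grow
monotonically with layer range and no extra margin is applied to them by
default (the MLC margin applies to the target side only).

## Leaf sequencing

The MLC has 54 opposing iron leaf pairs of 3.75 mm width; the maximum field
is 150 mm along leaf travel by 200 mm across. The stated "maximum opening
per pair" of 75 mm is interpreted as the *per-leaf retraction* from the
closed central position, because that is the only reading consistent with a
150 mm field parallel to leaf travel; openings may thus span up to
$[-75, 75]$ mm. The 54 × 3.75 mm = 202.5 mm stack slightly exceeds the
200 mm transverse field, so the outermost pairs sit partially outside the
field, which is the binding limit. Leaf positions are quantized to 0.1 mm,
outward for cover (the target is never clipped) and inward for block (the
shadow is never exposed).

* **Cover mode** dilates the layer cross-section by the MLC margin of
  0.5 σ, where σ is the *in-medium* spot sigma at the layer's Bragg depth,
  and opens each pair to the [min u, max u] span of mask pixels in its
  band.
* **Block mode** removes the shadow from the cover mask. A physical pair
  admits one interval, so when a row's admissible pixels split into
  several runs the run with the most pixels is kept, ties resolved toward
  the row's cover centroid. This is exactly the "intentional
  under-irradiation" of block mode: the discarded regions must be supplied
  by other beams. `check_block_feasibility()` verifies that no target
  voxel is geometrically shielded in *every* beam (a voxel is shielded
  when its BEV position is outside every aperture whose layer range
  reaches its depth).

Mirror-symmetric phantom/beam layouts are worth flagging: when the shadow
bisects a row into *equal* runs the tie-break becomes arbitrary, and with
several beams in mirror positions the discarded halves can align. The
default phantom orients the C opening so the reference beam arrangement
avoids such degeneracies (below).

## Spot placement

Spots sit on a hexagonal lattice with nearest-neighbor distance 0.75 σ,
anchored at the centroid of the layer cross-section, and a lattice point is
kept if its distance to the mask is at most 1.0 σ (spots up to one sigma
beyond the lateral target boundary). Both rules use the same in-medium σ at
the Bragg depth as the MLC margin. In block mode, spots whose centers
penetrate more than 0.5 σ into the leaf-covered region are excluded; the
penetration depth is the exact Euclidean distance to the open region
(union of pair rectangles), the boundary case at exactly 0.5 σ is kept,
and enlarging an aperture never removes a previously kept spot. "Overlap by
more than 0.5 σ" is interpreted as center-penetration depth rather than
fractional Gaussian area: it is geometric, unambiguous, and in the same
units as the margin rule.

## Dose engine

The engine uses a fluence-clip-then-transport decomposition. Per layer, the
in-air fluence at the isocenter plane is the weighted sum of unit
Gaussians (σ = in-air sigma) at the spot positions, multiplied by the MLC
transmission map — each BEV pixel carries the exact open-area fraction of
its footprint, softened by a 0.5 mm Gaussian edge (configurable; closed
leaves transmit 0 by default). In parallel geometry the MLC-plane and
iso-plane projections coincide, so clipping at the iso-plane is exact. At
WEL depth $z$ a voxel receives
$\sum_\ell DD_\ell(z)\,[F_\ell \otimes K_{\sigma_{MCS}(z)}](u, v)$:
depth dose times the clipped fluence convolved with the local
multiple-scattering kernel. The depth-dependent convolution is precomputed
at ten sigma values (0–6.5 mm) with linear interpolation in σ, keeping
desk-scale runtime; the engine is exactly linear in spot weights, and with
all apertures fully open the collimated and uncollimated doses agree to
better than 0.1%.

Setup/range scenarios reuse two exact identities of this geometry: shifting
the isocenter moves the fluence pattern relative to the patient while the
per-voxel WEPL field is unchanged, and a uniform RSP scaling multiplies
every WEPL by the same factor. Scenario dose therefore re-evaluates the
cached fluence at shifted coordinates with scaled depths — no re-tracing.

An independent verification path, `dose_plane_reference()`, computes planes
by brute-force sub-spot superposition: each spot Gaussian is split on a
fine quadrature grid over the aperture plane, each sub-spot is transmitted
with the exact open-area fraction of its quadrature cell (binary point
sampling does not converge at leaf edges) and transported with the exact
local σ, with no sigma binning and no shared convolution code.
`verify_beam_gamma()` recalculates a beam in uniform water and compares the
two paths at the isocenter plane with 2%/2 mm gamma — the in-silico analog
of per-beam plan verification.

## Robust optimization

The scenario set is the Cartesian product of seven axis-aligned setup
shifts (0 and ±2 mm along each axis) with three range errors (0, ±3.5%):
21 scenarios, nominal first. Sparse per-scenario dose-influence matrices
are built over the target and OAR voxels (per-spot aperture-clipped
patches, entries below $10^{-4}$ of the spot maximum dropped).

`worst_case_objective()` offers two flavors. The *composite* worst case is
the maximum over scenarios of the total penalty, with the subgradient of
the argmax scenario. The *objective-wise* (`per_term`) worst case lets each
term track its own worst scenario — the coverage term its coldest, the
homogeneity and OAR terms their hottest — and is the planning default: under
the composite maximum the argmax is invariably a cold scenario, hot spots
in the nominal dose are never penalized, and the plans violated the 107%
homogeneity goal by construction. The default objective combines
nominal-scope planning-goal terms (CTV minimum at the 74 Gy(RBE)
prescription, weight 1.5; CTV maximum at 75 Gy, weight 2.5) with
worst-case-scope guard terms at the clinical goal levels (95% / 107% of
prescription, weights 1 / 0.5) and worst-case OAR terms (maximum-dose bound
30 Gy and EUD bound 24 Gy with exponent a = 12, weights 0.02). These
weights are planning defaults tuned on the package's synthetic phantom —
not values from any clinical system — and are reported in the plan summary.

`optimize_weights()` is bound-constrained quasi-Newton (L-BFGS-B) on a
log-sum-exp smoothed worst case, annealed over a fixed temperature schedule
(10%, 2%, 0.5% of the current objective scale); a stage is accepted only if
the *exact* worst case decreases, so the reported objective history is
non-increasing and a start at the optimum terminates immediately. The
smoothing exists because the exact maximum is piecewise smooth and plain
(sub)gradient descent stalls on its kinks long before the optimum. The
pipeline is fully deterministic: the seed is recorded for provenance and
would only feed optional stochastic restarts, which are off.

Plans are normalized after optimization so the interpolated median CTV dose
equals the prescription (74 Gy(RBE) in 37 fractions); doses are reported as
Gy(RBE) under the constant-RBE convention (factor 1.1 folded into the
prescription level, as is standard clinically).

## Evaluation

$D_{x\%}$ uses linear interpolation between order statistics (quantile
type 7); at 2 mm grids the difference from nearest-rank percentiles is far
below 0.1 Gy. EUD is the power-law mean $(\overline{D^a})^{1/a}$. The
scenario table reports D98%, D2%, Dmean and EUD per (scenario, structure)
with min/max envelope bands. Gamma analysis is *global* (dose difference
normalized to the reference maximum, 10% low-dose threshold), with a search
radius of three times the DTA and 0.25 mm sub-pixel interpolation of the
evaluated plane; the vectorized search is verified against a per-point
exhaustive oracle on the same lattice. The 80–20% penumbra is read off a
profile by linear interpolation on the falloff side.

## The synthetic phantom: what it emulates and what it does not

`phantom_spec()` builds a water cylinder (RSP exactly 1.0, radius 45 mm,
height 60 mm) in air on a 2 mm grid, holding a C-shaped target (outer
radius 20 mm, height 24 mm, wrap 200°) partially surrounding a cylindrical
OAR (radius 4 mm) with a 7 mm radial gap — the geometric challenge of a
target abutting and partly wrapping a small serial organ, as in orbital or
sinonasal disease. The reference beam arrangement is three beams at gantry
0/120/240 with collimator 0. The C opening faces the anterior (+y) side so
that two of the three OAR shadow sectors fall inside the opening and only
one beam shields a target arc, which the other two compensate; this mirrors
the trial-and-error beam/collimator selection that block-mode planning
requires (with the gantry angles fixed, the phantom orientation carries
that degree of freedom). Wider wraps in mirror-symmetric orientations make
the single-interval leaf fits degenerate and were rejected at design time.

What passing tests on this phantom do **not** show about real data: there
is no tissue heterogeneity (no HU calibration uncertainty, no
heterogeneity-induced halo asymmetry), the target is two orders of
magnitude simpler than a clinical CTV, the dose engine is an analytic
pencil-beam model rather than Monte Carlo, and the target volume (~34 cm³)
is small enough that surface voxels dominate the D98%/D2% statistics,
making the planning goals *harder* to meet than for large clinical volumes.
Interleaf leakage, tongue-and-groove effects, LET/RBE variation, spot
timing and deliverability limits are all out of scope.

## Problem sizes and numerical defaults

The default experiment (acceptance-scale) uses a 55×55×32 voxel grid,
roughly 12–13 energy layers and 500–650 spots per beam, 21 scenarios, and
about 600 quasi-Newton iterations; a full three-beam robust plan takes
about two minutes on one CPU. Key tolerances: leaf step 0.1 mm (outward
for cover, inward for block); influence cutoff $10^{-4}$ of the per-spot
maximum; sigma bins 0, 0.4, 0.8, 1.2, 1.7, 2.3, 3, 4, 5, 6.5 mm; WEPL ray
step 0.5 mm; gamma search step 0.25 mm with radius 3×DTA; optimizer
relative-improvement tolerance $10^{-5}$. Degenerate inputs are rejected
with explicit messages (empty masks, non-monotone calibration tables,
targets deeper than the maximum reachable range, all-zero influence), and
an infeasible block configuration aborts the pipeline with the feasibility
report.

## Known limitations

Parallel-ray geometry (a divergent mode is reserved but not implemented);
no nuclear halo; single-Gaussian lateral model; no MU/deliverability
constraints; composite and per-term worst case only (no voxel-wise or
probabilistic robustness); DICOM import/export not included — phantoms are
generated or read from the package's archive format, and all tabular
artifacts are plain text.
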