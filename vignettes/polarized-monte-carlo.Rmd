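---
title: "Polarized light transport in voxelated turbid media: model and methods"
author: "polstokes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarized light transport in voxelated turbid media: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polstokes)
```

## The problem

Polarized light is exquisitely sensitive to the microstructure of a
scattering medium: two tissues with identical absorption, reduced
scattering and refractive index — indistinguishable to any
intensity-only diffuse-optics measurement — can differ strongly in the
polarization state of their backscattered light, because polarization
responds to the *shape* of the single-scattering phase function, not
just its first moment. `polstokes` simulates this regime: Monte Carlo
transport of polarized photon packets through an arbitrarily
heterogeneous medium described by a regular voxel grid, with each voxel
label mapped to a population of spherical scatterers (or directly to
bulk optical properties), and backscattered Stokes images accumulated
on an area detector.

## Model

### Stokes vectors and the meridian plane

Each photon packet carries a Stokes vector $S = [I, Q, U, V]$:
total intensity, horizontal/vertical linear balance, $\pm 45^\circ$
linear balance, and circular handedness. A Stokes vector is only
meaningful relative to a reference plane; between scattering events the
package uses the *meridian plane* — the plane through the propagation
direction and the global $+z$ axis. Individual packets remain fully
polarized ($\sqrt{Q^2+U^2+V^2} = I$, a tested invariant);
depolarization is an ensemble property that emerges when many packets
with decorrelated polarization states are summed on the detector.

### Mie precomputation

A medium defined by sphere radius $r$ (µm), number density $\rho$
(µm⁻³), sphere index $n_{sph}$ and host index $n$ at vacuum wavelength
$\lambda$ (nm) is preprocessed once on the host side:

* the Lorenz–Mie coefficients $a_n, b_n$ are computed for size
  parameter $x = 2\pi r n/\lambda$ and relative index $m = n_{sph}/n$,
  with the Wiscombe truncation $N = \lceil x + 4x^{1/3} + 2\rceil$ and
  the logarithmic derivative by downward recurrence started 15 orders
  above $N$ (the standard numerically stable route);
* the scattering cross-section gives
  $\mu_s\,[\mathrm{mm^{-1}}] = 1000\,\rho\, C_{sca}$, and the standard
  coefficient cross-terms give the asymmetry parameter $g$, hence
  $\mu_s' = \mu_s(1-g)$;
* the four independent elements of the single-sphere scattering
  (Mueller) matrix,
  $s_{11} = (|S_1|^2{+}|S_2|^2)/2$, $s_{12} = (|S_2|^2{-}|S_1|^2)/2$,
  $s_{33} = \mathrm{Re}(S_2 S_1^*)$, $s_{34} = \mathrm{Im}(S_2 S_1^*)$,
  are tabulated at 1000 evenly spaced zenith angles on $[0, \pi]$
  (endpoints included; transport looks elements up by nearest index).

Only real refractive indices are supported — absorption enters solely
through the bulk $\mu_a$ — and the suspension is monodisperse. The
tables are scaled by one common factor so that
$2\pi\int_0^\pi s_{11}\sin\theta \,d\theta = 1$ on the stored grid
(trapezoidal rule). Sampling and Stokes updates depend only on ratios
of the elements, so this normalisation is observable-neutral; fixing a
convention makes tables comparable across media and directly testable
(the identity $s_{11}^2 - s_{12}^2 = s_{33}^2 + s_{34}^2$, exact for a
homogeneous sphere, holds at every grid point).

```{r mie}
spec <- scatterer_spec(radius_um = 0.3, density_per_um3 = 2.198e-2,
                       n_sphere = 1.59, n_background = 1.33,
                       wavelength_nm = 632.8)
bulk_properties(spec, mua_per_mm = 0.001)
```

### Transport

The transport loop follows the classic launch / move / absorb / scatter
/ detect cycle:

* **Free paths** are sampled in *scattering* optical depth,
  $\tau = -\ln \xi$, and consumed voxel-by-voxel: a segment of length
  $\ell$ in a voxel with scattering coefficient $\mu_s$ uses
  $\mu_s \ell$ of the budget. Absorption does not terminate or deflect
  packets; each traversed segment attenuates the weight continuously by
  $e^{-\mu_a \ell}$, with the loss deposited in the voxel it occurred
  in (continuous absorption). Compared with per-interaction albedo
  weighting this changes variance, not expectation, and handles
  heterogeneous $\mu_a$ cleanly.
* **Scattering angles** $(\theta, \phi)$ follow the bivariate polarized
  phase function
  $P(\theta,\phi) = s_{11}(\theta) I + s_{12}(\theta)
  [Q\cos 2\phi + U\sin 2\phi]$
  (Stokes components in the current meridian frame), weighted by
  $\sin\theta$. Because the $s_{12}$ term integrates to zero over
  azimuth, $\theta$ has the *exact* marginal
  $s_{11}(\theta)\sin\theta$: the sampler draws $\theta$ by inverse
  transform over the table cells (cosine uniform within a cell) and
  then accepts $\phi$ by rejection against the envelope
  $s_{11} + |s_{12}|$. Since $|s_{12}| \le s_{11}$, the acceptance rate
  is at least 50% for any polarization state — a plain bivariate
  rejection sampler with uniform-$\cos\theta$ candidates produces the
  same law but its acceptance collapses to a few percent for
  forward-peaked media ($g \gtrsim 0.8$), which dominates runtime. The
  two-stage sampler is exact, not an approximation; a chi-squared test
  against direct quadrature of the phase function is part of the
  acceptance suite.
* **Stokes update**: the vector is re-referenced into the scattering
  plane by the Mueller rotation $R(\phi)$
  ($Q' = Q\cos 2\psi + U \sin 2\psi$,
  $U' = -Q \sin 2\psi + U\cos2\psi$), multiplied by the tabulated
  $M(\theta)$, and re-referenced into the new meridian plane by
  $R(\gamma)$. All reference frames are handled by explicit 3-vector
  algebra — the meridian basis of a direction, the transported
  scattering-plane basis, and the signed angle $\gamma$ between them —
  rather than spherical trigonometry, which removes the usual
  quadrant-sign pitfalls. When a direction lies within $10^{-6}$ of
  $\pm z$ the meridian plane degenerates and is taken as the $x$–$z$
  plane, deterministically. After each event the vector is renormalised
  to $I = 1$; the sphere identity guarantees this preserves full
  polarization.
* **Boundaries** are refractive-index matched (no Fresnel reflection or
  refraction — a stated non-goal). The $z = 0$ facet detects, the
  opposite facet absorbs escapes ("transmitted"), and the four lateral
  facets either absorb escapes or wrap cyclically to emulate a
  laterally infinite slab. Voxel label 0 is ambient: entering it
  terminates the packet.
* **Russian roulette** below weight $10^{-4}$: survive with probability
  $p = 0.1$ and boost by $1/p$ (conventional values; unbiasedness is
  tested). Launch positions are nudged $10^{-9}$ mm into the domain to
  avoid boundary-ownership ambiguity, and the same nudge steps packets
  across voxel faces.

On detection, the Stokes vector is rotated into the detector frame —
reference axis along global $+x$ projected on the plane normal to the
exit direction, so co-polarized detection of a $[1,1,0,0]$ source reads
positive $Q$ — and the weighted components are accumulated into the
pixel containing the exit point. Totals cover every $z=0$ escape;
weight exiting outside the pixel extent is tallied separately.

### Numerical bookkeeping

The run maintains an exact weight ledger: launched weight plus roulette
boosts must equal detected + transmitted + side-escaped + ambient +
absorbed + roulette-killed weight. The identity holds trajectory by
trajectory, so the audit is verified to $10^{-9}$ relative rather than
statistically. The per-photon variance of detected $I$, $Q$, $U$, $V$
is accumulated alongside the means, giving each run an internal
standard-error estimate (tested against the across-seed spread).

All randomness flows through R's RNG: `set.seed(config$seed)` before
the compiled loop, which draws exclusively via `unif_rand()`. Identical
config and seed give bit-identical output arrays.

## Benchmark scenes

Three programmatic scenes exercise the simulator end to end; all use a
horizontally polarized source $S = [1,1,0,0]$ at 632.8 nm, host
$n = 1.33$, sphere index 1.59:

* `benchmark_homogeneous()` — a 20×20×10 mm non-absorbing slab
  ($r = 1.015$ µm, $\rho = 1.152\times10^{-4}$ µm⁻³), pencil beam at
  the bottom centre, 20×20 mm detector. By symmetry the total detected
  $U$ and $V$ vanish; the suite checks both against their standard
  errors.
* `benchmark_twolayer(d_e)` — a 100×100×50 mm slab, superficial layer
  of thickness $d_e \in [0, 10]$ mm with $r = 0.05$ µm,
  $\rho = 19.11$ µm⁻³ over a bottom layer with $r = 0.3$ µm,
  $\rho = 2.198\times10^{-2}$ µm⁻³, both with
  $\mu_a = 0.001$ mm⁻¹. Both layers have $\mu_s' = 1$ mm⁻¹ within 1%
  (asserted at build time), so the total reflected intensity is nearly
  flat in $d_e$ — it rises only ~0.17%, a sub-diffusive
  phase-function effect — while total $Q$ rises strongly from the
  bottom-medium asymptote towards the superficial-medium asymptote as
  the small-sphere layer thickens. 1 mm voxels align every integer
  interface with voxel faces, so the layered geometry is represented
  exactly.
* `benchmark_inclusion()` — a 10×10×1.2 mm slab, planar source over
  the full face, cyclic lateral boundaries, and a 0.5 mm-radius
  spherical inclusion at (6, 6, 0.6) mm whose sphere population
  ($r = 1$ µm, $\rho = 1.11\times10^{-3}$ µm⁻³) matches the background
  ($r = 0.05$ µm, $\rho = 19.11$ µm⁻³) in $\mu_a$, $\mu_s'$ and $n$.
  An intensity-only diffuse forward model sees no contrast; the $Q$
  image shows the inclusion at far higher contrast-to-noise than $I$
  (quantified by `inclusion_cnr()`). Voxels are 0.1 mm — about ten
  across the inclusion diameter — the finest grid that keeps the scene
  desk-scale; the sphere is rasterised by voxel-centre membership.

## What the generator emulates — and what it does not

The scenes above are synthetic by construction: monodisperse spherical
scatterers, index-matched boundaries, piecewise-constant media on a
regular grid, and fully polarized pencil or uniform planar sources.
Passing tests demonstrate correct polarized radiative transport under
those assumptions. They do *not* demonstrate fidelity to real tissue,
which has polydisperse and non-spherical scatterers, birefringence,
refractive-index mismatch at surfaces (Fresnel effects change absolute
reflectance at the few-percent level), and continuous property
variation. Within the model's scope, the quantities with printed
reference values — the three $\mu_s' = 1$ mm⁻¹ design populations and
the two-layer total reflectance 0.9080–0.9095 — are reproduced by the
acceptance suite.

## Parameter and design notes

* `n_angles` (default 1000): zenith resolution of the matrix tables;
  the transport lookup is nearest-index, so angular discretisation
  error is $O(\pi/n_{angles})$ in the phase function.
* Voxel size: cubic voxels only; choose it to resolve the finest
  geometric feature (layer interfaces on voxel faces are exact;
  spheres are center-in-voxel rasterised). A voxel whose centre lies
  exactly on a layer interface belongs to the deeper layer.
* Roulette threshold/survival $10^{-4}$ / 0.1; with the benchmark
  $\mu_a$ values roulette almost never fires (weight decays slowly),
  but it bounds worst-case trajectory length.
* Detector pixels default to 100×100 over the detector extent
  (0.2 mm pitch for the homogeneous benchmark); the headline
  quantities of record are the per-photon totals, which are
  pixelisation-free.
* Photon counts: the builders default to $10^6$, which resolves the
  two-layer totals to a standard error of about $2\times10^{-4}$ in a
  few minutes on one core. The test suite uses $10^6$ for the
  reflectance checks, $10^7$ for the inclusion contrast scene (it is
  two orders of magnitude cheaper per photon), and smaller counts for
  distributional property tests; these sizes are stated in the tests
  themselves.
* Table caching: `write_smatrix_table()` / `read_smatrix_table()`
  round-trip bit-for-bit, so Mie precomputation can be cached; the
  serialisation is R's portable binary format.

## Known limitations

Mismatched refractive indices (Fresnel reflection/refraction) are not
modelled; neither are coated or non-spherical scatterers, size
distributions, birefringence, coherence effects, or time-resolved
output. The per-voxel absorption grid is accumulated (optionally) but
is a secondary observable; surface Stokes images are the primary
output. Cross-solver image RMSE values require the external reference
solver's output; the `rmse_log10()` metric is provided so users who
have such output can make the comparison on the matching detector area.
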