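# polstokes

Monte Carlo simulation of **polarized light transport in heterogeneous
turbid media**, for biomedical-optics work where intensity alone cannot
separate tissues: media with identical absorption μa, reduced scattering
μs′ = μs(1 − g) and refractive index n are invisible to diffuse
intensity measurements, but differences in their underlying scatterer
populations still imprint on the backscattered Stokes components.

The simulator is voxel-based: a 3D integer label volume assigns each
cubic voxel to a medium, and each medium is described either by bulk
optics (μa, μs, g, n) plus a scattering-matrix table, or by a population
of spheres (radius r in µm, number density ρ in µm⁻³, index n_sph) from
which μs, g and the four-element single-sphere Mueller matrix

    M(θ) = [ s11  s12   0    0
             s12  s11   0    0
              0    0   s33  s34
              0    0  −s34  s33 ]

are precomputed by Mie theory on a grid of 1000 zenith angles. Photon
packets carry a Stokes vector S = [I, Q, U, V] referenced to the
meridian plane (the plane through the propagation direction and +z).
At each scattering event the pair (θ, φ) is drawn from the polarized
phase function

    P(θ, φ) = s11(θ) I + s12(θ) [Q cos 2φ + U sin 2φ],

the Stokes vector is updated by the rotation–matrix–rotation
composition R(γ) M(θ) R(φ), and weight is attenuated continuously by
exp(−μa ℓ) along every traversed voxel segment. Escapes through the
z = 0 facet are rotated into the detector frame and accumulated into
pixelated I, Q, U, V images plus per-photon totals with internal
standard errors. The compiled (Rcpp) inner loop simulates about
3–5 × 10³ photons/s in a diffusive slab and ~5 × 10⁵ photons/s in thin
scenes, single-threaded and exactly reproducible by seed.

## Worked example

A two-layer slab whose layers share μa = 0.001 mm⁻¹ and μs′ = 1 mm⁻¹
but differ in sphere population (superficial: r = 0.05 µm at
ρ = 19.11 µm⁻³; bottom: r = 0.3 µm at ρ = 2.198 × 10⁻² µm⁻³):

```r
library(polstokes)

bulk_properties(scatterer_spec(0.3, 2.198e-2, 1.59, 1.33, 632.8), 0.001)
#> Bulk optics: mua = 0.001 mm^-1, mus = 6.913 mm^-1, g = 0.8554, mus' = 0.9999 mm^-1, n = 1.33

res <- run_simulation(benchmark_twolayer(d_e_mm = 10, photons = 1e5, seed = 8))
res
#> Polarized MC result: 1e+05 photons
#>   total per photon  I = 0.909687 +/- 0.000712
#>                     Q = 0.285014  U = -0.000262  V = -0.000005
#>   transmitted 0.0094, side 0.0073, absorbed 0.0736
#>   energy audit balanced (relative imbalance 6.11e-14)
#>   rejection-sampler acceptance rate 0.543
```

With a 10 mm superficial layer of small (nearly Rayleigh) spheres the
backscattered light stays strongly co-polarized (total Q ≈ 0.29 per
launched photon); at d_e = 0 the large-sphere medium scrambles
polarization and total Q drops to ≈ 0.04, while total I barely moves
(≈ 0.908 → 0.910) because both layers share the same μs′ — the
polarization channel sees what intensity cannot. `benchmark_inclusion()`
builds the companion scene: a sphere-population inclusion with matched
μa/μs′/n inside a thin slab, detectable in the Q image but not in I
(`inclusion_cnr()` quantifies the contrast-to-noise).

Configurations are plain lists or JSON files (`parse_config()` gives
the schema); `inst/cli/polstokes` exposes `run`, `mie` and `benchmark`
subcommands for shell use.

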