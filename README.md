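# ecmremodel

Simulation of force-driven plastic remodeling of fibrous extracellular
matrices (ECMs) — collagen I and fibrin — at two scales, plus the
experimental metrics used to quantify remodeling in 3D cell-in-gel
imaging.

Cells embedded in 3D biopolymer gels pull on nearby fibers through dynamic
filopodia. Because the crosslinks joining ECM fibers are transient slip
bonds, sustained pulling does three things at once: it recruits and
densifies matrix at the cell surface, it relaxes the network stress the
cell has built up, and it leaves much of the deformation in place after
the cell's forces stop — the matrix is remodeled *plastically*, on the
time scale of minutes. `ecmremodel` packages the computational machinery
to study this process:

* **Discrete fiber network engine** (compiled core). Fibers are chains of
  cylindrical segments with harmonic stretch and bend energies
  (U_s = κ_e Δr²/2, U_b = κ_b Δθ²/2), segment volume exclusion, and
  crosslink springs joining neighboring fibers. Nodes follow overdamped
  dynamics ζ dr/dt = F integrated with explicit Euler steps in a periodic
  box. Crosslinks unbind stochastically at the Bell slip-bond rate
  k_u = k_u0 · exp(λF/k_B T), applied per step with probability
  1 − exp(−k_u Δt); rebinding is optional. Filopodial pulling is a zone
  rule: any segment within 2 µm of the loading boundary feels a constant
  point force toward it. Readouts: fiber concentration profiles along the
  loading axis, accumulation time series, cross-plane stress, stress
  retention, and parameter sweeps (force, crosslink density, unbinding
  rate, mechanosensitivity) with replicate statistics.
* **Continuum viscoplastic solver** (spherically symmetric finite
  elements). The ECM around a contracting cell is an elastic medium whose
  Young's modulus degrades exponentially, E = A·exp(−B ε₁), with the
  running maximum principal tensile elastic strain (anchored at
  (2%, 1 kPa) and (6%, 0.2 kPa)), combined with Norton-Hoff power-law
  overstress creep and linear softening of the yield stress with plastic
  strain. Outputs: interface displacement and von Mises stress histories,
  recoverability index, half-max damage radius, and the error made by
  back-calculating stresses as if the matrix were still undamaged and
  elastic (the traction-force-microscopy scenario).
* **Remodeling metrics** on gridded 3D data: displacement length (mean
  |u| in a 60 µm ROI), densification factor (DF = I_dens/I_far over 5 µm
  radial windows), recoverability index (RI = 100·‖u_decell‖/‖u_overall‖),
  and radial displacement decay profiles — plus a synthetic fixture
  generator with known ground truth so every metric is testable without
  imaging data.

## Worked example

```r
library(ecmremodel)

# Desk-scale discrete run: 100 pN per loaded segment, weakly
# mechanosensitive crosslinks (0.3x of the 1x baseline)
cfg <- desk_config(seed = 1, lambda = 0.3e-4)
run <- simulate_remodeling(cfg, seed = 1)
acc <- accumulation_timeseries(run$series, region_depth = 3)
st  <- stress_series(run$series)
round(c(peak = max(acc$concentration),
        final = acc$concentration[nrow(acc)],
        peak_stress_Pa = attr(st, "peak"),
        retention = stress_retention_ratio(st)), 3)
#>           peak          final peak_stress_Pa      retention
#>          1.799          1.604        116.426          0.882
```

The normalized fiber concentration within 3 µm of the loading boundary
rises from 1 to about 1.8 during loading, and most of it (1.6) remains
after the forces are released: at these settings remodeling is largely
plastic. The cross-plane stress peaks above 100 Pa and still holds ~88%
of its peak at load cessation — unbinding has begun to relax the network
but has not collapsed it.

```r
# Continuum baseline: 0.1 kPa load, 1500 s creep, damage + softening
sol <- solve_sphere(continuum_config())
round(c(RI_pct = recoverability_index_model(sol),
        damage_radius_diam = damage_radius(sol)$cell_diameters,
        stress_overestimate = attr(apparent_true_stress_ratio(sol), "at_probe")), 2)
#>              RI_pct  damage_radius_diam stress_overestimate
#>               56.85                0.73                3.67
```

About 57% of the interface displacement is recovered on unload; the
half-max damage front sits 0.73 cell diameters from the cell edge; and a
naive elastic back-calculation of stress from the recovered deformation
overestimates the true stress 3.7-fold near the cell (approaching the
5-fold modulus degradation limit as creep lengthens).

A command-line interface wrapping the same functions is installed as
`exec/ecmremodel` (subcommands `generate`, `run`, `sweep`, `continuum`,
`metrics`, `fixture`).

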