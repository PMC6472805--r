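---
title: "Modeling force-driven plastic remodeling of fibrous extracellular matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling force-driven plastic remodeling of fibrous extracellular matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecmremodel)
```

Cells embedded in three-dimensional fibrous extracellular matrices (ECMs)
such as collagen I and fibrin remodel their surroundings within minutes:
dynamic, filopodium-driven pulling recruits fibers toward the cell body,
densifies the pericellular matrix, and leaves a substantial fraction of the
deformation in place after the cell's forces are removed. `ecmremodel`
provides the two computational engines needed to study this process --- a
discrete crosslinked fiber-network simulator with force-sensitive crosslink
kinetics, and a spherically symmetric continuum solver with viscoplasticity,
elastic damage and plastic softening --- together with the standard
experimental remodeling metrics computed on gridded displacement and
intensity data.

This vignette documents the models, their assumptions, the tunable
parameters (with units and the reasoning behind each default), the numerical
choices, and the known limitations. Everything quantitative stated here is
computed by the package's test suite or the acceptance script; nothing is
imported from elsewhere.

## 1. The discrete fiber-network engine

### Model

A network of fibers fills a periodic box (default 20 x 20 x 20 um^3; x and y
periodic, fiber ends near the +z face pinned, the loading boundary at
z = 0). Each fiber is a chain of cylindrical segments with harmonic stretch
and bend potentials

$$U_s = \tfrac12 \kappa_e \,\Delta r^2, \qquad
  U_b = \tfrac12 \kappa_b \,\Delta\theta^2,$$

where $\Delta r$ is the deviation of a segment from its rest length and
$\Delta\theta$ the deviation of consecutive segments from collinearity.
Segments additionally repel each other below one fiber diameter at closest
approach (a quadratic overlap penalty), and fibers are joined by crosslinks:
two-armed springs attached at arc-coordinates on their host segments, with
forces distributed to segment end nodes by lever-arm weights so the point
force and its torque are reproduced exactly.

The network is athermal. Every node follows the overdamped equation of
motion $\zeta\,\dot{\mathbf r}_i = \mathbf F_i + \mathbf F_{c,i}$ integrated
with explicit Euler steps; $\mathbf F_{c,i}$ is the filopodial loading force
(below) and $\mathbf F_i$ collects stretch, bend, repulsion and crosslink
terms. Each force term is the exact negative gradient of its potential; the
test suite verifies this against central finite differences to a relative
error below $10^{-4}$ and checks global force balance (internal forces sum
to zero) and energy dissipation along unloaded trajectories.

Crosslinks unbind stochastically as slip bonds. A bond carrying tensile
force $F$ (compression does not count) unbinds at the Bell rate
$k_u = k_{u0}\, e^{\lambda F / k_B T}$, realized per time step with
probability $1 - e^{-k_u \Delta t}$. An optional rebinding channel lets an
unbound crosslink whose attachment loci are within a capture reach rebind at
a constant rate, reattaching at the current geometry with zero strain (a
choice that cannot inject elastic energy). A Monte-Carlo test confirms the
realized unbinding statistics against the analytic rate over a three-decade
force range within binomial 3-sigma bounds at $10^4$ trials.

### Loading protocol

Filopodial pulling is modeled as a zone rule: while loading is active, every
fiber segment whose midpoint lies within 2 um of the z = 0 boundary receives
a point force of constant magnitude directed toward that boundary, split
between its end nodes. Segments entering the zone acquire the load; segments
leaving it lose the load. This realizes a continuously renewing population
of filopodial attachments without an explicit protrusion state machine. A
per-fiber variant (one site force shared by a fiber's in-zone segments) is
available behind the `load_mode` switch; conventions differ on whether
filopodial loads are tallied per fiber or per segment, and the per-segment
rule is the one that matches a continuously renewing attachment population.

A full protocol is: generate, relax to a prestress-free plateau (crosslink
kinetics disabled during this reference-state relaxation), load for a fixed
duration, then release all external forces and let the network relax again
— the in-silico analogue of decellularization. Time is reported on the
normalized axis with 0 at load onset and 1 at cessation; the post phase
extends beyond normalized time 2. The z = 0 boundary is a hard wall (nodes
cannot cross it), which is what makes "pulled to the boundary" a
well-defined accumulated state.

### Network generation

Fibers nucleate at uniform random positions with uniform random
orientations and grow as straight chains of equal-rest-length segments
(0.5 um default). Nucleation sites are drawn from a slab extended beyond
the z walls and chains are clipped exactly at the walls (with short
boundary stubs that hinge freely), because clipping a stationary line
process preserves its intensity: the initial concentration profile is
uniform to within sampling noise, which the tests assert. Fibers are added
until a target length density is reached (default 1.7 um of fiber per um^3,
about 1.3% volume fraction at 100 nm diameter --- a plausible figure for a
3 mg/mL gel).

Crosslink candidates are all distinct-fiber segment pairs within a capture
reach at closest approach, found with a periodic cell list and verified in
the tests against a brute-force all-pairs oracle. A random subsample
becomes crosslinks --- the subsample fraction scales linearly with the
relative crosslink density, so 0.5x halves the count exactly --- attached
at the closest-approach points. Two generation choices deserve emphasis:

* **Capture reach (default 0.3 um).** For straight random fibers the
  expected number of pairs within a distance $\delta$ scales as
  $\tfrac{\pi}{4}\delta L^2/V$; at a reach of twice the 20 nm arm length a
  percolating network would need an unphysical (~20%) fiber volume
  fraction. Real gels crosslink because fibers polymerize *into* contact;
  the larger default reach stands in for that formation-time capture range
  and yields 3--4 crosslinks per fiber at the 1x baseline, which percolates
  from the loading zone to the pinned boundary (checked with a graph
  component analysis).
* **Prestress-free formation.** A crosslink formed at generation has its
  spring rest length set to its formation-time separation, so the freshly
  generated network carries essentially no prestress and the pre-load
  relaxation settles quickly to the near-zero-stress reference state the
  protocol requires. Crosslinks created programmatically elsewhere default
  to the nominal rest length of two 20 nm arms.

### Parameters and the desk-scale preset

Fiber diameter (100 nm), fiber material modulus (125 MPa), crosslink arm
length (20 nm), the 20 um domain, the 2 um loading zone and the 1 pN--1 nN
force range are taken at face value. The unit system is pN--um--s, in which
1 pN/um^2 = 1 Pa and $k_BT$ at 310 K is 4.28e-3 pN um.

A second group of parameters is *assumed*: zero-force unbinding rate
$k_{u0}$ (1x = 0.01 /s), mechanosensitivity $\lambda$ (1x = 1e-4 um = 0.1 nm,
a typical slip-bond length scale), drag per node, time step, crosslink
spring stiffness (1000 pN/um), repulsion stiffness, and the absolute
crosslink density baseline. These live in `sim_config()` with documented
defaults, are reported by `load_config()` when a run relies on them, and
relative sweep factors (0.1x, 0.3x, ...) multiply them. The 1x kinetic
baselines were chosen so that the engine reproduces, at 100 pN per site,
the qualitative regime map reported for such gels: near-full recovery at
piconewton loads, strong and largely irreversible recruitment at
~100--300 pN with weakly mechanosensitive crosslinks, and force-destabilized
stress traces at nanonewton loads.

`desk_config()` is the problem size used by the test suite and sweeps: a
10 x 10 x 10 um^3 box, 5 um fibers (~3400 segments, ~1000--1500 crosslinks
at 1x), 8 s of loading and 10 s of relaxation at $\Delta t$ = 1 ms. Two
coarse-graining choices make this tractable with an explicit integrator:

* the axial stiffness is overridden to $\kappa_e$ = 5e3 pN/um. Fiber
  strain at the forces studied stays below ~2--6%, so
  the network remains effectively inextensible while the stable time step
  grows by orders of magnitude compared to the fully derived
  $EA/l_0 \approx 2\times10^6$ pN/um;
* the per-step displacement cap (an integration guard, default one tenth
  of a segment length) is widened to 0.2 um so that free ballistic motion
  of heavily loaded nodes at 1 nN — fast but accurately integrated — is
  not misflagged as instability. Stiffness-driven stability is governed by
  $\kappa\,\Delta t/\zeta \lesssim 0.7$ at these settings.

One desk-scale concession matters for interpretation: because the desk
network is soft relative to the loads, the *transient* peak concentration
saturates once the zone material has compacted, and the biphasic
dependences on crosslink density and on mechanosensitivity express
themselves in the *post-relaxation* (plastic) accumulation rather than in
the transient peak. The sweep functions report both; the suite asserts the
sigmoidal force response on the peak and the biphasic responses on the
plastic accumulation. At full experimental stiffness the two readouts
coincide qualitatively.

### Readouts

Concentration profiles distribute each segment's rest length (the conserved
material measure) over z bins in proportion to geometric overlap, normalized
by the uniform initial density; mass conservation is then exact by
construction and asserted to 0.1%. The accumulation time series averages
the region within 3 um (or 5 um) of the loading boundary. Cross-plane
stress sums the normal components of axial segment tensions, plus crossing
crosslink forces, over a plane parallel to the loading boundary (default
mid-domain) divided by its area; a hand-built uniformly tense chain
reproduces the applied force to within 1% at any plane position. The
stress retention ratio divides the stress just before load cessation by the
loading-phase peak. `parameter_sweep()` runs replicate seeds per swept value
and reports mean and s.e.m.; replicate networks are shared across values of
force and kinetic axes (the reference network does not depend on them).

## 2. The continuum viscoplastic solver

### Model

At the continuum scale the ECM around a contracting cell is a spherical
shell $a \le r \le R$ (cell radius $a$ = 10 um by default, $R$ = 10a) with
a radial surface tension $p$ at the cavity wall pulling the matrix inward
--- the coarse-grained filopodial pull --- under a ramp, creep
(constant-$p$), unload, hold history. The material combines:

* small-strain isotropic elasticity whose Young's modulus degrades
  exponentially, $E = A e^{-B\epsilon_1}$, with the running maximum
  principal *tensile elastic* strain $\epsilon_1$; $A$ and $B$ are fixed by
  the anchor points $(\epsilon_{1s}, E_s)$ and $(\epsilon_{1e}, E_e)$,
  default (0.02, 1 kPa) and (0.06, 0.2 kPa). Driving damage by the running
  maximum makes it irreversible, matching the persistence of degraded
  modulus profiles after unloading;
* Norton-Hoff power-law overstress viscoplasticity: equivalent plastic
  strain rate $C \langle(\sigma_{vm}-\sigma_y)/\sigma_{ref}\rangle^{n}$
  with associated (von Mises) flow, which in spherical symmetry reduces to
  $\dot\epsilon^p_{rr} = \pm\dot\epsilon^p_{eq}$,
  $\dot\epsilon^p_{\theta\theta} = \mp\tfrac12\dot\epsilon^p_{eq}$;
* linear softening of the yield stress beyond a critical equivalent
  plastic strain, floored at a small positive value.

The flow-law constants are assumptions (the source tabulates them only in
unavailable supplementary material): $C$ = 1e-4 /s, $n$ = 2,
$\sigma_{y0} = \sigma_{ref}$ = 35 Pa, softening slope -300 Pa per unit
plastic strain beyond 0.03, floor 5 Pa, Poisson ratio 0.3. They were fixed,
once, so that the baseline 0.1 kPa / 1500 s creep run sits in the reported
regime: recoverability of order 50--60% with softening and visibly higher
without it, damage radii below one cell diameter growing with creep time,
and an apparent-stress overestimation approaching (but not exceeding) the
five-fold bound set by the modulus degradation ratio.

### Numerics

Displacement-based linear finite elements on a geometric radial grid
(default 200 nodes), 2-point Gauss assembly with the $r^2$ metric, outer
boundary fixed, inner boundary loaded by the surface traction. Each step
solves the tridiagonal equilibrium system exactly (a Thomas solver in
compiled code), updates the damage state from the new elastic strains, and
advances the plastic strain explicitly with an adaptive time step that
bounds the per-step equivalent-strain increment (2e-4 by default) and never
crosses a phase boundary. Halving both resolutions moves the
recoverability index by less than 1% and the damage radius by less than
one element. The pure elastic limit matches the closed-form pressurized
cavity solution to a relative error below 2e-3 and reproduces the
$r^{-2}$ far-field displacement decay within 0.02 of the exponent when the
outer boundary is pushed to 50a (with a finite fixed boundary at 10a the
superposed image term would contaminate the far-field fit).

### Outputs

* **Recoverability index (RI)**: 100 x (displacement recovered between the
  end of creep and the final unloaded state) / (displacement at the end of
  creep), at the cell-ECM interface. 100% in the elastic limit (exactly, by
  construction); decreasing with load, creep duration, and softening.
* **Damage radius**: the outermost radius, measured from the cell edge, at
  which the damage variable $(E_s - E)/(E_s - E_e)$ reaches half its
  maximum attained value; reported in um and in cell-diameter (2a)
  multiples. It grows with creep time and with earlier onset strain, and
  shrinks with a later saturation strain.
* **Apparent/true stress ratio**: stress back-calculated from the model's
  displacements assuming the *undamaged* modulus, divided by the model's
  true von Mises stress at the end of creep. Two protocols are computed:
  from the total deformation, and from the unload-recovered deformation
  (the traction-force-microscopy protocol). The ratio profile is 1
  everywhere for an undamaged elastic run and decays toward 1 away from
  the cell. The headline scalar is taken at the stress-evaluation point
  5 um outward from the load surface: at the $r=a$ shell itself the
  boundary condition pins the radial stress while flow relaxes the
  deviator toward the softened yield surface, a geometric artifact of the
  1-D spherical reduction rather than a statement about the ECM near the
  load.

### Geometry reduction

A fuller treatment would use a 2-D axisymmetric finite-element mesh with
the load applied on an annular patch slightly outward of the cell edge.
The spherically symmetric reduction retains every scalar output (interface
displacement and stress histories, RI, damage radius, back-calculation
error) at a fraction of the cost, but it cannot represent the local
compressive contact at the cell-ECM interface or any non-radial loading
detail. That is the main modeling limitation on the continuum side.

## 3. Remodeling metrics and the synthetic fixture

The experimental metrics operate on gridded data: displacement length
(mean |u| over a 60 um cube around one cell), densification factor (DF,
the near-membrane 5 um radial intensity integral over a far-field 5 um
line integral, each averaged over four axis-aligned rays through the mask
centroid; far lines default to 25 um beyond the membrane), recoverability
index (100 x decell/overall displacement length), and radial decay profiles
of |u| normalized at the membrane. The membrane is located along each ray
as the 0.5 crossing of the interpolated cell mask. Profiles interpolate the
|u| field (interpolating components would cancel transverse parts), and
decay-exponent fits exclude the first voxel from the membrane, where
interpolation mixes in the mask interior.

`synth_fixture()` builds the fully synthetic ground-truth data set: a
radially contracting displacement field $u(r) = u_0 (a/r)^n$ split into an
elastic fraction `f` (the decell field) and a plastic remainder, an
intensity volume with a densified shell of known ratio within 5 um of the
membrane, and optional additive Gaussian noise (the intensity channel
receives the same relative noise). Voxel centers are offset half a voxel
from the cell center so the membrane never coincides with a sampling plane.
What the fixture does *not* emulate about real data: fibrous texture,
spatially correlated DVC errors, anisotropic cell shapes, and intensity
bleaching; passing the recovery tests therefore validates the metric
implementations, not the imaging pipeline.

`recover_fixture_params()` demonstrates estimator design under noise: the
decay exponent comes from a volumetric least-squares fit of the signed
inward radial projection $-(\mathbf u \cdot \hat r)$ (whose noise stays
Gaussian and unbiased at any signal level, unlike magnitudes, which are
chi-biased where the signal is weak), and the elastic fraction from a
cross-projection of the decell and plastic fields that cancels the
denominator noise bias. All three generating parameters are recovered
within 3% at a noise s.d. of 5% of $u_0$ across 20 seeds.

## 4. Problem sizes and reproducibility

The test suite runs the discrete engine at desk scale (10 um box, 3
replicate seeds per swept value; force sweep 1--1000 pN, density sweep
0.25x--2x at the 0.1x unbinding-rate condition, mechanosensitivity sweep
0.1x--3x), the continuum solver at its default resolution including a
~20-point damage-parameter sweep with one-hour creep, and the metrics
harness over 20 fixture seeds. One seed drives each run's generation and
kinetics; identical seeds give byte-identical outputs, which the suite
asserts. `scripts/acceptance.R` recomputes the headline quantities from
scratch with a caller-supplied seed.

## 5. Known limitations

* No thermal fluctuations (the network is athermal by design), no fiber
  rupture, branching, or intra-fiber fibril sliding; one crosslink species.
* The desk-scale coarse-grained stiffness compresses the dynamic range of
  concentration peaks relative to fully stiff fibers (see above).
* The continuum model is 1-D spherically symmetric; contact detail at the
  load surface is out of reach, and the apparent-stress artifact at the
  boundary shell is handled by reporting the 5 um probe value.
* Crosslink formation uses an enlarged capture reach as a stand-in for
  polymerization-time contact; absolute crosslink densities are therefore
  calibrated, not measured.
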