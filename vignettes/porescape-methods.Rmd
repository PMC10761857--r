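---
title: "Methods: pore discretization, flow, transport and the glucose/AI-2 model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore discretization, flow, transport and the glucose/AI-2 model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(porescape)
```

`porescape` analyses bacterial colonization of microfluidic porous media
whose pore space splits into advection-dominated transmitting pores (TPs)
and diffusion-dominated dead-end pores (DEPs). This vignette documents the
models and algorithms behind each module, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-scene generator
does and does not emulate.

## Pore-space discretization

The input is a binary mask (pore = 1, solid = 0) with a pixel size in
micrometres; flow runs from the left image edge (inlet) to the right
(outlet). The discretization chain is:

1. **Grains** — connected components of the solid phase. Solids are
   8-connected and pores 4-connected, the standard complementary pair that
   avoids topological paradoxes on a raster.
2. **Maximum inscribed disks** — for every pore pixel, the radius of the
   largest disk centred there that fits in the pore space, computed as an
   exact Euclidean distance transform to the solid phase (Felzenszwalb-
   Huttenlocher lower envelopes, exact to machine precision; the test
   suite checks it against an O(N^2) brute-force search). The local pore
   size is `lambda = 2r`, sampled at every skeleton point.
3. **Skeleton** — Zhang-Suen thinning to a 1-px-wide, connectivity-
   preserving medial representation, annotated with the inscribed radius.
4. **Segregation index** — at each skeleton point, the number of distinct
   grains with solid pixels within a tangency band of the inscribed disk
   boundary (band half-width 1.5 px). A disk confined by a *single* grain
   (index 1) can only sit inside a cavity recessed into that grain; disks
   in channels touch at least two grains. Index 1 therefore seeds DEP
   regions and index > 1 seeds TP regions.
5. **Label map** — every pore pixel takes the class of its nearest
   seeding skeleton point. Distance is *geodesic within the pore space*,
   not straight-line Euclidean: a Euclidean rule lets skeleton points on
   the far side of a thin solid wall claim pixels deep inside a cavity,
   which we observed on seeded scenes. Ties go to TP so that DEP
   entrances are conservative.
6. **Deeper-than-wide filter** — a candidate DEP region is kept only if
   its geodesic depth exceeds its width (twice the largest inscribed
   radius in the region). This enforces the defining property of a
   dead-end cavity. Without it, shallow pockets at channel junctions -
   where a large junction disk can graze only one grain on a raster -
   are spuriously labelled DEP.

Per-DEP geometry: entrance pixels are DEP pixels 4-adjacent to TP; the
depth `L` is the geodesic arc length from the entrance interface to the
farthest DEP *pixel*. The medial skeleton stops half a cavity width short
of the tip, so measuring to the farthest skeleton point would
systematically underestimate a constructed depth; the pixel-based measure
recovers carved cavity depths to a few pixels (tested).

Raster caveat: thinning is not exactly isotropic, so the DEP/TP boundary
near an entrance can shift by a few pixels under rotation of the input.
Classification away from entrances is exact (tested on 20 seeded scenes
with 100% agreement outside one cavity width of the mouth).

## Stokes flow

Creeping flow is solved on the mask with a staggered (MAC) finite
difference scheme: `u` on vertical faces, `v` on horizontal faces,
pressure at pore-cell centres, assembled into one sparse saddle-point
system and solved directly. No-slip on solid boundaries and the top and
bottom domain walls enters through ghost reflection of tangential
velocities; a unit pressure drop is imposed between inlet and outlet and
the linear solution is rescaled exactly, either to an imposed flow rate
`Q` (default 0.1 uL/min through a chip of thickness `h` = 0.05 mm) or to a
target mean pore velocity `u_m` (20 um/s in the reference experiments,
matching the mean fluid velocity in the gut). Scaled-down scenes use the
`u_m` target, since their cross-section differs from the real device. The
bulk shear rate is `u_m / h` (0.4 1/s at the defaults).

Verification: Poiseuille centreline-to-mean ratio 1.5 within 2% in a
straight channel, divergence residual below 1e-8 (direct solves reach
~1e-13), exact linearity in `Q`, and stagnation inside cavities (mean
speed beyond one cavity width of the entrance < 1% of the TP mean).

## Tracer transport and gradient persistence

Passive-solute transport uses the staggered face velocities in a
finite-volume scheme: explicit first-order upwind advection, sub-stepped
at a CFL number of 0.8 (monotone, no oscillations at sharp fronts),
operator-split with implicit backward-Euler diffusion (unconditionally
stable; the constant-coefficient operator is Cholesky-factorized once).
Solid boundaries are no-flux; in displacement mode the inlet edge holds a
fixed concentration both advectively and diffusively and the outlet is
advective outflow. Numerical diffusion of the upwind scheme,
`u dx / 2 ~ 3e-5 mm^2/s` at the default scales, is small against the
physical `D = 6e-4 mm^2/s`. A sealed 1D step initial condition matches
the closed-form erfc profile within 1% (tested).

**Gradient persistence.** For each DEP the entrance gradient is the mean
concentration over DEP pixels within one aperture (the cavity's width) of
the entrance minus the mean over TP pixels within the same distance of
it; persistence is the last time its magnitude exceeds 10% of the
resident/invading contrast. The window is sized to the cavity aperture
rather than a fixed pixel count: the mouth gradient separates the cavity
reservoir from the channel, its natural inner scale is the aperture, and
a resolution-bound sliver (a few micrometres on either side) straddles an
essentially continuous concentration field and never registers a
difference even while the cavity visibly retains tracer.

**Scaled-down scenes and time units.** The real device elutes one pore
volume (PV) in 24 minutes; its ~29 mm length cannot be simulated at pore
resolution on a desk. Displacement runs therefore use a domain of a few
pore-network cells at matched mean pore velocity (20 um/s), matched DEP
depth (0.2 mm) and the physical tracer diffusivity, measure persistence
in eluted pore volumes of that scene, and convert to minutes at the
experimental 24 min/PV equivalence. In these units the entrance gradient
at the most retentive DEP outlives one pore volume - far beyond the
diffusive time over the cavity depth, `T_d = L^2/D ~ 67 s` - which is the
transport mechanism that lets autoinducer gradients persist under flow.

## Biomass quantification

Bright-field stacks are corrected by subtracting the pre-injection frame
(frame 1); because cells attenuate a bright background the biomass signal
is background minus frame, clipped at zero (intensities are masses and
the read noise is symmetric), and solid pixels are zeroed. Fluorescence
channels use frame minus background.

Clusters are detected per region - each DEP independently, the TP class
as one region - with the regional-maxima rule: the frame is median
smoothed (3x3), 8-connected regional maxima are located within the
region, the threshold is the mean of the maxima intensities (an exposed
multiplier defaults to 1), and clusters are connected components of
pixels at or above the threshold in the *unsmoothed* frame, so that on
noise-free scenes with flat-topped colonies the integrated cluster masses
equal the deposited truth exactly (tested). Colony mass-per-area
densities use 64 logarithmic bins over the observed range and integrate
to one per time point.

The retention curve is `C_dep / C_tp` with `C_class` the class-summed
intensity divided by the class pixel count; the biomass series reports
`B_tp`, `B_dep`, `B_tot = B_tp + B_dep` and the DEP partition
`B_dep / B_tot`. Intensities are instrument-relative, so both statistics
are invariant under a global intensity rescaling (tested to machine
precision), and a uniform field gives ratio 1 and partition equal to the
DEP area fraction by construction.

## Reporter profiles and the activation front

Reporter activity is the corrected reporter intensity divided by the
corrected biomass intensity, valid only where biomass exceeds a floor.
Along each DEP skeleton, profiles are sampled every 10 px of arc length
from the entrance (s = 0 at the DEP-TP juncture, the skeleton point
adjacent to the label transition) to the tip, averaging activity within
the maximal inscribed disk clipped to the DEP's own pixels, so entrance
samples are not contaminated by TP signal. The activation front is the
smallest `s` where activity reaches 80% of the profile's own maximum
(per-profile maximum, configurable), linearly interpolated between
samples; a constant positive profile has its front at the entrance.

## The coupled glucose / AI-2 model

Along a DEP of depth `L` (default 0.2 mm) with biomass concentration
`c_B(x)` (g dry mass / L), glucose obeys

    dc_G/dt = D_G d2c_G/dx2 - U_1c c_B     (where c_G > 0)

with `c_G = c_0` at the juncture (x = 0; fresh medium in the TP),
no-flux at the tip, `D_G = 6e-4 mm^2/s`, uptake rate `U_1c = 10 mMol/s/g`
and `c_0 = 5 mM`. AI-2 obeys

    dc_A/dt = D_A d2c_A/dx2 + k_A+ c_B - k_A- f c_B

with Dirichlet 0 at the juncture (advective washout in the TP; the
strongest form of the washout boundary), no-flux at the tip, and the
catabolite-repression switch `f = 1` where `c_G < theta_G`, else 0.
`D_A` comes from the Stokes-Einstein relation with hydrodynamic radius
proportional to the cube root of molecular mass,
`D_A = D_G (M_G / M_A)^(1/3)`, using the DPD precursor mass 132.11 g/mol
for AI-2 by default (the sensed species is not settled; the mass is a
parameter). The reporter proxy is `lsrR = (1 - c_A)(1 - c_G)` on
normalized fields: `c_G` by `c_0`, `c_A` by its instantaneous maximum
(a fixed production scale is available as an alternative).

**Unprinted parameters.** `k_A+`, `k_A-` and `theta_G` are not reported
anywhere; the package's defaults are `k_A+ = 1e-3`, `k_A- = 0.1`
(mM L g^-1 s^-1) and `theta_G = 0.1 c_0`. Two properties motivated them.
First, induced uptake must be much faster than production
(`k_A- >> k_A+`): the penetration depth of AI-2 into the uptake zone is
then short, the AI-2 depletion front co-locates with the glucose front,
and the simulated activation front both matches `sqrt(D tau_U)` (within
~5% at the defaults) and scales as `sqrt(tau_U)` across a 100x biomass
range (log-log slope 0.50). With comparable rates the AI-2 dip never
localizes (its penetration length exceeds the DEP depth at realistic
biomass) and neither property holds. Second, `theta_G` of a few tenths
of a millimolar reflects the glucose level at which catabolite
repression is effectively relieved; it shifts the front by the factor
`1 - sqrt(theta_G / c_0)` and 0.5 mM lands the front on the scaling
estimate.

**Numerics.** Backward Euler in time (dt default 0.1 s; scaling studies
reduce dt to `tau_U / 100` when consumption is faster), second-order
central differences on a uniform grid with a node on the juncture (dx
default L/200). The zeroth-order reactions are handled as *projected*
steps: the non-negativity clamp is applied after the implicit diffusion
solve, so the steady state solves `D c'' = U` exactly on the active set.
Clamping the reaction before diffusing - the naive operator splitting -
pins the depletion front at `sqrt(D dt)` whenever `dt U c_B` exceeds
`c_0`, which destroys the `sqrt(tau_U)` scaling; this failure mode is why
the projection is applied after the solve. AI-2 uptake is additionally
limited to the signal actually present (a physical regularization of the
zeroth-order sink, which would otherwise oscillate cell-by-cell around
zero). The sealed-boundary diffusion step conserves mass to machine
precision, glucose respects the maximum principle, and halving dx and dt
changes the solution by < 1% (all tested).

The scaling prediction `zeta = sqrt(D tau_U)`, `tau_U = c_0 / (U_1c c_B)`
uses the glucose diffusivity for `D`; the tracer dye coefficient happens
to share the same numerical value 6e-4 mm^2/s.

## The synthetic-scene generator

The generator exists so that every downstream stage can be validated
against known truth. It emulates: grain-separated channel networks with
the reference medium's mean pore size (0.04 mm), porosity target and
pixel scale (0.65 um/px full scale; tests and desk-scale transport runs
coarsen to 2.6 um/px); stadium-shaped cavities of depth ~0.2 mm and
depth/width ratio > 1 carved into grains, occupying 8 +- 2% of the pore
volume, with ground-truth labels recorded at carving time; three-phase
biomass dynamics imposed through a DEP/TP concentration-ratio curve that
the rendered stacks reproduce exactly before noise; reporter activation
fronts at prescribed depths; and Gaussian read noise (level configurable;
the reference imaging noise is unreported).

Design choices: the geometry is a jittered channel lattice with solid
frame bars at the walls rather than random blob packing - percolation of
the TP network is then guaranteed by construction, which blob packing
cannot promise - and one to a few cavities are carved per scene with the
last cavity sized to land the DEP fraction on target. The hyperuniform,
spinodal-like character of the real medium is *not* reproduced; only the
quantities the analysis consumes (porosity, mean pore size, DEP fraction,
DEP depth) are matched. Biomass is rendered as flat-topped colonies (or a
uniform fill) under additive attenuation with no photobleaching or PSF;
colony placement and read noise are seeded separately so one placement
can be replicated across noise draws. Passing the closed-loop tests
therefore demonstrates correctness of the measurement chain, not realism
of bacterial dynamics: real data add drift, uneven illumination, optical
blur and biology the generator does not model.

## Problem sizes

The bundled tests and the acceptance script run on 300x400 to 440x640 px
scenes at 2.6 um/px, 1D model grids of 101-201 nodes, and displacement
horizons of a few pore volumes; these sizes were chosen so the whole
validation chain runs on a laptop in minutes while every oracle
(brute-force distance transforms, closed-form Poiseuille and diffusion
profiles, steady-state parabolas, construction truth) stays exact.

## Known limitations

* 2D plane flow: the chip thickness enters only through flux conversion
  and the shear estimate, not as a Brinkman drag.
* First-order upwind advection smears fronts over a few cells; acceptable
  at the Peclet numbers studied, but not for front-steepness questions.
* The classifier's DEP/TP boundary near an entrance is raster-dependent
  by a few pixels; depth and entrance-window statistics inherit that
  uncertainty.
* The QS model is 1D per DEP with static (piecewise-constant in time)
  biomass and no oxygen field or metabolic switching.
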