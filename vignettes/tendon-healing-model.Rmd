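---
title: "The tendonheal healing model: mechanics, transport and tissue differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tendonheal healing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tendonheal` simulates the first twenty weeks of Achilles tendon healing as
a daily feedback loop between whole-construct mechanics and local tissue
biology. A ruptured tendon is represented as two intact stumps bridged by a
soft repair callus; each simulated day the construct is loaded in tension,
the resulting biophysical stimuli select which tissue (tendon-, fat-,
cartilage- or bone-like) every callus element produces, and the accumulating
tissue feeds back into the mechanics through a mixture material rule. The
package exists to explore, on an idealized geometry, why healing tendons so
often develop cartilage- and bone-like inclusions (heterotopic
ossification), and how cell infiltration, angiogenesis and oxygen transport
gate that process.

## The daily iteration

`run_healing()` executes, for every day of the 140-day horizon:

1. **Material assembly.** Every element's stiffness parameters are the
   intact-tendon values scaled by the mixture rule
   $M = (0.5\,\rho^F + \rho^T + 2.62\,\rho^C + 40.40\,\rho^B)\,M^{\text{intact}}$,
   times a fibril-alignment factor (below).
2. **Mechanics.** A 2 N tensile ramp (1.1 N/s) is solved quasi-statically;
   element stimuli are extracted at centroids: principal strains
   $\varepsilon_1 \ge \varepsilon_2 \ge \varepsilon_3$ (reported in %),
   octahedral shear strain
   $\varepsilon_{os} = \tfrac13\sqrt{(\varepsilon_1-\varepsilon_3)^2 +
   (\varepsilon_1-\varepsilon_2)^2 + (\varepsilon_2-\varepsilon_3)^2}$,
   hydrostatic stress $\operatorname{tr}(\sigma)/3$, pore pressure and
   Darcy fluid-flow speed.
3. **Transport.** Nodal cell density always diffuses in from the external
   callus surface; for the oxygen-coupled rule set, angiogenesis advances
   by diffusion *through elements whose shear strain is below the A-OSS
   gate*, nodes above 90% angiogenesis become matured vessels, and oxygen
   diffuses from the surface and every matured vessel while cells consume
   it: $\dot\rho^{oxy} = O\nabla^2\rho^{oxy} - C\,\rho^{cells}\rho^{oxy}$.
4. **Differentiation.** A declarative rule table maps each element's
   stimuli to the tissue produced (see below), optionally filtered by the
   endochondral gate.
5. **Production and degradation.** The chosen tissue grows by
   $\Delta = \text{rate} \times \rho^{cells} \times \Delta t$; the other
   tissues jointly lose $\min(\Delta, \text{their total})$, split in
   proportion to their current densities. Days 1-5 instead apply an
   inflammation-driven baseline: tendon at 50% of the default rate,
   independent of the stimuli.
6. **Reorientation.** Each callus element's 13 collagen fibrils rotate
   toward the current maximum-principal-strain direction on a fixed
   schedule that completes alignment in four weeks.

Defaults: default production rate 0.02/day (tendon, cartilage, fat), bone
0.012/day; one-day iterations; everything configurable through
`simulation_config()`.

## Rule sets

Five differentiation schemes ship as data-driven rule tables
(`rule_set()`), all using tendon as the fibrous fallback tissue:

| scheme  | bone | cartilage | tendon | fat |
|---------|------|-----------|--------|-----|
| PE (and PE-ENDO) | $\varepsilon_1 < 2\%$ | $2\text{--}4\%$ | $> 4\%$ | — |
| PE-HS (Carter-type) | $\varepsilon_1 \le 5\%$, compression $< 0.2$ MPa | $\varepsilon_1 \le 5\%$, compression $\ge 0.2$ MPa | otherwise | — |
| PE-PP (Claes–Heigele-type) | $\varepsilon_1 \le 5\%$, $|PP| < 0.15$ MPa | $\varepsilon_1 \le 15\%$, $PP \ge 0.15$ MPa | otherwise | — |
| OSS-FF (Prendergast-type) | $stim < 1$ | $1 \le stim \le 3$ | $stim > 3$ | — |
| PE-OXY | vascularized, $\varepsilon_1 < 2\%$ | hypoxic ($\rho^{oxy} < 3\%$) | vascularized, $2\text{--}25\%$ | vascularized, $> 25\%$ |

with $stim = \varepsilon_{os}/3.75 + FF/3$. Boundary ties are closed on
the cartilage side. In PE-OXY, hypoxia takes precedence over the vascular
rules (hypoxic chondrogenesis), and normoxic but avascular sites produce
nothing. The original source table is typographically garbled for some
cells; the PE-HS / PE-PP / OSS-FF fibrous-tissue cells are reconstructed
from the cited classical models, with the fibrous outcome playing the
tendon role. PE-ENDO additionally requires, before any bone is produced,
$\varepsilon_1 < 2\%$ **and** either cartilage above
$\rho^C_{endo} \in \{20\%, 25\%\}$ or pre-existing bone — ossification
through a cartilage template or apposition only.

Tendon production under PE, PE-ENDO and PE-OXY follows a strain-magnitude
law (`tendon_rate_law()`): zero at zero strain, rising linearly to the
default rate at 15% strain and falling back to zero at 30% (production
declines with overstrain). The exact functional form of the original law
is not published; this continuous piecewise-linear shape with those
breakpoints is the package's configurable default. The classical schemes
(PE-HS, PE-PP, OSS-FF) use the constant default rate for tendon.

## Geometry and mechanics engine

The published rat geometry is not available, so `build_mesh()` constructs
a parameterized idealization: two cylindrical stumps (radius 1 mm, length
3 mm each) joined by a cosine-bulge callus (maximum radius 2.5 mm, length
5 mm), revolved into a structured hexahedral mesh (a square grid mapped
elliptically onto the disc, default 8 divisions across and 14 axial
layers, 896 elements). Mesh volume is within 1.3% of the closed-form
profile volume at the default resolution and converges quadratically.

The original fiber-reinforced hyper-visco-poro-elastic constitutive model
is defined in prior work without published parameters and is out of scope;
the engine here is deliberately simple and pluggable:

* small-strain isotropic linear elasticity per element (trilinear
  hexahedra, 2×2×2 Gauss), with one effective axial modulus — the mixture
  rule scales all stiffness parameters identically, so a single scalar
  captures the feedback loop exactly;
* a fibril-alignment factor $\alpha + (1-\alpha)\,\overline{\cos^2\theta}$
  (default $\alpha = 0.5$) multiplying the modulus, where $\theta$ is the
  angle between each fibril and the load axis: randomly oriented fibrils
  yield 2/3 of the aligned stiffness, so reorientation stiffens the callus
  by up to 1.5× over four weeks;
* a staggered pore-fluid stage: the undrained pore pressure
  $-B K \varepsilon_v$ is relaxed by one implicit Darcy step over the ramp
  duration (≈1.8 s) with the external surface drained, yielding pore
  pressure and fluid-flow stimuli.

**Intact modulus.** The intact-tendon effective axial modulus defaults to
10 MPa, chosen by regime placement: the initial 10%-density callus core
then carries ≈15% axial strain at 2 N — the peak of the tendon production
law, i.e. the start of the healing trajectory in the tendon-production
regime — and its early octahedral shear strain (≈9%) sits above the 6%
angiogenesis gate, so vessel ingrowth follows the stiffening front from
the periphery inward rather than preceding it. The intact stump then
strains ≈6% at 2 N. Absolute stiffness magnitudes are not reproduced (nor
intended to be): the construct stiffness readout is meaningful as a
monotone, qualitative trajectory.

## Transport model and its units

All three fields (cells, angiogenesis, oxygen) are nodal fractions in
[0, 1], advanced by backward-Euler steps of the finite element diffusion
operator with lumped mass, Dirichlet value 1 on the external callus
surface, and zero flux across the stump cross-sections (infiltration and
vascularization are extrinsic, periphery-to-core). The consistent
trilinear-hex Laplacian has positive off-diagonal entries on the mapped
disc elements, which breaks the discrete maximum principle exactly where
it matters (the steep oxygen profile); the package therefore applies the
standard monotone repair — positive off-diagonal conductances are clipped
per element and row sums restored — keeping the operator symmetric and
exactly mass-conservative while guaranteeing oscillation-free fields.

The literature gives only *relative* diffusivities (A, O = 0.25–0.5–1.0);
absolute units are anchored as follows:

* **Cells**: `calibrate_cell_infiltration()` bisects the diffusivity so
  the volume-weighted mean callus cell density reaches 95% at day 14
  (≈0.105 mm²/day on the default mesh).
* **Angiogenesis**: A × the calibrated cell diffusivity — vessel fronts
  advance with the granulation tissue they grow through.
* **Oxygen**: O × 0.0225 mm²/day, so that at the default O = 0.5 and
  C = 0.5/day the Krogh-type penetration length $\sqrt{O_{abs}/C}$ is
  0.15 mm — the physiologic oxygen diffusion distance from a capillary.
  Oxygenation is thereby vessel-limited: tissue more than a few hundred
  micrometres from the surface or a matured vessel is hypoxic, which is
  the mechanism the oxygen-coupled scheme encodes.

The oxygen sink is integrated exactly (operator splitting with an
$e^{-C\rho^{cells}\Delta t}$ factor), so an isolated fully cellularized
node decays as $e^{-Ct}$ to machine precision. The angiogenesis field is
explicitly monotone per node (vessels do not regress), and matured-vessel
flags are never revoked.

## What a default run looks like

```{r, eval = FALSE}
library(tendonheal)
cfg <- simulation_config(rule_set = "PE", horizon = 140, seed = 42)
h <- run_healing(cfg)
summary_report(h)
temporal_curves(h)    # tidy day x quantity table for plotting
```

Under PE on the default mesh, tendon is produced first (the callus starts
above the 4% threshold), mean cartilage exceeds 0.1% around day 8 as the
stiffening callus passes through the 2–4% window, and bone follows within
a week; stiffness rises monotonically. PE-ENDO retains cartilage through
week 20 and produces roughly half the bone of PE (less at the 25%
threshold than at 20%). PE-OXY concentrates cartilage in the hypoxic
callus core — the cartilage-weighted mean radius is about half the
volume-weighted mean callus radius — and ossifies late, as vessels must
mature inward before bone can form. Sweeping the transport parameters one
factor at a time (`parameter_sweep()`), every hypoxia-increasing
perturbation (A-OSS = 3%, O = 0.25, A = 0.25, C = 0.75) increases
time-integrated cartilage relative to baseline. These statements are the
package's acceptance properties and are recomputed by the test suite; the
exact numbers for a given seed are printed by the README example.

## Numerical choices and degenerate inputs

* Iteration = 1 day; stimuli from the same morning's solve gate that
  day's angiogenesis (the loop order is fixed as listed above; the source
  framework does not specify transport-vs-mechanics order within a day).
* The mixture-times-alignment stiffness factor is floored at 0.01 so
  early acellular elements cannot make the system singular; the flag is
  returned by `assemble_material()`.
* Density bookkeeping clamps every tissue to [0, 1] and the four-tissue
  total to 1; degradation is apportioned proportionally to current
  composition (the split is not specified in the source; proportionality
  preserves relative composition).
* Fibril rotation uses the day-0 reference angle divided by 28 days as a
  constant daily step, never overshooting; directions are sign-symmetric.
* Zero-day horizons return the initial record; zero production rates
  freeze densities exactly (stiffness additionally requires reorientation
  disabled to stay constant, since alignment itself stiffens).
* Single RNG stream, consumed only by the callus fibril initialization;
  histories are bit-identical for identical config and seed.

## Problem sizes

The shipped defaults (896 hexahedra, 1215 nodes, 140 daily iterations,
~2700 degrees of freedom in the mechanics solve) run a full 20-week
simulation in well under a minute on one core; the test suite's eight
study runs complete in a few minutes. The mesh resolution was chosen as
the coarsest that resolves the oxygen consumption boundary layer (the
hypoxic core needs at least ~4 element rings across the callus radius);
`geometry_params()` exposes finer resolutions for convergence studies.

## Limitations

* The mechanics engine is linear and small-strain: no viscoelasticity,
  no finite-strain kinematics, and stiffness magnitudes are qualitative.
  The engine sits behind a narrow interface (`solve_ramp()`) so a
  higher-fidelity model can be substituted.
* The idealized geometry produces a high-strain band where the bulge
  meets the stumps; elements there can sit above the 30% production
  cut-off until reorientation stiffens them. Real calli are irregular and
  the published rat geometry is unavailable.
* Continuum densities cannot represent the discrete, unconnected
  ossification islands seen histologically; an element's "bone density"
  is a volume fraction, fully load-bearing through the mixture rule.
* The synthetic study conditions emulate free-cage-activity loading as a
  single daily 2 N ramp; passing tests demonstrate internal consistency
  and the qualitative mechanisms, not quantitative agreement with any
  animal's healing trajectory.
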