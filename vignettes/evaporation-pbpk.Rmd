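---
title: "Modelling evaporation-coupled dermal absorption with pbpke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evaporation-coupled dermal absorption with pbpke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpke)
```

## The physical picture

A finite dose of a liquid vehicle — typically a few mg/cm² of an aqueous or
ethanolic solution of the permeant — sits on excised skin in an open Franz
diffusion cell. Two processes compete for the permeant: diffusion into and
through the skin towards the stirred receptor fluid, and evaporation through
the still air column of the donor chamber. Because the film is thin, both
processes visibly deplete it, the vehicle volume shrinks as solvent
evaporates, and the permeant concentration in the residual film changes over
time. `pbpke` simulates this coupled system and accounts for every
microgram: at any time the applied dose is distributed over six compartments
(atmosphere, vehicle, stratum corneum, viable epidermis, dermis, receptor
fluid) that sum to 100%.

## Evaporation

The gas immediately above the film is assumed in equilibrium with the liquid
(Raoult's law with an ideal liquid, activity coefficient 1), and the ambient
above the donor chamber is a perfect sink, so the evaporative flux of
component $i$ is Fickian diffusion across the chamber height $h$:

$$ J_{evap,i} = D_{evap,i}\,\frac{M_{s,i}-M_{a,i}}{h},\qquad
   M_{s,i} = \frac{P_i\,x_{l,i}\,a_{l,i}}{RT}. $$

We store $J_{evap}$ as a positive outward magnitude; the vehicle balance
equations subtract it. Ambient concentrations $M_a$ are zero except for
water, where humidity sets $M_a = \mathrm{RH}\cdot P_{sat}/(RT)$ with
$P_{sat}$ from the Antoine equation (coefficients 8.07131 / 1730.63 /
233.426, mmHg and °C, the standard 1–100 °C fit). Net condensation is
clamped to zero — the model describes loss — except optionally for water
(`allow_water_condensation`).

The gas diffusivity comes from the Stokes–Einstein equation with the
viscosity of air ($\eta = 1.89\times10^{-5}$ Pa·s near skin-surface
temperature, overridable) and a molecular radius estimated from the liquid
molar volume, $r = (3 (MW/1000)/(4\pi\rho N_A))^{1/3}$, which needs no input
beyond what a chemical record already carries. A caveat stated openly:
Stokes–Einstein is a continuum hydrodynamic model and for gas-phase
diffusion it sits one to two orders of magnitude below tabulated binary
gas diffusivities (kinetic-theory values are $\sim 10^{-5}$ m²/s). We keep
the equation in its printed form because it is the package's defined
default, and expose a first-class per-chemical override (`d_evap_m2_s`) so
tabulated or Chapman–Enskog diffusivities can be supplied; absolute
evaporation rates scale linearly with this choice, and predicted evaporated
fractions under the default are correspondingly conservative.

A **legacy mode** reproduces the empirical wind-speed mass-transfer
coefficient used by earlier unoccluded dermal models,
$K_{evap} = 1.756\times10^{-5} P\, MW^{2/3} u^{0.78}/(RT)$ (SI with MW in
Da), applied to the same concentration gradient. An **occluded mode** forces
all evaporative fluxes to zero; this is also, by design, the plain
no-evaporation PBPK pathway, so comparisons between the two models are a
mode switch on one code path and agree bit-for-bit with a zero-volatility
mechanistic run.

## Vehicle dynamics

The vehicle is a well-mixed ideal solution: volumes are additive
($V=\sum m_i/\rho_i$), so evaporation shrinks it as
$dV/dt = -\sum J_{evap,i}A/\rho_i$; volume loss into the skin is neglected
(dilute permeant). The per-component balance
$d(VC_i)/dt = -J_{evap,i}A - J_{skin,i}A$ expands by the product rule into
the concentration form exported as `vehicle_rhs()`. The integrator itself
advances component **masses**, which is the same mathematics but exactly
conservative and free of the $V\to 0$ singularity; concentrations and volume
are derived algebraically. A useful identity falls out: a pure
single-component film keeps $C=\rho$ exactly while $V$ shrinks linearly —
one of the package's acceptance checks.

**Dry-down.** When a component's mass reaches a floor of $10^{-15}$ kg its
evaporation stops and a `dry_down` event is logged. When the total volume
falls below $10^{-6}$ of its initial value the film is frozen as a residue:
evaporation ceases entirely but skin contact continues, with the remaining
masses held in that minimal film volume (leave-on exposures continue to
absorb long after an ethanol vehicle has flashed off). The residue regime is
our own documented choice and is flagged in the run manifest whenever it
triggers. If a configured solubility is exceeded during dry-down a
supersaturation warning event is emitted; no precipitation kinetics are
applied.

## Skin transport

The skin is a layered diffusion domain: stratum corneum (SC), viable
epidermis and dermis, with depth measured downward from the vehicle–SC
interface. Transport parameters come from a QSPR constants table —
power laws in $K_{ow}$ for partition, log-linear/power decay in MW for
diffusion, the established functional shapes for skin QSPRs. The numeric
coefficients are the package's own version-stamped parameterisation
(`pbpke-qspr-1`), tuned to produce permeability coefficients and SC lag
times in the physiological range for moderately lipophilic permeants; any
laboratory with fitted coefficients should override them, which is why every
parameter accepts a per-chemical override that is returned verbatim. The
viable epidermis and dermis deliberately share one parameter set (the SC is
the dominant barrier); this is adequate for total dermal delivery but limits
the fidelity of per-layer amounts.

Discretization is finite-volume method-of-lines. Interface conductances act
on the activity $\psi = C/K$:
$U_{ij} = [\delta_i/(D_iK_i)+\delta_j/(D_jK_j)]^{-1}$ with $\delta$ the
centroid-to-face distances, which reduces to the harmonic-mean two-point
conductance in a homogeneous medium and makes inter-cell fluxes exactly
antisymmetric (discrete conservation to machine precision). The default 1D
mode uses homogenized effective SC parameters
($K_{sc}=\phi K_{lip}+(1-\phi)K_{cc}$ in parallel,
$(KD)_{sc}$ in series, lipid fraction $\phi = 0.125$). The 2D mode resolves
staggered corneocyte bricks in lipid mortar on a laterally periodic unit
cell (exact four-column layout, channels offset by half a brick between
layers); with identical phase parameters it degenerates to the 1D lipid
slab, which is tested. The receptor fluid is a finite well-mixed volume
(partition coefficient 1, aqueous) with a perfect-sink flag, matching a
stirred Franz-cell receptor.

Verification anchors the discretization to Crank's closed-form membrane
solution: steady-state flux $KD\,\Delta C/L$ (exact at any resolution for a
homogeneous slab, by the series-resistance structure) and lag time $L^2/6D$
(within 1% at 60 cells).

## Integration and numerics

The coupled state — vehicle component masses, per-cell skin concentrations,
receptor mass, cumulative evaporated masses — is integrated with
`deSolve::lsoda` (adaptive, switches to BDF when stiff), `rtol = 1e-6`,
`atol = 1e-12` (kg scale), on a 5-minute reporting grid by default.
Tightening `rtol` to $10^{-9}$ moves 24 h compartment percentages by less
than 0.01 points, and the six-compartment sum stays within 0.1% of 100% (at
`rtol = 1e-8`, within $10^{-4}$%). The clamp at the dry-down floors
introduces mild discontinuities that lsoda handles without event machinery;
events are detected on the dense output afterwards.

## Default scenario

The shipped template (`hewitt_ivpt_default`) represents a typical
finite-dose cosmetic-safety IVPT: 32 °C skin surface, RH 50%, unoccluded
24 h leave-on, 1 cm² area, 10 mg/cm² vehicle load at 1% w/w permeant, 1 cm
donor height, 5 mL receptor; skin of 20 µm SC / 80 µm viable epidermis /
900 µm dermis at 12/6/10 cells. These are documented assumptions of the
package, chosen once as field-typical values: the exact diffusion-cell
dimensions and per-chemical doses of any specific published study should be
supplied through the config (`load_scenario()`) or the supplementary-inputs
CSV template in `inst/extdata/`. Panels are batch-run with `run_panel()`,
which doses ethanol-annotated chemicals in ethanol and the rest in
water/PBS.

The 23-chemical reference panel spans MW 92–240 g/mol, log $K_{ow}$ −0.1 to
4.2 and vapour pressure 0.0023–55.2 Pa — the applicability domain of the
evaporation model. Liquid densities in the panel are auxiliary handbook
values (the panel's primary data are MW, log $K_{ow}$, vapour pressure);
they enter only the molecular-radius estimate and the volume balance.

## Evaluation harness

`volatility_screen()` partitions observed mass-balance records at strict
recovery < 90%. `r_squared()` computes both the squared Pearson correlation
and the identity-line form $1-SS_{res}/SS_{tot}$: the two are not
interchangeable (a biased but perfectly correlated prediction scores 1.0 on
the first and below 1.0 on the second), published R² values rarely say which
was used, and so `compare_models()` reports both, labelled, per compartment
and per model, with n. Observed "mass loss" is `100 − recovery`; the
predicted counterpart is the atmosphere compartment, which is undefined for
the no-evaporation model (it predicts zero loss for every chemical — zero
variance).

## What the defaults do and do not show

Simulations under the shipped defaults exercise every code path the package
claims — multi-component evaporation, solvent dry-down and residue films,
coupled uptake, conservation — but they are not a reproduction of any
specific laboratory study: that requires the study's own doses, cell
geometry, measured recoveries, and ideally gas diffusivities and fitted QSPR
coefficients, all of which enter through the override paths. Passing tests
demonstrate internal correctness against closed-form oracles and
conservation laws, not agreement with any particular experimental dataset.

## Known limitations

- Ideal-solution thermodynamics throughout ($a_l = 1$); non-ideal vehicles
  evaporate and deliver less than predicted.
- No skin metabolism, keratin-binding kinetics, appendageal transport, or
  precipitation physics (supersaturation only warns).
- Vapour pressure is taken at the scenario temperature; no
  temperature-dependence model is included.
- The ambient is a perfect sink at height $h$; vapour build-up inside the
  donor chamber over time is not modelled.
- Solvents evaporate but do not permeate; only configured permeants carry
  skin flux.

```{r example, eval = FALSE}
res <- run_scenario(ivpt_scenario(table1_chemicals()[1, ]))
mass_balance(res)
autoplot(res)
```
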