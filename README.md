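# pbpke

Mechanistic simulation of **simultaneous evaporation and dermal absorption**
of volatile chemicals under finite-dose, unoccluded in-vitro permeation test
(IVPT / Franz diffusion cell) conditions.

## The problem

Finite-dose IVPT studies apply a thin film of vehicle (a few mg/cm²) to
excised skin and leave the donor chamber open. For volatile permeants a large
part of the dose can leave through the air instead of the skin, so any model
that ignores evaporation systematically over-predicts dermal delivery. Wind
speed — the driver in classical empirical evaporation models — is poorly
defined inside a tall donor chamber. `pbpke` instead treats evaporation as
passive Fickian diffusion through the donor-chamber headspace, driven by the
permeant's vapour pressure, and couples it to a layered-skin PBPK
(physiologically based pharmacokinetic) diffusion model. The package is aimed
at researchers in dermal safety and delivery who need fully predictive (no
fitting to the data being predicted) compartmental mass balances.

## The model

For each component of the liquid vehicle film, the evaporative flux across
the donor headspace of height *h* is

```
J_evap = D_evap (M_s − M_a) / h          (outward magnitude)
M_s    = P x_l a_l / (R T)               (Raoult + ideal gas, a_l = 1)
D_evap = k_B T / (6 π η r)               (Stokes–Einstein; overridable)
```

with `P` the pure-component vapour pressure, `x_l` its liquid mole fraction,
and `M_a` the ambient gas concentration (0 except water, which follows
relative humidity). A legacy wind-speed mode replaces the transport factor by
the empirical liquid-spill mass-transfer coefficient
`K_evap = 1.756e-5 P MW^(2/3) u^0.78 / (R T)`, and an occluded mode forces
zero flux — the occluded pathway *is* the plain PBPK model, so "PBPK vs
PBPK-E" is a mode switch, not separate code.

The vehicle obeys the ideal-solution mass balance

```
dV/dt  = − Σ J_evap,i A / ρ_i
V dC/dt = −J_evap A + C Σ (J_evap A / ρ) − J_skin A
```

(the integrator advances the equivalent, exactly conservative per-component
mass form). `J_skin` is the flux into a finite-volume, method-of-lines
discretization of stratum corneum / viable epidermis / dermis, with
interface conductances acting on the activity `ψ = C/K`, a well-mixed (or
perfect-sink) receptor fluid below, and diffusion/partition coefficients from
an overridable QSPR table in (MW, log K_ow). The stratum corneum is
homogenized in the default 1D mode or resolved as a staggered
brick-and-mortar microstructure in 2D mode. Everything is integrated with a
stiff adaptive solver (`deSolve::lsoda`), and the six-compartment balance
(atmosphere, vehicle, SC, viable epidermis, dermis, receptor fluid) closes to
100% of the applied dose by construction.

A 23-chemical volatile reference panel (`table1_chemicals()`) and an
R²-based evaluation harness (`r_squared()`, `compare_models()`,
`volatility_screen()`) round out the toolchain.

## Worked example

```r
library(pbpke)

panel    <- table1_chemicals()                    # 23 volatile permeants
scenario <- ivpt_scenario(panel[panel$name == "4-Tolunitrile", ])
result   <- run_scenario(scenario)                # 24 h unoccluded leave-on
mass_balance(result, t = 86400)
#> # A tibble: 7 × 2
#>   compartment     percent_dose
#>   <chr>                  <dbl>
#> 1 atmosphere            0.0503
#> 2 vehicle              43.3
#> 3 sc                   54.4
#> 4 ve                    0.0337
#> 5 dermis                0.211
#> 6 rf                    1.95
#> 7 dermal_delivery       2.19
```

The rows are percent of the applied 4-tolunitrile dose after 24 h in the
default aqueous scenario (1 cm², 10 mg/cm² vehicle at 1% w/w, 32 °C, RH 50%,
1 cm donor height): 0.05% has evaporated (with the Stokes–Einstein gas
diffusivity; supply `d_evap_m2_s` to use tabulated diffusivities), 43% is
still in the vehicle film, 54% is held in the stratum corneum, and 2.2% has
reached the living tissue + receptor fluid ("dermal delivery"). The six
compartment rows sum to 100%.

Results pipe naturally: `tidy(result)` gives the long time course,
`glance(result)` a one-row summary, `autoplot(result)` the compartment
kinetics, and `write_results(result, "out/")` tidy CSVs plus a JSON
manifest. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pbpke.R run   --config inst/extdata/example_scenario.yaml --out results/
Rscript inst/cli/pbpke.R batch --panel table1 --mode pbpk-e --out results/
```

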