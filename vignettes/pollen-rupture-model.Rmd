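---
title: "Modelling grass-pollen rupture and sub-pollen particle transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grass-pollen rupture and sub-pollen particle transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sppsim)
```

## The problem

Epidemic thunderstorm asthma follows some — but only some — thunderstorms
that coincide with the grass-pollen season. Whole ryegrass pollen
(~35 µm) is too large to reach the small airways; the suspected agents are
sub-pollen particles (SPPs), sub-micron allergen-bearing fragments released
when a grain ruptures. The most-cited trigger is osmotic shock at high
relative humidity, but competing hypotheses exist: mechanical friction by
wind, electrical charging in very dry air, and lightning. `sppsim` is a
desk-scale simulator for confronting these rupture parameterisations with
the meteorology of a dry gust-front storm of the kind that caused the 2016
Melbourne event: hot (~34 °C), extremely dry (~18 % surface RH) pre-frontal
air, a sharp wind spike at frontal passage, humidity recovering to 80 % only
about five hours later, scant rain, and a track of lightning strikes passing
west and south of the city.

Every simulation carries three tracers: whole-pollen mass (µg m⁻³), SPP mass
(µg m⁻³) and pollen-shell number (m⁻³) — shells being the broken exines that
a volumetric trap can count, and hence the only observable proxy for
rupture.

## Pollen physics

Whole grains are treated as spheres of diameter 35 µm and density
1000 kg m⁻³, giving a per-grain mass m_pol = 22.4 × 10⁻⁹ g, so
1 grain m⁻³ ≡ 0.0224 µg m⁻³. SPPs are 600 nm spheres of the same density
(m_SPP = 1.13 × 10⁻¹³ g); each ruptured grain releases n_spg = 700 SPPs
and one empty shell. `pollen_params()` checks the stated masses against
sphere geometry at construction (1 % tolerance). The fraction of available
grains that ruptures per event is F_rupt = 0.7, taken from laboratory
rupture of ryegrass pollen in water.

Two bookkeeping conventions are provided for the mass removed from the
whole-pollen tracer when grains rupture. The default (`"spp_mass"`) removes
only the SPP mass produced — about 0.35 % of the grain mass, the literal
emission-accounting reading, under which the shell's mass stays in the
whole-pollen tracer. The alternative (`"full_grain"`) removes the whole
grain mass. The difference matters for long humid episodes, where the
default keeps the ruptureable inventory nearly intact; both are tested.

## Emission activity functions

Surface pollen emission is a potential-emission field modulated by three
activity factors built from a logistic curve
f_l(y) = 1 / (1 + exp(α (y − c))):

* **Humidity** f_RH = f_baseline + (1 − f_baseline) f_l(RH), calibrated so
  f_l = 0.95 at 50 %RH and 0.05 at 80 %RH. Closed-form log-odds inversion
  gives α_RH = 2 ln 19 / 30 ≈ 0.196 per %RH and c_RH = 65 %RH. Note that
  with the curve written in this form the calibration forces a *positive*
  rate parameter; `solve_logistic_params()` stores whatever sign the
  calibration yields, and the decreasing behaviour (moist air suppresses
  emission) is what the tests pin down.
* **Precipitation** f_PR = f_baseline + (1 − f_baseline) f_l(PR)/f_l(0),
  calibrated to 0.95 at no rain and 0.05 at 0.5 mm h⁻¹; the f_l(0)
  normalisation makes f_PR exactly 1 in dry weather. The same normalised
  f_PR is used inside the mechanical-rupture retained fraction below.
* **Wind** f_WS = f_baseline + (1 − f_baseline)(1 − exp(−WS/U_sat)) with a
  saturation speed U_sat = 5 m s⁻¹: 0.33 at calm, 0.75 at 5 m s⁻¹,
  asymptoting to 1 above ~15 m s⁻¹.

f_baseline = 0.33 is the fraction of pollen emitted at very low humidity.
The emission composition used here, P_fx = potential · f_RH · f_PR · f_WS,
is a deliberate simplification standing in for a full
vegetation-index-driven emission model, which is out of scope.

```{r}
plot_activity_functions()
```

## Rupture mechanisms

The eight named experiments (`experiment_names()`) pair five in-atmosphere
rupture laws with three on-plant mechanical-rupture emission laws:

* threshold laws N_rupt = F_rupt · χ at RH ≥ 80 % (osmotic) or RH ≤ 30 %
  (electrical charging in dry air), requiring at least 1 grain m⁻³;
* wind laws N_rupt = F_rupt · χ · f_WS (no threshold — some rupture even at
  calm) and N_rupt = F_rupt · χ · WS (gated at WS ≥ 5 m s⁻¹);
* the lightning law N_rupt = F_rupt · χ · n_lightning, scaled by the
  per-cell hourly strike count re-gridded from a point-strike list.

Because the WS and lightning multipliers are unbounded, the raw product can
exceed the available grains; n_rupt is capped at χ (the uncapped value is
kept as a diagnostic). The 1 grain m⁻³ gate is stated only for the
threshold law; we apply it to all in-atmosphere mechanisms by default for
consistency (`gate_all_mechanisms = FALSE` restricts it to the humidity
thresholds). Lightning counts are column quantities — strike locations
carry no altitude — so the count triggers rupture at every level of its
column where pollen is present.

On-plant mechanical rupture is a surface SPP emission flux,
M_rupt = F_rupt n_spg P_fx G (m_SPP/m_pol), with G = (1 − f_PR f_RH) for
the moisture variant, G = f_WS for the wind-function variant and G = WS
(threshold-gated) for the wind variant. One airborne shell per ruptured
grain accompanies the flux, since mechanical-rupture experiments add
thousands of countable shells to the air. There is deliberately no cap on
the on-plant pollen reservoir; a reservoir term is a documented hook for
when SPP measurements become available.

Operator order within a model step is: transport first, then surface
emission, then in-atmosphere rupture acting on the freshly computed
whole-pollen field — so rupture products are transported only from the
following step, which is what confines lightning-produced SPPs behind a
fast-moving front.

## Transport core

The dispersion component is intentionally minimal — a stand-in for a full
chemical-transport model, chosen for positivity and exact budget closure:

* first-order upwind advection in flux form with dimensional splitting and
  automatic sub-stepping (total outflow Courant number ≤ 1 per cell);
  boundary inflow is tracer-free, outflow is recorded for the budget;
* implicit (backward-Euler) vertical diffusion in flux form, solved with
  the Thomas algorithm; conserves column burdens to roundoff;
* explicit donor-cell gravitational settling with the flux through the
  lowest layer base accumulated as surface deposition.

Settling velocities come from Stokes' law (ρ g d²/18µ): ~0.037 m s⁻¹ for
whole grains (also used for shells, whose fall speed is otherwise
unconstrained — they are airborne and advected, since trap counts of shells
are the observable). For SPPs the adopted default is 1 × 10⁻⁴ m s⁻¹
(0.01 cm s⁻¹), the value used in this parameterisation family; it is ~9×
the plain Stokes value for a 600 nm sphere, and is kept as an overridable
config default with the discrepancy noted here.

The default grid is 40 × 40 cells at 3 km with 15 height levels to 5 km and
a ~40 m lowest layer (so "the first 40 m" diagnostic is the lowest level),
time step 300 s with hourly met held constant within the hour. These sizes
keep every experiment to well under a minute while preserving the study's
horizontal resolution. Wet scavenging is omitted (scant rain in the event;
no formulation given), as are chemistry, aerosol microphysics and nesting.

A first-order scheme converges slowly: halving the time step changes a
24-h site series by a few percent once the settling Courant number
v_s Δt/Δz is small, and the suite checks convergence in that regime. Mass
budgets, by contrast, close to ~1e-15 at any step size, and that closure —
emission + rupture production − deposition − boundary outflow − rupture
removal = airborne change — is asserted hourly in every test run.

## Synthetic meteorology

`gust_front_scenario()` generates the storm deterministically from printed
event anchors: 18 % pre-frontal surface RH and 34 °C; frontal passage at
the site 26 h into a 34-h run (17:30 local time); a linear RH ramp reaching
80 % exactly `rh_recovery_lag = 5` h after local passage; a one-hour gust
spike (20 m s⁻¹ default); a ~10 °C temperature drop; up to 4 mm of rain
west of the site and 2 mm east; a moist mid-level band (~4 km) tracking the
front but kept below the 80 % rupture threshold; and a strike track running
from the domain's north-west to south of the site. Strikes are placed 5–20
km behind the gust front's leading edge, reflecting that the convective
cores (where lightning originates) trail the outflow boundary — in the 2016
event no strikes were recorded in the city itself. Strike lists are thinned
so no cell-hour exceeds 6 strikes, the observed domain maximum. The front's
propagation speed was not reported and is a free parameter (default
15 m s⁻¹ eastward, typical of severe gust fronts). Pre-frontal winds are
north-westerly at ~7 m s⁻¹ with small seeded perturbations; the post-frontal
westerly (3 m s⁻¹) is deliberately slower than the front so nothing
produced behind it can outrun it.

`humid_night_scenario()` is the counterfactual: a diurnal humidity cycle
(RH > 80 % around 03:00 local, < 50 % mid-afternoon), light winds, no rain,
no lightning — several consecutive quiet nights. Under the RH ≥ 80 % rule
this scenario ruptures pollen every night, the false-positive behaviour
that undermines the humidity hypothesis as a forecasting trigger.

`synthetic_observations()` emulates hourly volumetric-trap counting:
concentrations are sampled at 0.6 m³ per hourly transect (10 L min⁻¹),
counts drawn from a Poisson distribution and converted back to
grains m⁻³. What the generator does *not* emulate: taxon mixtures, trap
efficiency drift, sub-hourly intermittency, or the possibility that grains
shatter without leaving a countable shell. Passing tests therefore show
that the mechanisms behave as parameterised under clean forcing — not that
any mechanism is validated against the real event.

The emission potential defaults to 1 × 10⁻⁷ g m⁻² s⁻¹, set once so that
the quasi-steady surface-layer concentration implied by emission against
Stokes settling over a 40 m layer, C ≈ P_fx/v_s, is of order 100 grains
m⁻³ — the magnitude recorded at the Melbourne trap around the event.

## Evaluation

`regression_stats()` reports the slope *s* of an ordinary least-squares
regression and the Pearson correlation *r* between modelled and observed
hourly series. The regression direction is the model regressed on the
observations (slopes are quoted per model run); hours missing in either
series are dropped pairwise. `vertical_profile()` adds the height at which
whole pollen drops below 1 grain m⁻³ (log-linear interpolation, exact for
an exponentially decaying column); `fraction_below()` gives the
thickness-weighted fraction of a column burden below a height;
`surface_map()` splits the domain-total burden about the front line, the
statistic that distinguishes the lightning mechanism (behind-front fraction
> 0.9) from the wind and dry-air mechanisms (SPPs on both sides).

## A worked run

```{r, fig.width = 6, fig.height = 5}
met <- gust_front_scenario()
run <- run_experiment(experiment_config("rh80"), met)
glance(run)
autoplot(run)
```

The humidity-threshold experiment produces no SPPs at the site until five
hours after frontal passage — the central negative result: under the dry
gust front the osmotic mechanism cannot act at storm time.

## Design choices that were genuinely open

* The `mrupt_*` experiments run their paired in-atmosphere rule
  simultaneously (both pathways on), matching how combined shell series are
  presented; `mech_includes_in_atmosphere = FALSE` isolates the surface
  pathway.
* Emission is applied after transport and before rupture; only the
  rupture-last ordering is externally constrained, the emission placement
  is our choice and is documented here.
* Correlations use all pairwise-complete hours; whether missing transects
  should be excluded differently is unresolved and configurable upstream
  of `regression_stats()`.
* Gridded I/O uses self-describing long-format CSV with named dimensions
  (time, level, y, x) and a units header rather than a binary array format,
  keeping every artefact plain text.

## Known limitations

The transport core is first-order and diffusive; fronts smear over a few
cells and deposition near sharp gradients carries O(Δt) bias. The scenario
generator produces idealised monotone ramps, not observed soundings; the
vertical humidity structure is a two-layer idealisation. Shell fall speed
is assumed equal to whole-grain fall speed. No allergen-potency weighting
of SPPs is attempted. None of the acceptance-level findings depend on
these simplifications' details, but absolute concentrations do.
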