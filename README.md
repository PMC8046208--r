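# sppsim

Desk-scale simulation of grass-pollen rupture and sub-pollen particle (SPP)
transport for thunderstorm-asthma research.

Epidemic thunderstorm asthma is caused by sub-micron, allergen-bearing
fragments released when whole grass pollen grains rupture — whole grains
(~35 µm) are too large to reach the small airways. The most-cited rupture
trigger is osmotic shock at high relative humidity, yet the worst recorded
event (Melbourne, November 2016) happened in extremely dry gust-front air.
`sppsim` lets you run that confrontation on a desktop: a gridded
emission–rupture–transport model with eight rupture parameterisations, a
synthetic-meteorology generator that reproduces the storm's observed
anchors, and the slope/correlation evaluation used to compare modelled and
trap-observed pollen-shell time series.

## The model in brief

Pollen is carried as mass concentration and converted to grains with the
per-grain mass m_pol = 22.4 × 10⁻⁹ g (1 grain m⁻³ ≡ 0.0224 µg m⁻³).
In-atmosphere rupture converts whole grains into one empty shell plus
n_spg = 700 SPPs each (m_SPP = 1.13 × 10⁻¹³ g), with rupture fraction
F_rupt = 0.7, under one of five laws:

| experiment  | rupture law                        | trigger                |
|-------------|------------------------------------|------------------------|
| `rh80`      | N_rupt = F_rupt χ                  | RH ≥ 80 %              |
| `rh30`      | N_rupt = F_rupt χ                  | RH ≤ 30 % (electrical) |
| `fws`       | N_rupt = F_rupt χ f_WS             | none                   |
| `ws5`       | N_rupt = F_rupt χ WS               | WS ≥ 5 m s⁻¹           |
| `lightning` | N_rupt = F_rupt χ n_lightning      | strikes in cell        |

plus three `mrupt_*` variants adding on-plant mechanical rupture, a surface
SPP emission flux M_rupt = F_rupt n_spg P_fx G (m_SPP/m_pol) with
G ∈ {1 − f_PR f_RH, f_WS, WS}. Emission activity factors are logistic:
f_RH is calibrated to 0.95 at 50 %RH and 0.05 at 80 %RH, f_PR to 0.95 at no
rain and 0.05 at 0.5 mm h⁻¹, and f_WS rises from 0.33 at calm to 0.75 at
the 5 m s⁻¹ saturation speed. Transport is first-order upwind advection,
implicit vertical diffusion and Stokes settling on a 40 × 40 × 15 grid at
3 km resolution, with exact mass-budget closure.

## A worked example

```r
library(sppsim)

met <- gust_front_scenario()          # the 2016-style dry gust-front storm
run <- run_experiment(experiment_config("rh80"), met)
glance(run)
#> # A tibble: 1 × 7
#>   experiment n_hours peak_whole_pollen peak_shells peak_spp_number total_ruptured_grains max_rel_residual
#>   <chr>        <int>             <dbl>       <dbl>           <dbl>                 <dbl>            <dbl>
#> 1 rh80            34              111.        290.         238065.               2.83e15          3.62e-15

subset(run$site, hour >= 25 & hour <= 32,
       c(hour, whole_pollen, shell_number, spp_number, rh, ws))
#> # A tibble: 8 × 6
#>    hour whole_pollen shell_number spp_number    rh    ws
#>   <dbl>        <dbl>        <dbl>      <dbl> <dbl> <dbl>
#> 1    25         97.2          0           0   18.0  6.62
#> 2    26         83.1          0           0   18.0 22.8
#> 3    27         21.8          0           0   30.4  2.90
#> 4    28         22.3          0           0   42.8  3.38
#> 5    29         49.2          0           0   55.2  2.76
#> 6    30         41.6          0           0   67.6  3.11
#> 7    31         32.6         96.0     76487.  80.0  2.85
#> 8    32         29.7        232.     184306.  88.0  2.84
```

Read the table as the event unfolds: ~100 grains m⁻³ of whole pollen and
18 % RH before the front, the ~23 m s⁻¹ gust at passage (hour 26), and —
the central negative result — **zero SPPs at storm time**: the humidity
threshold only triggers when RH reaches 80 % five hours later (hour 31),
far too late to explain an emergency-call spike immediately after frontal
passage. Running `experiment_config("lightning")` instead produces SPPs at
storm time and confines > 90 % of them behind the front
(`surface_map(..., front_x = front_position(...))`), the only mechanism to
do so; the wind and dry-air mechanisms scatter SPPs on both sides.

Evaluation against (synthetic or real) trap observations:

```r
obs <- synthetic_observations(run$site$whole_pollen, seed = 1)
regression_stats(model = run$site$whole_pollen, obs = obs$whole_pollen)
#> <eval_result> n = 34 hours: s = 0.903 (se 0.052), r = 0.950
```

A thin command-line wrapper lives at `inst/cli/sppsim`
(`simulate`, `scenario`, `evaluate`, `selftest`).

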