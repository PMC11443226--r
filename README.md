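# hemsim

A functional–structural plant model (FSPM) of daylily (*Hemerocallis
citrina*) stands, for agronomists and crop modellers who want to compare
planting configurations by the flower-bud yield they produce. The package
simulates one production season (days 91–242) at a daily step with explicit
3D leaf geometry, then sweeps 36 planting configurations (row pattern, row
and plant spacing, density) and analyses the sweep with PLS path modeling.

Each simulated day couples four submodels:

* **Sky radiation** — daily extraterrestrial radiation from solar geometry,
  surface radiation from the cloud-cover model
  `H/H₀ = −0.08 + 0.21 √(Tmax − Tmin) − 0.012 N̄` (clamped to [0, 1]), and a
  discretized sky of 72 diffuse sources plus one direct sun.
* **Canopy light interception** — a deterministic depth-sorted projection
  tracer (with a Monte Carlo cross-check mode) over parallelogram leaf
  facets, 3×3 periodic tiling, black ground; absorbed W m⁻² convert to PPFD
  with the factor 2.275 µmol J⁻¹.
* **Leaf physiology** — Farquhar–von Caemmerer–Berry C3 assimilation
  coupled to Ball–Woodrow–Berry stomatal conductance
  (`gs = g0 + m·A·RH/Cs`) and a leaf energy balance, solved jointly per
  leaf per day.
* **Source–sink carbon allocation** — organ sink strengths from the beta
  growth function `dw/dt = c_m ((t_e−t)/(t_e−t_m)) (t/t_m)^{t_m/(t_e−t_m)}`,
  proportional allocation from a shared per-plant assimilate pool
  (`gr = (S_pot/S_totdem)·ap`, capped at potential), growth respiration
  (1.39 g glucose g⁻¹ DM), maintenance respiration (0.014 g g⁻¹ day⁻¹), a
  15 % root draw, and fresh weights from per-organ fresh:dry ratios.

Statistics utilities fit beta growth curves to organ time series
(`fit_beta()`, with R², RMSE and F metrics) and run a from-scratch PLS-PM
implementation (`fit_plspm()`: path weighting scheme, Cronbach's alpha,
Dijkstra–Henseler rho_a, composite reliability, AVE, specific indirect
effects).

## Worked example

```r
library(hemsim)

weather <- generate_synthetic_weather(seed = 1)  # 2022-like Datong season
season  <- simulate_season(5, weather = weather, seed = 1)
season
#> <hemsim_season> scenario 5
#>   plants 40 (interior 16), density 83333 /ha
#>   yield 42.5 t/ha; 510.3 g/plant; 170.1 g/inflorescence
#>   mean bud length 0.128 m; buds/scape 40.0; scape@215 1.19 m
```

Scenario ID5 is equidistant rows 0.8 m apart with 0.15 m plant spacing
(83,333 plants ha⁻¹). The summary says: the stand yields 42.5 t of fresh
buds per hectare; each plant carries on average 510.3 g of buds across its
three inflorescences (170.1 g per inflorescence, 40 buds each); the mean
final bud length of 0.128 m clears the 0.12 m market-quality threshold; and
the scape reaches its calibrated 1.19 m length by day 215. A full sweep and
the dual-criterion selection (bud length ≥ 0.12 m and yield ≥ 35 t ha⁻¹)
run as:

```r
sweep <- run_sweep(seed = 1)          # 36 scenarios, shared weather
select_optimal(sweep)                 # qualifying ids and the top yielder
pls <- fit_plspm(sweep_plspm_data(sweep), sweep_plspm_spec())
tidy(pls)                             # standardized path coefficients
```

A thin command-line front end lives at `inst/cli/hemsim.R`
(`simulate`, `sweep`, `select`, `plspm` subcommands).

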