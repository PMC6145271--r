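# fermkin

Kinetic modelling of lactic acid bacteria (LAB) growth during Thai
fermented-sausage fermentation, for food microbiologists and
fermentation engineers who want to simulate, fit and validate an
unstructured six-state model of the process — and to weigh the
economics of fermenting in transit against refrigerated delivery of
pre-fermented product.

## The model

Six coupled ODEs track, per 100 g of sausage: LAB biomass `y1` (g dry
cells), total protein nitrogen `y2` and nonprotein nitrogen `y3`
(g N), lactic acid `y4`, formic acid `y5` and glucose `y6` (g).
Growth is protein-limited Monod kinetics with a logistic bracket, an
exponential lag factor `1 − exp(−k3 t)` and first-order lysis:

    dy1/dt = (1 − e^(−k3·t)) · k1·y2/(k2 + y2) · y1·(1 − y1/y1_max) − k12·y1

Protein consumption is tied to biomass formation and NPN release
through nitrogen mass fractions (with correction factors `cor_bio`,
`cor_NPN` and a first-order loss `cor_X`); NPN, lactate and formate
follow Luedeking–Piret laws (growth-associated + non-growth terms, the
products saturating at `y4_max`, `y5_max`); glucose is consumed for
growth (`k10`) and lactate synthesis (`k11`). The system is solved by
orthogonal collocation on finite elements (compiled core), with an
adaptive Runge–Kutta route through `deSolve` as an independent
numerical oracle.

Parameters are estimated by Metropolis-within-Gibbs Monte-Carlo
sampling (log-uniform priors, log-space random walk, least-squares
initialisation, ≥10,000 draws) and fits are screened by a per-state
chi-squared goodness-of-fit test at the 95% level. A synthetic-data
generator reproduces the study's sampling design (6 timepoints ×
triplicate assays, assay-scale Gaussian noise), so the whole pipeline
is testable without any external data. A companion module implements
the preparation-plus-transportation cost model
`TC = C0 + (C1 + C2)·t_dr + C3(t_dr)` for refrigerated and
nonrefrigerated trucks, including the driver overtime rule.

## A worked example

```r
library(fermkin)

# simulate the calibrated control batch over the 60-h fermentation
tr <- simulate_fermentation(batch_params("control"),
                            default_initial_conditions("control"),
                            times = c(0, 12, 24, 36, 48, 60))
as.data.frame(tr)
#>   time_hr      y1     y2     y3     y4      y5     y6
#> 1       0 0.00400 0.5630 0.1090 0.0000 0.00000 2.5000
#> 2      12 0.02195 0.4150 0.1091 0.6076 0.01698 1.5527
#> 3      24 0.14402 0.2937 0.1092 1.0060 0.03384 1.0026
#> 4      36 0.19537 0.2123 0.1092 1.2190 0.04839 0.6994
#> 5      48 0.19842 0.1569 0.1092 1.3325 0.06112 0.5223
#> 6      60 0.19847 0.1163 0.1093 1.3996 0.07276 0.4164
```

Biomass shows the long lag (11% of its plateau at 12 h), climbs to its
carrying capacity of 0.2 g dcw/100 g (10^9 CFU/g) by ~36 h, protein
falls while lactate approaches saturation — the qualitative signature
of the fermentation. Fit the model back to noisy synthetic data and
inspect the posterior:

```r
obs <- generate_observations(
  generator_config("control", noise_frac = 0.01, truncate = FALSE,
                   seed = 1))
fit <- ferm_fit(obs, n_draws = 10000, seed = 1)
summary(fit)   # medians, 95% intervals, acceptance, PSRF, chi-squared
plot(fit)      # observations vs fitted trajectory, one panel per state
```

Transport economics of one 4.2-t truckload:

```r
compare_scenarios(c(0, 120, 360, 600))
#>   distance_km refrigerated nonrefrigerated difference
#> 1           0     13170.15        13042.15      128.0
#> 2         120     13199.49        13057.09      142.4
#> 3         360     13258.17        13086.97      171.2
#> 4         600     13318.44        13118.44      200.0
```

The nonrefrigerated truck (fermenting in transit) is cheaper at every
distance — lower labor and fuel cost — and the gap widens with
distance.

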