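# shelfcarbon

Tools for timing and quantifying the fate of terrestrial organic carbon
(terrOC) during cross-shelf sediment transport, built around
compound-specific radiocarbon ages of terrestrial biomarkers. Written for
isotope biogeochemists working on land–ocean carbon transfer on wide
continental margins (the motivating system is the Laptev Sea shelf,
from the Lena River mouth to the shelf edge).

The package implements one inference chain, end to end:

1. **Radiocarbon algebra** — conversions between Δ¹⁴C, fraction modern
   (*f*ₘ) and conventional age via the 8033-year ¹⁴C mean life,

   Δ¹⁴C = (*f*ₘ·e^((1950−yr)/8033) − 1)·1000,  age = −8.033 kyr·ln *f*ₘ,

   plus decay of isotope distributions over a transport time
   (μ_τ = μ₀·e^(−τ/8033), σ_τ = σ₀·e^(−τ/8033)), the FAME
   methylation dead-carbon correction, and calendar calibration against a
   user-supplied curve.
2. **Transport times** — a Monte-Carlo fit of the linear age–depth model
   Age = *a*·depth + *b* (slope = inverse net cross-shelf transport
   velocity, intercept = pre-ageing on land), and net transport times
   τ = *a*·depth per station.
3. **Degradation kinetics** — Bayesian errors-in-variables MCMC fit of
   C(t) = C_deg·e^(−kt) + R to surface-area-normalized pool loadings
   vs transport time, with the recalcitrant fraction f_R = R/C(0).
4. **Source apportionment** — a dual-carbon-isotope (δ¹³C, Δ¹⁴C)
   three-endmember Bayesian mixing model (active-layer permafrost, Ice
   Complex Deposit permafrost, marine) whose active-layer endmember is
   decayed by each sample's transport time, sampled by a tuned
   Metropolis MCMC and cross-checked against an exact grid posterior.
5. **Support modules** — loading normalization and hydrodynamic-sorting
   correction, a seeded synthetic-transect generator with known truth,
   delimited-text I/O, and a one-call pipeline (`run_pipeline()`).

The bundled station table (`laptev_stations()`) carries the published
radiocarbon transect data; per-pool loading tables are supplementary
material of the original study and can be supplied by the user.

## Worked example

```r
library(shelfcarbon)

st <- laptev_stations()
dated <- !is.na(st$csra_cal_age_kyr)
model <- fit_age_depth(st$depth_m[dated], st$csra_cal_age_kyr[dated],
                       st$csra_cal_age_sd_kyr[dated],
                       n_draws = 10000, seed = 42)
model
#> Age-depth transport model (8 stations, 10000 Monte-Carlo draws, seed 42)
#>   a = 0.03621 ± 0.00347 kyr/m   b = 6.831 ± 0.1166 kyr
#>   R^2 = 0.728, slope p = 0.00705

transport_time_at_depth(model, 92)
#> 3.331 ± 0.3192
```

The slope says the material crosses the shelf at ~28 m of water depth
gained per millennium; at the 92 m shelf-edge station that amounts to a
net transport time of ~3.3 kyr (the published analysis reports
3.6 ± 0.3 kyr; the unweighted and inverse-variance-weighted estimators
bracket this value, see `fit_age_depth(..., weights =)`). The intercept —
the age of the biomarkers on arrival at the river mouth — is ~6.8 kyr of
pre-ageing on land.

```r
ems <- build_endmembers(tau_kyr = 3.56, sampling_year = 2014)
ems
#> # A tibble: 3 × 6
#>   name    d13c d13c_sd  d14c d14c_sd time_dependent
#>   <chr>  <dbl>   <dbl> <dbl>   <dbl> <lgl>
#> 1 AL     -27       1.2 -507.    94.4 TRUE
#> 2 ICD    -26.3     0.7 -940     84   FALSE
#> 3 marine -21       2.5  -50     12   FALSE

obs <- isotope_observation(-24.6, 0.1, -364, 2, sampling_year = 2014)
mix <- apportion_sample(obs, ems, mcmc_config(seed = 7))
mix
#> Dual-isotope source apportionment (99000 retained draws, acceptance 0.22, seed 7)
#>   AL       0.391 ± 0.199
#>   ICD      0.169 ± 0.100
#>   marine   0.440 ± 0.118
#>   f_terr   0.5602 ± 0.1179
```

After 3.56 kyr of transport the active-layer endmember has decayed from
−232 ± 147‰ to −507 ± 94‰. For this shelf-edge-like bulk sample a bit
over half of the organic carbon is still terrestrial; note the
identifiability structure — the terrestrial *total* is much better
constrained (±0.12) than its split between the two permafrost sources
(±0.20, ±0.10), because the two terrestrial endmembers differ by only
0.7‰ in δ¹³C.

The whole chain (transport fit → per-station τ → decay fits → per-station
apportionment) runs in one call on any station table with the documented
columns: `run_pipeline(laptev_stations(), default_run_config(seed = 1))`.

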