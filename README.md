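# tempmort

Estimation and projection of temperature-attributable mortality for regional
daily time series, built around the distributed lag non-linear model (DLNM)
workflow used in environmental epidemiology: how many deaths does non-optimal
temperature cause today, and how many will it cause by the end of the century
under different emission, adaptation and population scenarios?

The package was designed for the Finnish setting — wellbeing-service-county
mortality counts censored below 3 deaths/day for data protection, county-mean
temperatures, minimum-mortality temperatures between 14 °C (north) and 16 °C
(south) — but every component is generic. Because the real mortality data are
restricted, the package ships a synthetic-data module that generates every
input with known ground truth, so the full pipeline is testable end to end.

## The model

Daily death counts are modelled by quasi-Poisson time-series regression

log E[Y_t] = α + f(x_t; θ) + s(t; β) + Σ_p h_p(z_pt; γ_p)

where `f` is a cross-basis — the row-wise tensor product of a natural cubic
spline in temperature (internal knots at the 10th/75th/90th percentiles in
the fixed-knots variant, or selected by qAIC) and a natural cubic spline in
lag over 0–21 days — `s` is a natural cubic spline of time with 7 df per
year controlling seasonal and long-term trends, and `h` holds day-of-week
indicators. Overdispersion is estimated by the Pearson statistic and scales
the coefficient covariance; qAIC = −2·logLik + 2·p·φ̂ ranks knot candidates.

The fitted surface is reduced by summing lag contributions to the overall
cumulative relative-risk curve RR(T), centred so RR = 1 at the region's
minimum-mortality temperature (MMT). Attributable deaths on each day are

AN_t = D_t · (1 − exp(−log RR(T_t)))

split into heat (T > MMT) and cold (T < MMT), summed over closed ten-year
intervals, and expressed as attributable fractions AF = 100·AN/ΣD.
Uncertainty comes from Monte-Carlo draws of the reduced-curve coefficients
(empirical 95% intervals). Projections run the attribution over pseudo-GCM
ensemble temperature series, with optional adaptation scaling of the
heat-side excess risk (RR′ = 1 + (1−a)(RR−1) for fractions a = 0.2 or 0.5)
and population scaling of baseline deaths from five-year trajectories.

## Worked example

Simulate an 18-year Helsinki-like series with a known V-shaped
exposure–lag–response surface (cumulative RR 1.3 ten degrees above the MMT,
1.4 twenty degrees below, overdispersion 1.5), fit the fixed-knots DLNM, and
project heat-attributable deaths onto a five-member high-emission ensemble:

```r
library(tempmort)

surface  <- true_surface(mmt = 16, heat_slope = log(1.3) / 10,
                         cold_slope = log(1.4) / 20)
helsinki <- gen_region_series("Helsinki", surface, baseline_rate = 15,
                              overdispersion = 1.5, seed = 42)
fit <- fit_region(helsinki, mmt = 16, variant = "fixed_knots")
fit$fit
#> Quasi-Poisson DLNM fit: 149 coefficients, 6553 days
#>   dispersion 1.520, qAIC 40910.2

predict_rr(fit$curve, c(-10, 0, 16, 20, 24))
#>   temp    rr  lo95  hi95
#> 1  -10 1.570 1.193 2.068
#> 2    0 1.335 1.065 1.673
#> 3   16 1.000 1.000 1.000
#> 4   20 1.072 0.974 1.179
#> 5   24 1.440 1.071 1.937

climatology <- baseline_death_series(helsinki)
ensemble <- gen_projection_members(climate_gen_spec(seed = 202), "SSP5-8.5",
                                   warming_range = c(5.8, 9.1))
proj <- project_scenario(fit$curve, ensemble, climatology,
                         gen_population(enabled = FALSE),
                         n_draws = 300, seed = 1)
subset(proj, component == "heat" &
         decade %in% c("2010-2019", "2050-2059", "2090-2099"))
#>     decade component     an  af   lo95   hi95
#>  2010-2019      heat  174.8 0.3 -274.2  574.9
#>  2050-2059      heat 1504.0 2.3 -283.6 3203.2
#>  2090-2099      heat 4397.6 6.6  470.2 8114.7
```

The fitted curve recovers the generating risk within its (wide) confidence
bands, the Pearson dispersion recovers the simulated overdispersion, and
heat-attributable deaths grow steeply with the ensemble's warming while the
intervals remain wide — the qualitative signature of county-level heat
projections. `run_full_pipeline()` loops this over regions × scenarios ×
adaptation levels × population settings and writes curve/result tables plus
a JSON run manifest; a thin command-line wrapper with subcommands
`simulate | fit | curve | attribute | project | all` lives at
`inst/cli/tempmort.R`.

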