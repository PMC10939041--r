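# ordstar

Ordinal geo-additive regression for areal household-survey data.

`ordstar` is for analysts who study a 3-level (or generally R-level)
ordinal outcome — the motivating case is household food-insecurity levels
cut from food consumption scores at 35.5 and 49 — observed on a panel of
households spread over administrative zones, and who want to separate
linear covariate effects, non-linear continuous effects, and spatially
structured vs. unstructured zone effects in one model.

## The model

A cumulative-link threshold model with a structured additive predictor:

    P(Y_i <= r) = F(theta_r - eta_i),      r = 1, ..., R-1
    eta_i = x_i' gamma + sum_j f_j(z_ij) + f_str(s_i) + f_unstr(s_i)

with `F` the standard normal (probit) or logistic (logit) CDF, `f_j`
cubic P-splines (20 equally spaced knots, second-order random-walk
penalty), `f_str` an intrinsic Gaussian Markov random field over the zone
contiguity graph (penalty = graph Laplacian) or a tensor-product P-spline
of zone centroids, and `f_unstr` an i.i.d. Gaussian zone effect.
Estimation is empirical Bayes: penalized Fisher scoring for the
coefficients and Fellner–Schall-type REML updates for the variances
`tau^2`, with a small-variance stop rule (`tau^2 <= 1e-5` freezes a term
to its penalty nullspace).  Models are compared by
`GCV = n * deviance / (n - edf)^2`; global Moran's I (analytic +
permutation inference) tests zone aggregates for spatial clustering; zones
whose 95% spatial-effect band excludes zero are classified hot/cold
spots.  See the methods vignette
(`vignettes/ordinal-geoadditive-methods.Rmd`) for the full account.

## Worked example

```r
library(ordstar)

# a synthetic three-wave study: 64 zones, 3,835 households, known truth
truth <- synthetic_truth(seed = 1)
panel <- gen_panel(truth, n_households = 3835, waves = 3, seed = 1)

fit <- ordstar(panel$data,
               level ~ urban + shock + s(coping) + s(age) +
                 mrf(zone) + re(zone),
               graph = truth$graph, link = "probit")
tidy(fit)
#> # A tibble: 4 x 5
#>   term    estimate std.error statistic  p.value
#>   <chr>      <dbl>     <dbl>     <dbl>    <dbl>
#> 1 theta_1  -0.0652    0.0177     -3.68 2.31e- 4
#> 2 theta_2   0.776     0.0187     41.5  0
#> 3 urban    -0.342     0.0342     -9.99 1.77e-23
#> 4 shock     0.0654    0.0229      2.85 4.32e- 3

tidy(fit, "smooths")
#> # A tibble: 4 x 6
#>   term      kind    variance smooth_par    df stopped
#>   <chr>     <chr>      <dbl>      <dbl> <dbl>   <int>
#> 1 s(coping) pspline  0.00526     3010.   5.96       0
#> 2 s(age)    pspline  0.00216     7314.   6.42       0
#> 3 mrf(zone) mrf      0.597         12.9 50.0        0
#> 4 re(zone)  iid      0.0366        27.3 10.2        0

variance_partition(fit)   # % of spatial variation that is structured
#> [1] 94.23

zone_effects(fit)         # per-zone effects, bands, hot/cold class
morans_i(zone_aggregate(panel$data, "insecure-proportion",
                        graph = truth$graph),
         truth$graph, seed = 2)
#> I = 0.518, E[I] = -0.0159, analytic p = 4.7e-09, permutation p = 1e-04
```

The urban and shock estimates recover the generating values (−0.3883,
0.0683) within sampling error, and the thresholds recover the generating
(−0.3789, 0.4742) shifted by the generator's calibration offset −0.3112,
which the thresholds absorb (expected −0.0677, 0.7854).  The structured
variance estimate 0.597 sits next to the generating 0.6104; the
structured share (94.2% in this seed) brackets the generating share
90.04%, and the structured-field correlation with the truth is 0.899 at
this size.  `run_analysis()`
drives the whole workflow (imputation, descriptives, Moran's I, several
model variants, GCV comparison, CSV export) from one configuration;
`simulate_study()` writes a complete synthetic study (panel CSV, `.gra`
graph, centroids, truth sidecar) to disk.

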