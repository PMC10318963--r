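# fpchoice

How far will a woman travel for a better family planning facility?

In facility surveys, women routinely *bypass* the nearest provider: the
closest facility may be a few hundred metres away while the one actually
visited is several kilometres off. `fpchoice` is an R package for
quantifying what drives that behaviour. It is aimed at reproductive-health
researchers and health-systems analysts working with linked woman/facility
survey data: a women's survey (location, age, education, household assets,
the facility chosen) and a facility survey (location, type, contraceptive
methods and their stock, other services, fees, opening days, provider-sex
composition).

## The model

Each woman `i` chooses among the same `J` facilities. Facility `j` gives
her utility

    u_ij = Σ_m β_m x_ijm + Σ_p λ_{g(j)p} Z_ip + ε_ij

with alternative-varying attributes `x_ijm` (distance in km, a
nearest-facility flag, the stock-validated number of family planning
methods, other services, hospital indicator, fee, weekend opening,
female-only providers), case-specific covariates `Z_ip` (education and
wealth-quintile dummies) interacted with facility groups `g(j)`
(hospital vs other by default), and i.i.d. standard Gumbel errors. Utility
maximisation then gives the alternative-specific conditional logit

    P_ij = exp(V_ij) / Σ_k exp(V_ik).

The package fits this model by maximum likelihood (Newton–Raphson with
analytic score and observed information) and converts the estimates into
the headline quantity, the **willingness to travel**

    WTT_a = β_a / |β_d|   (km per unit of quality attribute a),

with a delta-method standard error and Wald interval. Around the model sit
the data-construction stages: haversine or external (road-network)
distance matrices, nearest-facility indicators, stock-validated method
counts (a method counts only with an unexpired lot on the survey day), a
DHS-style PCA wealth index, and descriptive summary tables. A
synthetic-study generator reproduces the whole survey structure —
clustered women, facility quality margins, Gumbel-error utility-maximising
choices — so the entire pipeline is testable without microdata.

## Worked example

Simulate the default study (336 women, 110 clusters, 28 facilities, the
published coefficient values as truth) and run every stage:

```r
library(fpchoice)

cfg <- simConfig(seed = 2020)
res <- runPipeline(outDir = tempdir(), cfg = cfg, seed = 2020)
res$fit
```

```
Conditional logit fit: 336 cases, 15 coefficients
  log-likelihood -722.5208; converged: TRUE (6 iterations, |grad| 7.50e-12)
                               term estimate    se ci_low ci_high        p
                           distance    -0.18 0.017  -0.22   -0.15  <0.0001
                            nearest     0.68 0.188   0.31    1.05 0.000279
                       n_fp_methods     0.24 0.040   0.16    0.32  <0.0001
                   n_other_services     0.19 0.025   0.14    0.23  <0.0001
                           hospital     0.18 0.324  -0.46    0.81    0.589
                        charges_fee     0.20 0.172  -0.13    0.54    0.236
                      open_weekends     0.64 0.180   0.29    1.00 0.000375
              female_only_providers     1.92 0.176   1.58    2.27  <0.0001
 ...                                  (case-covariate interaction terms)
```

The negative `distance` coefficient says farther facilities are less
likely to be chosen; positive quality coefficients say what compensates
for distance. Dividing by |β_distance| expresses each as kilometres:

```r
wttTable(res$fit, c("n_fp_methods", "n_other_services",
                    "female_only_providers"))
```

```
              attribute        km        se    ci_low   ci_high
1          n_fp_methods  1.306130 0.2448578 0.8262083  1.786051
2      n_other_services  1.013061 0.1748182 0.6704170  1.355704
3 female_only_providers 10.519314 1.3031145 7.9652092 13.073418
```

In this simulated study a woman accepts ~1.3 extra km for one more
contraceptive method in valid stock, ~1.0 km for one more non-FP service,
and ~10.5 km for a facility staffed by female providers only — close to
the generating ratios (0.27/0.17, 0.23/0.17 and 1.89/0.17). Bypassing
emerges as in real data: here the mean nearest-facility distance is
2.00 km while the mean chosen-facility distance is 6.42 km.

A command-line wrapper (`inst/scripts/fpchoice-cli.R`) exposes
`simulate`, `summarize`, `fit`, `wtt` and `run-all` over CSV files; every
randomised command requires an explicit `--seed`.

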