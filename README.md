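# maekin

Kinetic modelling and statistical analysis of microwave-assisted
extraction (MAE) of mangiferin.

## The problem

Mangiferin, a xanthone-C-glycoside with strong antioxidant activity, is
extracted from dried mango ginger (*Curcuma amada*) by microwave-assisted
solid–liquid extraction. A one-factor-at-a-time (OFAT) screen varies
microwave power (250–550 W, with a degrading 900 W level), aqueous-ethanol
concentration (50–100 % v/v) and pre-leaching time (1–30 min), recording
mangiferin yield (mg per g dry matter) over an extraction-time grid of
1–120 s. `maekin` is for researchers in natural-product extraction and
bioprocess modelling who need to (i) fit sigmoidal extraction kinetics per
design point, (ii) fit a whole curve family jointly against the design
variable, (iii) test factor effects and rank levels, and (iv) quantify
antioxidant activity of the extract.

## Models and statistics

Per design point, two kinetic models describe yield *Y*(*t*):

* modified first-order: *Y*(*t*) = *Y*<sub>max</sub> (1 − e<sup>−*k*<sub>m</sub>*t*</sup>)
* delayed logistic: *Y*(*t*) = *Y*<sub>max</sub> / (1 + e<sup>−*k*<sub>m</sub>(*t* − *τ*)</sup>)

with asymptotic yield *Y*<sub>max</sub> (mg/g), rate constant
*k*<sub>m</sub> (s⁻¹) and time delay *τ* (s). A generalized logistic
couples the whole family of one factor to its design variable *x* (power
in W or ethanol in % v/v):

*Y*(*t*, *x*) = *A* (1 − e<sup>−*x*/*x*<sub>ref</sub></sup>) / (1 + e<sup>−*k*<sub>m</sub>(*t* − *τ*)</sup>)

fitted by variable projection (the amplitude *A* is solved by linear least
squares inside each Levenberg–Marquardt iteration, so only
(*x*<sub>ref</sub>, *k*<sub>m</sub>, *τ*) are iterated). Fits are judged by
the dimensionless indicator *Y*<sub>RMS</sub>/*Y*<sub>max</sub>
(root-mean-square residual over fitted asymptote). Factor effects are
tested with a balanced two-way ANOVA (factor × extraction time, one
observation per cell, error = interaction) reporting noncentrality
λ = df·F and observed power; levels are ranked with the
Student–Newman–Keuls studentized-range procedure. DPPH radical-scavenging
IC50 is estimated by log-linear interpolation (default) or a
four-parameter logistic fit. A seeded synthetic-data generator reproduces
the OFAT design so every stage is testable without raw instrument data.

## Worked example

Simulate the microwave-power screen at the default design (5 levels × 25
times, additive noise sd 0.01 mg/g) and run the full pipeline:

```r
library(maekin)
rep <- run_report("power", noise_sd = 0.01, seed = 11)
print(rep$table_logistic, digits = 4)
#>   level     y_max     k_m     tau       gof converged
#> 1   250 4.759e+05 0.01484 1261.51 1.572e-08      TRUE
#> 2   350 5.578e-01 0.15087   11.57 1.648e-02      TRUE
#> 3   450 6.127e-01 0.16300   11.71 1.393e-02      TRUE
#> 4   500 6.343e-01 0.12216   12.54 1.530e-02      TRUE
#> 5   550 7.160e-01 0.12236   11.24 1.249e-02      TRUE
```

Levels 350–550 W recover their generating parameters (compare
`default_truth("power")`) with the goodness indicator near 0.015, the
noise-to-asymptote ratio. The 250 W level sits at the noise floor
(asymptote ≈ 0.014 mg/g ≈ noise sd), so its parameters are not
identifiable: the optimizer converges to an extrapolated, essentially
linear curve — a caveat discussed in the methods vignette (note the
deceptively tiny indicator, normalized by the runaway asymptote).

```r
print(rep$anova)
#>  source     ss  df       ms      f         p noncent power
#>   power 6.1640   4 1.541000 341.80 7.516e-56  1367.0     1
#>    time 1.7600  24 0.073320  16.26 3.972e-24   390.3     1
#>   error 0.4328  96 0.004509     NA        NA      NA    NA
#>   total 8.3570 124       NA     NA        NA      NA    NA
print(rep$snk)
#>  level        mean subset
#>    550 0.630061099      a
#>    500 0.552274795      b
#>    450 0.540691106      b
#>    350 0.492157899      c
#>    250 0.009769109      d
```

Both power and extraction time are highly significant and 550 W alone
occupies the top homogeneous subset — the optimum power. Joint fit of a
family generated from the generalized-logistic reference truth
(*x*<sub>ref</sub> = 759.42 W, *k*<sub>m</sub> = 0.14 s⁻¹, *τ* = 11.68 s):

```r
ds <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 11,
                            truth_model = "global")
fit_global(ds)
#> Kinetic fit: generalized logistic (joint) model
#>        ref        k_m        tau  amplitude
#> 748.880000   0.138840  11.995400   0.990807
#>   rms = 0.00927482 mg/g, Y_RMS/Y_max = 0.017994, converged in 6 iterations
```

DPPH antioxidant assay on a synthetic dose–response with midpoint
17.04 µg/ml:

```r
concs <- c(1, 5, 10, 20, 40, 60, 80, 100)
hill <- log(1 / 0.9765 - 1) / log(17.04 / 100)
set.seed(11)
inh <- 100 / (1 + (17.04 / concs)^hill)
a <- pmax(0.80 * (1 - inh / 100) + rnorm(8, 0, 0.005), 0)
dr <- dose_response(concs, a, control_absorbance = 0.80)
ic50(dr)                 # 16.55028  (log-linear interpolation, ug/ml)
ic50(dr, "logistic4p")   # 16.78064  (4PL fit, ug/ml)
```

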