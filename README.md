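# sovex

Modelling of packed-bed supercritical CO₂ extraction of plant oils:
broken-and-intact-cell (BIC) kinetics, mass-transfer correlations,
factorial yield analysis, and manufacturing-cost scale-up. The package
bundles a complete *Pistacia lentiscus* (mastic) leaf-oil case study —
operating conditions, design tables, fitted kinetic parameters and cost
constants — together with seeded synthetic-data generators, so every stage
of the analysis is runnable and testable from the package alone.

## Who it is for

Process engineers and natural-product researchers who fit overall
extraction curves (OEC) from supercritical fluid extraction (SFE)
experiments, screen operating conditions with small factorial designs, and
need a first-pass manufacturing cost for scale-up decisions.

## The models

**Kinetics.** Milling breaks a fraction *G* of the plant cells. With
dimensionless time ψ = t·Q·y_s/(N·x₀), the cumulative extracted fraction
e = E/(N·x₀) follows the three-period analytical BIC solution

    e(ψ) = ψ (1 − e^(−Z))                                  ψ < G/Z
    e(ψ) = ψ − (G/Z) e^(Z(h_k − 1))                        G/Z ≤ ψ < ψ_k
    e(ψ) = 1 − (1/Y) ln{1 + (e^Y − 1) e^(Y(G/Z−ψ)) (1−G)}  ψ ≥ ψ_k

where Z and Y are the external and internal transfer groups built from
k_f·a₀ and k_s·a₀ (1/s). `fit_bic()` estimates (G, k_s a₀, k_f a₀) from a
cumulative curve by multistart Levenberg–Marquardt least squares, with a
correlation-based variant that holds k_f a₀ at a Sherwood-correlation
value.

**Transport.** Sh = c₀·Re^c₁·Sc^(1/3) calibration in log space
(`fit_sherwood()`, c₁ confined to [0.5, 0.8]), conversions between Sh, k_f
and D_AB, and a Catchpole–King-type dense-gas diffusivity estimate for the
α-pinene/CO₂ pair.

**Design analysis.** OLS of yield on three coded factors and their two-way
interactions (`fit_rsm()`), Y_D = a₀ + a₁x₁ + … + a₂₃x₂x₃, with t tests on
3 df, leave-one-out predicted R², significance-based model reduction,
design-column correlation structure and Fedorov-exchange D-optimal subset
selection.

**Economics.** Fixed-multiplier annualised cost of manufacturing,
COM = 0.340·FCI + 2.73·C_OL + 1.23·(C_UT + C_WT + C_RM), over a vessel-cost
table, a batch schedule and solvent-cycle energies (`cost_scenario()`,
`cost_breakdown()`, `com_matrix()`).

## Worked example

Fit the kinetic model to a synthetic reconstruction of experiment 2
(220 bar, 220 µm, 0.602 kg CO₂/h) with 1 % weighing noise, then refit the
yield design and cost the 0.1 m³ plant:

```r
library(sovex)
kin   <- lentiscus_kinetics()
truth <- bic_parameters(kin$G[2], kin$ksa0[2], kin$kfa0[2])
curve <- gen_curve(curve_gen_spec(lentiscus_system(2), truth,
                                  noise_sigma = 0.01, seed = 42))
fit_bic(curve)
#> BIC model fit (fitted_kf), 16 observations
#> BIC parameters: G = 0.6354, ksa0 = 7.172e-05 1/s, kfa0 = 0.001738 1/s
#>   R^2 = 0.99882, RMSE = 6.158e-07 kg
```

The generating truth was G = 0.61, k_s a₀ = 7.01e-05, k_f a₀ = 1.72e-03:
at 1 % noise all three parameters come back within a few percent, and the
fit explains 99.9 % of the curve (RMSE is in kg of extract, here ≈ 0.6 mg).

```r
rsm <- fit_rsm(lentiscus_design())
rsm
#> Factorial yield model, 10 runs
#>        estimate          se       t        p
#> a0   0.18283308  0.01471250 12.4271 0.001123 **
#> a1   0.08431743  0.02270062  3.7143 0.033940 *
#> a2   0.00012986  0.01755809  0.0074 0.994563
#> a3  -0.00198440  0.01938029 -0.1024 0.924905
#> a12 -0.01338351  0.01674200 -0.7994 0.482500
#> a13  0.01667400  0.02357026  0.7074 0.530310
#> a23  0.01937524  0.02241876  0.8642 0.451024
#> R^2 = 0.9116 (91.2% of yield variability), predicted R^2 = -40.5729
reduce_model(rsm)$equation
#> [1] "YD = 0.183 + 0.084*x1"
```

Pressure (x₁, +0.084 % yield per coded unit) is the only significant
factor at α = 0.05; the reduced model is the intercept plus the pressure
effect.

```r
cost_breakdown(cost_scenario(vessel_volume = 0.1, yield_pct = 0.3))
#> Annual cost of manufacturing
#>   0.340 FCI : 290,351.50 USD/yr
#>   2.73 C_OL : 96,681.31 USD/yr
#>   1.23 C_UT : 49,468.11 USD/yr
#>   1.23 C_RM : 397,801.79 USD/yr
#>   COM       : 834,302.71 USD/yr
#>   extract   : 710.4 kg/yr -> 1,174.41 USD/kg
```

At a 0.3 % yield the 0.1 m³ plant produces 710 kg of extract per year at
about 1174 USD/kg, dominated by raw material (the leaves) and capital;
doubling the yield exactly halves the cost per kg.

`run_pipeline()` chains all stages (synthesise curves → kinetic fits →
Sherwood calibration → design analysis → cost matrix) and writes a JSON/CSV
report bundle; see the methods vignette
(`vignettes/extraction-modelling.Rmd`) for the model assumptions,
conventions and limitations.

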