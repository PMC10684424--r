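# fraxforge

Tools for synthesising a country-specific, FRAX-style 10-year
fracture-probability model from sentinel-city hip-fracture registry data,
and for comparing an original and an updated model over exhaustive
clinical-scenario grids. It is aimed at epidemiologists and biostatisticians
who maintain national fracture-risk calculators: people who need to turn a
handful of city registries, a life table and a set of risk-factor
coefficients into a runnable competing-risk model, and then quantify what a
revision does to absolute probabilities and to the rank order of patients.

## What it computes

The pipeline has four stages, each usable on its own:

1. **Incidence synthesis** — city counts are region-weighted into national
   rates per 100,000 person-years, then smoothed per sex by a continuous
   piecewise log-linear regression of rate on age,
   `log λ(a) = β₀ + β₁a + Σₖ γₖ(a − κₖ)₊`, with fixed knots (defaults: 62
   and 87 years for men, 62 and 82 for women). National burden is
   `Σ λ/10⁵ × population`; non-hip major-osteoporotic-fracture (MOF) rates
   are imputed via age/sex-specific site:hip ratios.
2. **Hazard calibration** — per sex and integer age, baseline hazards are
   the observed population hazards divided by the population-mean relative
   risk `Πc (1 − pc + pc e^βc) · E[g^(−T)]`, so the population average of
   individual hazards reproduces the input incidence and mortality exactly
   while preserving the relative importance of the coefficients.
3. **Competing-risk probability** — the 10-year probability of hip or MOF
   for a profile is `P = Σₜ S(t) · h_f/(h_f+h_d) · (1 − e^−(h_f+h_d))` with
   year-constant hazards, fracture as the first-event outcome and death as
   the competing risk; a monthly micro-simulation (`simulate()`) provides
   an independent stochastic check.
4. **Model comparison** — for each age (50/60/70/80), sex and outcome the
   two models are evaluated on all 2⁶ risk-factor combinations × 8
   T-scores (512 scenarios), and the report gives Pearson/Spearman
   correlations, a two-segment regression with a knot at 30 percentage
   points, and the updated model's value at the original model's median
   with a 95% empirical tolerance interval.

A synthetic-data module generates every input (registry counts, demography,
life tables, site:hip ratio tables, risk-factor coefficient sets) with
known ground truth, so the full chain runs and is tested without any
external data.

## Worked example

```r
library(fraxforge)
pipe <- run_pipeline(pipeline_config(seed = 1))
print(pipe)
```

```
End-to-end fracture-probability pipeline (seed 1)

Estimated annual fractures: 60,692, of which 18,611 (31%) in men and 42,082 in women

10-year probability (%) at the median of the original model's distribution,
with 95% tolerance intervals for the updated model

MOF
  male
    age 50  original   3.1  update   1.7 ( 1.7- 1.8)  r 1.000
    age 60  original   4.5  update   2.5 ( 2.4- 2.6)  r 1.000
    age 70  original   5.6  update   3.2 ( 3.1- 3.3)  r 0.999
    age 80  original   5.8  update   3.3 ( 3.2- 3.5)  r 0.999
  female
    age 50  original   6.6  update   3.7 ( 3.6- 4.0)  r 0.999
    age 60  original   9.1  update   5.2 ( 5.1- 5.5)  r 0.998
    age 70  original  10.1  update   5.8 ( 5.7- 6.2)  r 0.998
    age 80  original   9.9  update   5.7 ( 5.5- 6.1)  r 0.999
HIP
  male
    age 50  original   0.8  update   0.5 ( 0.5- 0.5)  r 1.000
    ...
```

The burden line is the expected annual number of hip fractures implied by
the synthetic national incidence and demography. Each comparison row reads:
at that age/sex, half the scenarios of the original model fall below the
"original" value; the "update" value is the updated model's probability at
that median (here the update was calibrated to incidence scaled by 0.55,
so medians drop by roughly 45%), with the tolerance interval describing the
scatter of updated-model values around the regression at that point; `r` is
the Pearson correlation across the 512 scenarios — near 1, meaning the
revision shifts absolute risk but barely reorders patients.

Individual predictions work from a profile:

```r
m <- pipe$model_original
p <- risk_profile(age = 70, sex = "female", crfs = "prior_fracture",
                  tscore = -2.5)
ten_year_probability(m, p, "hip")   # 0.0208 -> 2.1%
```

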