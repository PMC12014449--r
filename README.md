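# fluorisk

Health-risk assessment for dietary fluoride in foods roasted over
high-fluoride coal.

In coal-burning fluorosis regions, staple foods (corn, chili, pork, tofu)
roasted over high-fluoride briquettes accumulate fluoride over roasting
time. fluorisk is for exposure scientists who need to turn three kinds of
field data — replicate food fluoride concentrations by roasting stage,
Caco-2 transwell transport assays, and dietary intake surveys — into
quantitative risk statements: hazard quotients and indices, probabilistic
risk distributions, and maximum allowable daily intakes with and without a
bioavailability correction.

## The model

Relative bioavailability from apical depletion in a transwell assay:

    RBA = (C_IV − C_AV) · V_IV / (T_S · M_S)

EPA-style chronic non-carcinogenic risk:

    ADD = C · IR · EF · ED / (BW · AT),   HQ = ADD / RfD,   HI = Σ_foods HQ

Maximum allowable intake, inverting the model at a target HQ (default 1),
with `C_eff = C` or `C · RBA` for the bioavailability-corrected limit:

    IR_Max = HQ_target · RfD · BW · AT / (C_eff · EF · ED)

For probabilistic assessment, survey intakes are fitted by maximum
likelihood against five candidate families (normal, lognormal, logistic,
Gumbel-max, Weibull), ranked by the Anderson-Darling statistic A²; stage
concentrations (n = 3 replicates) are modelled as normal. A seeded Monte
Carlo (default 10,000 iterations, inverse-CDF sampling, independent
substreams per scenario) propagates both through the HQ model and reports
mean, 5th/95th percentiles and Pr(HQ > 1).

## Worked example

```r
library(fluorisk)

## peak-roast corn, children: hazard quotient from the built-in survey constants
p <- population_parameters("children", "corn")
point_hq(308.24, p)
#> [1] 1.983526
#> attr(,"at_risk")
#> [1] TRUE

## maximum allowable intake of peak-roast chili, children (kg/d)
ir_max(869.82, population_parameters("children", "chili"))
#> [1] 0.001786577

## the RBA-corrected limit at 11.3% bioavailability is 1/RBA higher
ir_max(869.82, population_parameters("children", "chili"), rba = 0.113)
#> [1] 0.01581041

## Monte Carlo: normal concentration x Gumbel-max intake
s <- scenario_spec("corn", 10, "children",
                   fitted_distribution("normal", c(location = 100, scale = 10)),
                   fitted_distribution("gumbel_max", c(location = 0.0177, scale = 0.004)),
                   p)
simulate_hq(s, simulation_config(seed = 1, n_iter = 10000))
#> <risk_summary> corn day 10 (children): mean 1.284 [p05 = 0.812, p95 = 1.934], Pr(>1) = 0.791 (n = 10000, seed 1)
```

A hazard quotient of 1.98 means the average daily dose is roughly twice
the fluoride reference dose (0.06 mg/kg/d): a potential health risk. The
intake limit of 0.0018 kg/d says that at peak accumulation, even a few
grams of roasted chili per day would push a child past HQ = 1; correcting
for the fraction actually absorbed relaxes that limit by 1/RBA.

## The analysis workflow

`analysis/01_simulate_data.R` … `analysis/06_irmax.R` run the whole study
shape on a synthetic bundle with known ground truth (84 concentration
records, inverted transport assays, 1000-person intake surveys per group),
writing summary tables under `results/`: bioavailability per stage, point
HQ/HI with contribution shares, distribution fits, Monte Carlo summaries
and intake limits. Each script is a thin driver over the package functions.

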