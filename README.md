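# cdtransfer

Threshold regression analysis of cadmium transfer from soil to wheat grain.

## The problem

Cadmium taken up by wheat from contaminated topsoil is a food-safety
concern, and the strength of soil-to-grain transfer — summarised by the
bioconcentration factor, BCF = Cd_grain / Cd_soil (both mg/kg dry weight) —
depends on soil conditions: pH, organic matter, phosphorus, calcium, zinc,
particle-size composition, and the speciation of Cd itself. Ordinary linear
regressions of log[BCF] on these factors force one slope across all soils,
but a factor can act differently on either side of a critical value of pH or
of total soil Cd. `cdtransfer` implements the two-regime threshold
regression used to detect and estimate such change points, together with the
descriptive layer of a paired soil–wheat survey, for analysts working on
trace-metal transfer in agricultural systems.

## The model

For sample *i* with response *y_i* (log₁₀ BCF), regressor *x_i* and
threshold variable *q_i* (soil pH or total soil Cd):

    y_i = β₁' x_i + ε_i   if q_i ≤ γ      (regime 1)
    y_i = β₂' x_i + ε_i   if q_i > γ      (regime 2)

* **Estimation** — concentrated least squares: for every admissible
  candidate γ (the distinct observed values of *q*, trimmed so each regime
  keeps at least `max(ceiling(0.15 n), p + 1)` observations), both regimes
  are fitted by OLS and γ̂ minimises the total SSR S(γ), ties going to the
  smallest candidate.
* **Inference on γ** — the likelihood-ratio sequence
  LR(γ) = n · (S(γ) − S(γ̂)) / σ̂², σ̂² = S(γ̂)/n, inverted at the
  asymptotic critical value c(α) = −2 ln(1 − √(1 − α)) (7.352 at α = 0.05)
  to give a confidence set for γ.
* **Existence of a threshold** — a residual bootstrap of the sup-F statistic
  n · (SSR_null − S(γ̂)) / σ̂² under the fitted single-regime null, with
  p = (1 + #{sup-F* ≥ observed}) / (B + 1).

Around the core the package provides summary statistics with coefficients
of variation, Pearson correlation tables with two-tailed significance
flags, Tessier speciation percentages (exchangeable, carbonate-bound,
Fe–Mn-oxide-bound, organic-bound, residual Cd), regulatory exceedance
screening (1 mg/kg soil, 0.1 mg/kg grain), and a seeded synthetic-survey
generator so the entire analysis is reproducible without access to raw
field data.

## Worked example

```r
library(cdtransfer)

d  <- generate_dataset(synthetic_config(n = 22, seed = 1))
sp <- threshold_spec("log_bcf", "ph", "ph")
fit_threshold(d, sp)
```

```
Two-regime threshold regression: log_bcf ~ ph | threshold on ph
  n = 22 (regime 1: 16, regime 2: 6), gamma_hat = 7.968
  regime 1 (q <= gamma): [-3.766, 0.3511], R2 = 0.219
  regime 2 (q >  gamma): [6.264, -0.8746], R2 = 0.781
  SSR = 0.220335 (null 0.493649), sup-F = 600.4
```

The generator plants a two-regime pH response with its threshold at
pH 7.98; at the survey scale of 22 samples the fit recovers the change
point at the observed pH value just below it (7.968), a positive slope in
the sub-threshold regime and a negative slope above — pH promotes Cd
accumulation in grain below the threshold and inhibits it above. The 95%
LR confidence set for γ from `gamma_ci(fit)` is [7.968, 8.047) and covers
the planted value; `bootstrap_test(d, sp, n_boot = 499, seed = 1)` gives
p ≈ 0.014, so a single-regime line is rejected.

## The analysis workflow

The `analysis/` scripts rerun the full study replica step by step, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R                  # synthetic 22-sample survey
Rscript analysis/02_descriptives.R              # summary stats, correlations,
                                                #   speciation, exceedance
Rscript analysis/03_threshold_models.R          # 9 factors x 2 threshold vars
Rscript analysis/04_operating_characteristics.R # recovery + bootstrap size MC
```

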