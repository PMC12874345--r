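# biogasbench

Mechanistic and machine-learning prediction of daily biogas and methane
production at a full-scale agricultural co-digestion plant.

## The problem

Agricultural biogas plants co-digest livestock slurry with crop residues
(maize and grass silage, deep litter, straw, ...). Feedstock quality and
availability vary through the year, so operators need models that predict
daily biogas (m³ d⁻¹) and methane production from routine records. Two very
different model families compete for this job:

* **mechanistic digestion models**, which simulate the biochemistry of the
  reactor but need proximate feedstock characterisation, and
* **data-driven regressors** (random forests, LSTM networks), which need
  only the daily feeding records.

`biogasbench` implements both families behind one benchmark: a simplified
mechanistic digester, the two machine-learning baselines, the shared
evaluation stack (Nash–Sutcliffe efficiency at daily and weekly resolution,
Pearson correlation structure, Shapley feature attribution, computational
profiling), and a synthetic plant-campaign generator so the whole pipeline
is testable without any plant data.

## The models

**Digester.** A continuously stirred tank reactor (volume *V*, hydraulic
retention time HRT, dilution rate *D* = 1/HRT). Each fed substrate is
fractionated by proximate (Weender) analysis — crude ash XA, carbohydrates
XC, protein XP, lipid XL (g per kg TS) — into degradable particulate influent
loads *X*<sub>ch</sub>, *X*<sub>pr</sub>, *X*<sub>li</sub> (kg d⁻¹), using
TS, VS and a carbohydrate degradability resolved from DQ<sub>XC</sub>, ADL
or crude fibre. Hydrolysis is the rate-limiting step and is first order:

  d*X*<sub>j</sub>/dt = *D*(*X*<sub>j,in</sub> − *X*<sub>j</sub>) −
  *k*<sub>j</sub>*X*<sub>j</sub>,  j ∈ {ch, pr, li}

Hydrolysed mass converts to CH₄/CO₂ with Buswell stoichiometry
(C₆H₁₀O₅, C₅H₇O₂N, C₅₇H₁₀₄O₆ defaults; gas at 273.15 K, 1.013 bar). The
three rate constants *k*<sub>ch</sub>, *k*<sub>pr</sub>, *k*<sub>li</sub>
(d⁻¹) are the only calibrated parameters: they minimise the RMSE between
simulated and observed daily biogas, bounded in [0.001, 10] d⁻¹
(box-constrained Levenberg–Marquardt, multi-start). An optional Monod
acetoclastic-methanogenesis extension adds a soluble pool and methanogen
biomass.

**Baselines.** A random forest (500 trees, depth 10, ≥15 samples to split,
≥2 per leaf, √p feature subsampling) and a single-layer LSTM (128 units,
dropout 0.1, Adam, batch 16, 50 epochs, 7-day input windows, min–max
scaling) regress daily production on four feature sets: feedstock
quantities (t d⁻¹); + organic loading rate (OLR, kg VS m⁻³ d⁻¹); + maize
VS flow (t VS d⁻¹); or feedstocks + summed ADM1 inputs (kg d⁻¹).

**Evaluation.** NSE = 1 − Σ(xᵢ−yᵢ)²/Σ(xᵢ−x̄)², computed daily and on weekly
(7-day block) sums; RMSE; exact (2ᵖ-enumeration) or permutation-sampled
Shapley values with normalised mean-|SHAP| shares; wall-clock and
resident-memory profiling of training vs testing.

## Worked example

```r
library(biogasbench)

cfg <- campaign_config(seed = 1)      # two-year synthetic plant campaign
ds  <- generate_plant_dataset(cfg)
ds
#> Plant dataset: 730 days, 8 feedstocks
#>   observed biogas: mean 4332.0 m3/d
#>   synthetic (ground truth attached)

fit <- adm_model(ds, config = cfg$digester, seed = 1)   # calibrates on year 1
summary(fit)
#> Mechanistic digester model summary
#>   k_ch = 0.2411, k_pr = 0.3711, k_li = 0.1017 (1/d)
#>   train: NSE daily 0.951, weekly 0.991, RMSE 259.0 m3/d
#>   test: NSE daily 0.981, weekly 0.997, RMSE 226.6 m3/d

fm <- build_feature_set(ds, combo_id = "feedstocks", target = "biogas")
sp <- chronological_split(fm)                    # 2023 train / 2024 test
rf <- fit_random_forest(sp$train, seed = 1)
ev <- evaluate_series(sp$test$.target, predict(rf, sp$test))
#> RF (feedstock inputs): test NSE daily 0.12, weekly 0.13, RMSE 1540 m3/d
```

The campaign is generated with true rates (0.25, 0.23, 0.12) d⁻¹ and 5 %
multiplicative metering noise. Calibration recovers the carbohydrate rate
well (0.24 vs 0.25); the protein and lipid rates sit in a flat objective
valley (their loads are nearly proportional across these feedstocks), which
is why the simulated gas still scores NSE ≈ 0.98 — see the methods vignette
for the identifiability discussion. Weekly NSE exceeds daily NSE for every
model because 7-day sums average out independent daily metering noise.

The full benchmark — calibration, both ML families on all four feature
sets, Shapley shares, correlation matrix and profiling, written as CSV
artifacts — is one call:

```r
res <- run_pipeline(seed = 1, out_dir = "bench-out")
res$comparison        # 9 rows: mechanistic model + 2 families x 4 combos
```

A thin CLI wraps the same functions:
`Rscript inst/cli/biogas-bench.R run --seed 1 --out bench-out`.

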