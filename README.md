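# dendrocycle

Analysis of **automated dendrometer band (ADB)** time series for forest
ecophysiology: from raw 15-minute band-logger records to quality-controlled
series, growth/water-signal decomposition, wavelet-based classification of
diurnal stem shrinkage vs. swelling, and mixed-effects models of what drives
daily amplitudes and how stems respond to rain.

ADBs record stem circumference (via a potentiometer on a tensioned steel
band) and band temperature every 15 minutes. The signal superimposes slow
growth, a reversible diurnal shrink/swell cycle driven by transpiration and
stem water storage, transient expansion after rain, and instrument
artifacts. `dendrocycle` separates these components and quantifies them.

## The method in brief

For each tree, circumference change Δc (mm, relative to the first usable
sample) is decomposed with a cubic smoothing spline S whose effective
degrees of freedom equal the number of days in the window:

- daily increment `I_i = S(midnight_{i+1}) − S(midnight_i)` (growth + day-scale hydration),
- residual `Δc_r = Δc − S` (the diurnal cycle),
- daily amplitude `A = max(Δc_r) − min(Δc_r)` per calendar day.

Each tree's `Δc_r` is compared against the site-ensemble band temperature by
Morlet wavelet coherence (ω₀ = 6). At the scale whose Fourier period is
nearest 24 h, the phase angle θ of coherent samples (coherence > 0.7,
rain-free days, outside the cone of influence) measures the
temperature–circumference lag: π/2 < θ < 3π/2 indicates daytime **shrinkage**
(antiphase with temperature), otherwise in-phase **swelling**. Trees are
classified *shrinking* / *swelling* when more than 75% of their classified
days agree, else *no dominant pattern*.

Daily amplitudes of shrinking trees are regressed on scaled daily drivers
(band-temperature range, mean VPD, radiation sum, sap-flux or ET sum) with
`lme4` mixed models — random intercepts and slopes by tree — and
likelihood-ratio tests against a null without the fixed slope. The rain
response is the rainy-minus-rain-free difference in `I` from
`I ~ rain + (1 + rain | tree)`, optionally with bark-thickness and
irrigation covariates.

Before any of that, records pass a three-stage screen: manual-caliper
discrepancy (> 4 mm between visits), jump days (> 0.5 mm position change
within an hour masks the day), and isolated spikes (rolling-median/MAD
rule). Trees retaining < 50% of samples are excluded.

Because the original field records are not distributed, the package ships a
**synthetic cohort generator** (weather with Markov rain, per-tree signal
model `p0 + growth + diurnal + rain pulse + noise`, scheduled faults) with
full ground truth, and every stage is verified by parameter recovery against
it. See the vignette (`vignettes/dendrometer-band-analysis.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(dendrocycle)

cohort <- generate_cohort(n_trees = 12, n_days = 30, seed = 7)   # synthetic inputs
cfg <- default_config(
  start = as.character(cohort$start_date),
  end   = as.character(cohort$end_date),
  paths = list(out_dir = "run_out"), seed = 7)
res <- run_pipeline(cfg, cohort = cohort)

res$phase_summary[, c("tree_id", "tree_class", "theta_mean", "frac_days_coherent")]
#>    tree_id tree_class theta_mean frac_days_coherent
#> 1      T02  shrinking       2.89              0.944
#> 2      T03  shrinking       2.87              1.000
#> ...
#> 7      T08   swelling       6.04              1.000
#> 11     T12   swelling       6.02              0.050

res$table5[, c("category", "n_obs", "n_trees", "p", "rain_effect", "rain_effect_sd")]
#>   category n_obs n_trees        p rain_effect rain_effect_sd
#> 1     live   300      10 5.56e-05      0.0583         0.0127
```

Reading this: ten usable live trees (one tree lost to a scheduled sensor
drift masking >50% of its record), mean phase angles near π for hydraulic
shrinkers and near 0 (≡ 2π) for in-phase swellers, and a rain response of
+0.058 ± 0.013 mm on the daily increment (LRT p ≈ 6e-5) against a generator
truth of ~0.06–0.10 mm across trees. One run writes `qc_report.csv`,
per-sample and per-day decomposition tables, `phase_summary.csv`, the
driver-model and rain-model tables and a `manifest.json` into `out_dir`.

A thin CLI wrapper is included:

```sh
Rscript inst/cli/dendrocycle.R synth --n-trees 30 --days 62 --seed 42 --out cohort_dir
Rscript inst/cli/dendrocycle.R run --config run.yaml
```

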