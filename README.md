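# ureanox

Quantifying how much marine nitrification — and its nitrous oxide (N2O)
by-product — is fuelled by ammonium versus urea.

Ammonia-oxidising archaea, the dominant marine nitrifiers, can oxidise
nitrogen from both ammonium and urea. Field studies measure the two
contributions with parallel ¹⁵N-tracer incubations, then ask where urea
matters: the answer turns out to track the *ratio* of the two substrate
concentrations, not either concentration alone. `ureanox` implements that
entire analysis chain as a tested R package, for biogeochemists working
with ¹⁵N incubation time courses, cross-site rate compilations, or
functional-gene (metagenomic coverage) tables.

## What it computes

**Gross rates from tracer incubations.** After adding a ⁹⁹%-¹⁵N tracer to
a pool with labelled fraction

```
F = (C_a f_a + C_t f_t) / (C_a + C_t),
```

nitrite production is the ¹⁵NO₂⁻ accumulation slope corrected for tracer
dilution, `rate = (d¹⁵NO₂⁻/dt) / F`. N2O production inverts the binomial
isotopologue model — mass 44/45/46 fractions `(1−F)², 2F(1−F), F²` — via
the ¹⁵N-atom excess slope: `R = (slope₄₅ + 2·slope₄₆) / (2F)`. Both come
with regression SEs, design-based detection limits
(`t₁₋α,df · SE₀(slope) / F`, with `2F` for N2O), and below-detection
flags.

**Derived statistics.** N2O yield `100·R_N2O/(R_N2O + R_NO2)` on a
nitrogen-atom basis, error-propagated urea:ammonium rate ratios, substrate
fractions, and Welch t-tests for substrate-manipulation treatments.

**Cross-site framework.** OLS and robust (Huber, c = 1.345) log-log fits
of oxidation-rate ratios on substrate concentration ratios, 2-SD residual
outlier flagging (which isolates the anomalous polar-ocean regime),
habitat subgroup fits, and prediction of rate ratios from concentration
ratios.

**ureC:amoA gene metric.** Depth-normalised gene coverage (per million
reads), per-sample ureC:amoA ratios for AOA, region medians, and the
linear fits of gene ratios against substrate and rate ratios.

**Synthetic data.** Seeded generators for every input table, emulating the
incubation design (0/4/8/12 h, duplicate bottles, tracer at ~10% of the
pool), measurement noise, ammonium inhibition of urea oxidation, the
global power-law coupling, the polar outlier regime, and Poisson-sampled
gene coverage — so the full pipeline is testable without any downloads.

## Worked example

```r
library(ureanox)

cfg <- sim_config(seed = 1)                               # study conditions
tc  <- simulate_incubation(cfg, "urea", station = "CB2", depth_m = 9.9)

nitrite <- nitrite_production_rate(tc)
n2o     <- n2o_production_rate(tc)
nitrite
#> <rate_estimate> nitrite from urea: 2.021 +/- 0.08162 nmol N/L/d (DL 0.159)
n2o
#> <rate_estimate> n2o from urea: 0.002306 +/- 0.0004962 nmol N2O/L/d (DL 0.000964)
yield_from_estimates(n2o, nitrite)
#> <yield_estimate> 0.228 +/- 0.05 %
```

The simulated incubation was generated at a true urea-oxidation rate of
2 nmol N L⁻¹ d⁻¹ and an N2O rate of 0.002 nmol N2O L⁻¹ d⁻¹; the estimates
recover both within their standard errors, and the N2O yield (~0.2% of
oxidised N on the atom basis) is well above the design detection limit.

```r
sites <- simulate_global_dataset(cfg, 300)
fit <- loglog_fit(sites)
#> 1 record(s) excluded from the ratio fit (missing, zero or below-detection rates)
fit
#> <regression_fit> ols: y = 1.039 x + -0.9219 (n = 299, r2 = 0.759, p = 1.08e-93)
#>   16 point(s) flagged beyond the residual threshold
predict_rate_ratio(fit, 1)
#> [1] 0.1196909
fraction_preferring_ammonium(sites)
#> [1] 0.9
```

The fitted slope and intercept recover the generator's power law
(`log10 y = 1.113·log10 x − 0.97`) within uncertainty: even where urea-N
equals ammonium (ratio 1), urea oxidation runs at ~12% of ammonium
oxidation, and 90% of the synthetic sites oxidise ammonium faster — the
ammonium preference seen across real compilations.

A thin CLI over the same functions ships in `inst/scripts/ureanox`
(subcommands `simulate`, `rates`, `yields`, `regress`, `generatio`). The
methods vignette (`vignettes/tracer-rates.Rmd`) documents the model
assumptions, noise calibrations, generator design and limitations.

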