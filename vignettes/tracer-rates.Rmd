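---
title: "Estimating nitrification and N2O production from ammonium and urea with 15N tracers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nitrification and N2O production from ammonium and urea with 15N tracers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ureanox)
```

## The measurement model

Marine nitrification — the microbial oxidation of ammonia to nitrite and
nitrate — is the dominant source of oceanic nitrous oxide. Ammonia-oxidising
archaea (AOA), the most abundant marine nitrifiers, can also oxidise
urea-derived nitrogen, so both ammonium and urea fuel nitrite and N2O
production. This package implements the quantitative chain that turns
15N-tracer incubations and compiled field data into gross rates and
comparative statistics for the two substrates.

### Labelled fraction

A tracer experiment adds a small amount of highly enriched substrate
(`tracer_atom_frac15`, default 0.99) to the ambient pool at natural
abundance (0.003663). The labelled fraction of the combined pool is the
concentration-weighted mean

$$F = \frac{C_a f_a + C_t f_t}{C_a + C_t},$$

computed by `label_fraction()`. Urea concentrations are handled in nitrogen
units throughout (`urea_to_N()`, two N atoms per molecule). `F` is treated
as constant over the short (at most 12 h) incubation; substrate turnover
that dilutes the pool within the incubation is a documented non-goal.

### Nitrite production

Bottles are sacrificed at successive times (default design 0, 4, 8, 12 h in
duplicate) and the 15N-nitrite concentration is regressed on time, pooling
all bottles as independent observations (`fit_time_course()`; slopes are per
day). The gross rate corrects the slope for tracer dilution:

$$\text{rate} = \frac{1}{F}\,\frac{d\,{}^{15}\mathrm{NO}_2^-}{dt}.$$

Dividing by `F` is deliberate: only a fraction `F` of substrate molecules
carries the label, so the labelled-product slope underestimates the gross
rate by exactly that factor. Multiplying by `F` would be dimensionally
inconsistent with tracer dilution, and the correction direction is exposed
in the code rather than buried, so it can be audited.

### N2O production and the binomial isotopologue model

N2O carries two nitrogen atoms. Under production from a single labelled
pool, each atom is 15N with probability `F` independently, so the mass
44/45/46 isotopologue fractions are binomial,
$(1-F)^2,\; 2F(1-F),\; F^2$ (`isotopologue_fractions()`). The 15N-atom
excess series $E = [{}^{45}\mathrm{N_2O}] + 2\,[{}^{46}\mathrm{N_2O}]$ then
accumulates at $2F R$ for gross rate $R$, giving the exact inversion

$$R = \frac{\text{slope}_{45} + 2\,\text{slope}_{46}}{2F}$$

implemented by `excess_to_n2o_rate()` and used by `n2o_production_rate()`.
The inversion is an algebraic identity for every `F` in (0, 1], which the
test suite verifies both analytically and against a per-molecule
Monte-Carlo atom-labelling simulation. Two modelling assumptions are worth
stating: both atoms come from the traced pool (no hybrid molecules formed
with ambient nitrite — consistent with the similar yields observed for the
two substrates), and mass-45 interference from 17O is not corrected (the
upstream instrument workflow is out of scope).

Atom-excess inversion was chosen over regressing the summed 45+46 molecule
concentrations; the two differ by a factor $(2-F)/2$ and only the
atom-excess form inverts the binomial model exactly.

### Detection limits

`rate_detection_limit()` converts the incubation design and a measurement
noise SD into the smallest rate distinguishable from zero: the one-sided
$t_{1-\alpha,\,n-2}$ quantile times the OLS slope SE under pure noise,
divided by `F` (nitrite) or `2F` (N2O). With the default design, `F` = 0.2
and a 15N-nitrite noise of 0.005 nmol N L^-1, the nitrite DL is about 0.09
nmol N L^-1 d^-1; an N2O excess-series noise of 5e-5 nM puts the N2O DL
near 1e-3 nmol N2O L^-1 d^-1. Negative fitted slopes are retained, not
truncated, and flagged `below_detection`; truncation would bias the
downstream ratio statistics. When no external noise estimate is available,
`nitrite_production_rate()` and `n2o_production_rate()` use the fitted
residual slope SE, which makes the per-incubation DL self-contained.

## Derived statistics

The N2O yield is the percentage of oxidised N emitted as N2O,
$100\, R_{\mathrm{N_2O}} / (R_{\mathrm{N_2O}} + R_{\mathrm{NO_2^-}})$. The
two inputs have different natural units (nmol N2O vs nmol N), and the
source formulation leaves the basis unstated; `yield_from_estimates()`
defaults to the nitrogen-atom basis (N2O rate doubled), which makes the
yield a true fraction of oxidised nitrogen, with `basis = "molecule"`
available for comparison. Yield and ratio uncertainties use first-order
(delta-method) propagation; `rate_ratio()` carries below-detection flags
through, and the propagated sigma is validated against large Monte-Carlo
draws (it is accurate to a few percent for relative errors up to ~10%,
degrading as the denominator CV grows). Treatment effects
(`compare_treatments()`) use a Welch t-test on the two slope estimates with
their regression SEs, with percent change expressed relative to the
untreated estimate.

## The cross-site correlation framework

Across marine environments, the ratio of urea to ammonium oxidation rates
rises with the ratio of the substrate concentrations. `loglog_fit()`
estimates the power law on log10 scales by OLS over "ratio-eligible"
records: both concentrations and both rates positive and neither rate
below detection. Below-detection rates are excluded rather than substituted
at half the DL — substitution policies distort log-scale fits and the
eligible-pair fit matches how the compiled field datasets are analysed.

`robust_loglog_fit()` fits the same relation with Huber IRLS (tuning
constant 1.345, via `MASS::rlm`) and flags points whose residuals exceed
`sd_threshold` (default 2) robust residual SDs. On clean Gaussian data this
flags about $2\Phi(-2) \approx 4.6\%$ of points; coherent high-ratio
clusters at low substrate ratios — the polar-ocean regime — are flagged at
high but not perfect sensitivity, because a cluster of outliers in one
predictor region partially attracts even a robust line. A Theil–Sen
estimator is available (`method = "theil_sen"`) since "robust regression"
is not otherwise pinned down. The robust fit's p-value is the asymptotic
t-type p from the IRLS slope SE, matching the reporting style of the OLS
fit. Whether the global fit should exclude the polar records first is left
to the caller: both variants are computable (`subgroup_fit()` drops
habitats; the default fit keeps everything eligible).

`predict_rate_ratio()` back-transforms a fit to predict rate ratios from
concentration ratios, and `fraction_preferring_ammonium()` reports the
fraction of observations with higher ammonium than urea oxidation (ties
count as not-higher).

## The ureC:amoA gene-coverage metric

The urease gene *ureC* marks the capability to hydrolyse urea; *amoA* marks
ammonia oxidizers. From a per-gene coverage table (the documented boundary
of this module — assembly, annotation and taxonomy are upstream tools, not
reimplemented here), `normalize_coverage()` divides per-nucleotide mean
coverage by library size in millions of reads; no gene-length correction
is needed because per-nucleotide coverage is already length-free.
`urec_amoa_ratio()` sums normalised coverage across gene hits (sums, not
means: summed coverage approximates total gene copies across variants) and
forms ureC/amoA for one taxon group (default AOA). A sample with amoA but
no ureC has a genuine ratio of zero; a sample without amoA coverage has an
*undefined* ratio and is reported missing, never zero or infinite.
`region_summary()` gives per-region medians and quartiles, and the two
linear fits (`ratio_vs_substrate_fit()`, `ratio_vs_rate_ratio_fit()`) are
on the linear scale, matching how such gene-ratio relations are reported.

## What the synthetic-data generators emulate

`sim_config()` fixes the study conditions; all generators are deterministic
functions of the configuration seed, with per-call substreams derived by
hashing a tag, so regenerating any one object never perturbs another.

* **Incubations** (`simulate_incubation()`): four time points, duplicate
  bottles; tracer sized by `tracer_conc_for_F()` to hit target labelled
  fractions of 0.10 (within the observed field ranges of 0.085–0.372 for
  ammonium and 0.061–0.180 for urea); 15N-nitrite accumulating at
  `rate * F * t` over the natural-abundance baseline of a 2 umol N L^-1
  ambient nitrite pool; N2O isotopologues accumulating binomially over a
  10 nM ambient N2O pool. Noise is Gaussian on concentrations: 0.33 nM on
  total N2O (the concentration measurement precision), 5e-5 nM on the
  45/46 excess series and 0.005 nmol N L^-1 on 15N-nitrite. The latter two
  reflect isotope-ratio rather than concentration precision and were
  calibrated so the design-based detection limits land at the order of
  magnitude reported for such measurements (~1e-3 nmol N2O L^-1 d^-1 and
  ~0.1 nmol N L^-1 d^-1); they are calibrations, not instrument ground
  truth. Measured values are censored at zero, which is why the baselines
  matter: at the default settings censoring is negligible, but a
  user-supplied configuration with large noise and a small baseline will
  bias slopes near zero. Default true rates (nitrite 50 and 2
  nmol N L^-1 d^-1, N2O 0.04 and 0.002 nmol N2O L^-1 d^-1 for ammonium and
  urea) sit at the scale of productive estuarine waters and imply N2O
  yields near 0.16% and 0.19%.
* **Manipulations** (`simulate_manipulation()`): +2 umol L^-1 ammonium or
  +18 umol N L^-1 urea; ammonium amendment multiplies the true
  urea-oxidation rates by `inhibition_factor` (default 0.4, the middle of
  the observed 52–73% inhibition range); urea amendment leaves ammonium
  oxidation unchanged. By default the tracer is re-sized to the amended
  pool (the field protocol); `rescale_tracer = FALSE` keeps the unamended
  tracer mass so the labelled fraction drops as the pool grows.
* **Cross-site compilations** (`simulate_global_dataset()`):
  habitat-structured lognormal concentrations spanning eutrophic estuaries
  (ammonium ~2 umol L^-1) to oligotrophic gyres (~0.05 umol L^-1), rate
  ratios coupled to substrate ratios through the power law
  `log10 y = 1.113 log10 x - 0.97` with 0.3 log10 scatter, absolute
  ammonium-oxidation rates scaled to ammonium concentration, and a polar
  outlier regime (5% of sites, +1.0 log10 intercept shift at low substrate
  ratios). The ammonium-preference fraction is a *derived* property of
  these choices, not a dial; under the defaults it comes out near 0.9,
  somewhat higher than typical field compilations report, because the
  synthetic habitat mix is thinner in high-urea-ratio deep-ocean samples.
* **Coverage tables** (`simulate_coverage_table()`): per-sample substrate
  ratios on (0.3, 8); true gene ratio `max(0, 0.083 x - 0.018)`; amoA
  abundance lognormal around 0.5 coverage per million reads; observed
  coverages Poisson around abundance x depth with library sizes of 10–100
  million reads. At low expected ureC counts the ratio estimator is
  noticeably biased upward (small-count division), which is a property of
  the real metric too.

What passing tests on these generators shows is that the estimators invert
the models they assume, at the noise scales stated above — not that real
incubations are linear, that real noise is Gaussian, or that real site
effects are absent. Features deliberately not emulated: Michaelis–Menten
substrate kinetics, oxygen co-limitation, time-varying labelled fractions,
isotope dilution from urea decomposition (observed as an artifact in
urea-amended field incubations), and mechanistic models of the polar
regime (represented as a plain intercept shift).

## Numerical choices and degenerate inputs

* Hours are converted to days inside the slope fits; all rates are per day.
* A slope needs two distinct times (error below that, warning below
  three); SEs and p-values require three points.
* `label_fraction()` errors on an empty pool; rate functions error at
  `F = 0` and warn below a configurable floor (`f_floor = 0.01`), where
  the 1/F correction amplifies noise explosively.
* A constant predictor in `loglog_fit()` returns the flat-line fit
  (slope 0, intercept at the mean response, `r2 = NA`); the linear
  gene-ratio fits treat a constant predictor as an error, since a constant
  gene ratio or substrate ratio cannot anchor those relations.
* Robust flagging adds a tiny scale-relative epsilon to the threshold so
  exact-fit data (robust scale zero) produce no flags.
* Outputs are written at full precision by `readr`, so seeded runs are
  byte-stable; readers validate headers verbatim and report offending
  rows.

## Problem sizes used in the shipped checks

The package's own verification uses 1,000 random (rate, F) pairs for the
inversion identity; a 5 x 4 x 500 grid of rates and labelled fractions for
coverage of the nitrite-rate CIs; 1e5 Monte-Carlo draws for ratio error
propagation; 300 sites for the scattered regression recovery and outlier
flagging (600 in the standalone script, where the flag-sensitivity value
is reported rather than thresholded); and 30–40-sample coverage tables.
These sizes make the stochastic checks reproducible and sharp at the
package's chosen tolerances.

## Worked example

```{r example}
cfg <- sim_config(seed = 1)
tc <- simulate_incubation(cfg, "urea", station = "CB2", depth_m = 9.9)
nitrite <- nitrite_production_rate(tc)
n2o <- n2o_production_rate(tc)
nitrite
n2o
yield_from_estimates(n2o, nitrite)
```

```{r crosssite}
sites <- simulate_global_dataset(cfg, 300)
fit <- loglog_fit(sites)
fit
predict_rate_ratio(fit, 1)
```

## Known limitations

Rates assume linear accumulation over the incubation; saturating time
courses are not modelled. The binomial inversion assumes a single labelled
source pool. Detection limits depend on a noise SD that real studies
estimate from instrument replicates; the self-contained variant uses the
fitted residual SE and is therefore itself noisy at n = 8. The robust
outlier flag is a screening device, not an inference: coherent outlier
clusters shift even robust fits, and flag sensitivity varies accordingly.
Gene-ratio estimates from low-coverage samples are biased upward by
small-count division; interpret ratios from expected ureC counts below ~5
with care.
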