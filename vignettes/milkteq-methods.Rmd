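---
title: "Methods: PCB exposure assessment in human milk with milkteq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCB exposure assessment in human milk with milkteq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkteq)
```

## The problem

Human milk is the standard matrix for biomonitoring persistent organochlorine
pollutants: it is non-invasive to collect, its lipid phase concentrates
lipophilic compounds, and it directly measures the infant's dietary exposure.
`milkteq` implements the analysis chain such a monitoring study needs:

1. congener-level concentration handling (basis, units, censoring),
2. toxic-equivalent (TEQ) computation over the dioxin-like congeners,
3. stage-wise statistics across lactation,
4. constrained ordination of congener profiles on maternal covariates,
5. infant intake estimation and regulatory screening, and
6. a seeded synthetic cohort generator so the entire chain is testable
   without access to any confidential mother/milk records.

## Congener registry and TEQ model

The registry tracks 18 PCB congeners by IUPAC number: the four non-ortho
dioxin-like congeners (77, 81, 126, 169), the eight mono-ortho dioxin-like
congeners (105, 114, 118, 123, 156, 157, 167, 189), and the six
non-dioxin-like (ndl) indicator congeners (28, 52, 101, 138, 153, 180).
We deliberately use the *full* eight-congener mono-ortho set of the WHO TEF
framework: monitoring protocols sometimes quantify only a five-congener
subset, but TEF schemes and regulatory sums are defined over all eight, and
a registry that omitted 123, 167 and 189 could not score data that reports
them. PCB 135 and a "PCB 186" occasionally appear in monitoring reports as
transcription slips for 153/138 and 81/118 neighbourhoods; they are not
valid members of any of the three sets and the registry rejects them.

The toxic equivalent of a sample is the TEF-weighted sum

$$\mathrm{TEQ} = \sum_i c_i \cdot \mathrm{TEF}_i$$

over the 12 dioxin-like congeners, in pg-TEQ per gram. The default
`tef_scheme("who2005")` carries the WHO 2005 factors
(77 → 0.0001, 81 → 0.0003, 126 → 0.1, 169 → 0.03, all mono-ortho → 0.00003).
Schemes are data, not code: a named numeric vector defines an alternative
(e.g. the 1998 factors) without touching the engine.

### Bases, units and censoring

Concentrations live on two bases — per gram whole milk ("wet weight") and
per gram extracted milk fat ("lipid") — related through the sample's lipid
percentage: $c_\mathrm{lipid} = c_\mathrm{ww} / (\mathrm{lipid\%}/100)$.
All values are normalised to pg/g at ingestion (original units are
retained for output); a zero-lipid sample makes the conversion degenerate
and is rejected.

Left-censored values (below the limit of detection or quantification) are
carried as their applicable limit plus a censoring flag, and substituted at
computation time under one of three bound strategies: `lower` (0), `middle`
(limit/2) or `upper` (limit). All three are exposed because monitoring
reports frequently do not state which convention their sums used; the
package defaults are **upper** for regulatory compliance (the conservative
convention for limit checks) and **middle** for trend statistics. A
congener that is absent from a sample altogether has no limit to
substitute; it contributes 0 and, except under the lower bound, raises a
warning — there is no defensible nonzero substitute.

### LOD/LOQ from calibration curves

`fit_calibration()` is ordinary least squares of instrument response on
nominal concentration; `lod_loq()` implements the calibration-curve
convention LOD = 3.3·s/slope and LOQ = 10·s/slope, where *s* is the
standard error of the fitted intercept. "Standard deviation of the
intercept" is ambiguous between estimators; we use the OLS standard error,
which is the quantity every regression summary reports and the one the
3.3/10 multipliers were calibrated against. The LOQ/LOD ratio is
consequently 10/3.3 for every curve — a useful structural check.

## Lactation-stage statistics

The collection schedule has 17 stages: weekly in the first month
(`<7 days`, `7 days`, `14 days`, `21 days`, `28 days`), monthly through
month 12, and `>1 year of feeding`. A day is assigned to the most recent
completed scheduled point. Month boundaries are not universally defined, so
they are configurable; the default places the month-*m* point at
round(30.44·*m*) days and cuts to the final stage after day 366.

Stage summaries report mean, sample SD (n−1 denominator) and CV =
100·sd/mean. The grand "average content" row is the **unweighted** mean and
n−1 SD across the 17 stage means — not weighted by per-stage sample counts.
Both conventions were checked arithmetically against the packaged printed
stage table (`table2_fixture()`), which only the unweighted/n−1 pair
reproduces.

Pearson correlations come with a two-sided p from the t transform and a
Guilford strength label. The Guilford band edges are |r| < 0.2 negligible,
0.2–0.4 low, 0.4–0.7 moderate, 0.7–0.9 high, ≥ 0.9 very high, inclusive on
the lower edge — the mid-century convention the label "Guilford
classification" conventionally denotes.

`stage_group_tests()` bundles the standard battery: one-way ANOVA, Levene's
homogeneity test (the original mean-centred form), a per-group
Kolmogorov–Smirnov normality check, and Tukey's HSD at α = 0.05. The K–S
p-values are computed against a normal with parameters estimated from the
data, which makes them conservative (the Lilliefors correction is not
applied); they are labelled approximate in the output for that reason.

## Redundancy analysis

`rda_fit()` is written out in full rather than delegated: each response
column is centred (and scaled to unit variance under the default
correlation scaling), regressed on the centred explanatory design by least
squares, and the covariance matrix of the fitted values is eigendecomposed.
Site scores are projections of the fitted values on the eigenvectors,
species scores are eigenvectors scaled by √eigenvalue (the "scaling 2"
correlation-biplot convention, chosen because variable–variable angles are
then interpretable), and biplot scores are correlations of the explanatory
variables with the site scores. Categorical covariates are dummy-coded and
ordinal food-frequency codes are treated as numeric. Aliased design columns
are dropped with a warning. Total response variance always equals
constrained plus residual variance, and when the responses are exactly
linear in the design the analysis reduces to a PCA of the standardised
responses — both are exercised as tests, alongside a brute-force
normal-equations oracle and a cross-check against `vegan::rda`.

Covariance scaling is available (`scale = "covariance"`) because ordination
reports frequently omit which was used; correlation scaling is the default
since congener concentrations span two orders of magnitude and covariance
scaling would let the abundant congeners dominate every axis.

## Intake and compliance

Infant exposure: daily intake (pg-TEQ/kg bw/day) = TEQ~ww~ × volume ×
density / body weight, weekly = 7 × daily, compared to the tolerable weekly
intake (default 2 pg-TEQ/kg bw/week; the superseded value 14 is kept for
comparison). Milk density defaults to 1.0 g/mL — intake literature mixes mL
volumes with per-gram concentrations without stating a density — and is
configurable to 1.03. `default_sex_volumes()` splits an overall mean volume
(798 mL/day, range 478–1356) into sex-specific means given the male–female
gap (76 mL) and the male share (62.5%), solving the two-group mean
identity so the share-weighted mean reproduces the overall mean exactly.

Body weight over lactation uses a piecewise-linear ramp from birth weight
(0.6 kg/month for months 0–6, 0.4 kg/month after, 30-day months), with a
constant-weight mode. This is deliberately simple plumbing: the point of
the growth model is a defensible denominator, not growth-chart fidelity.

Compliance screening compares the wet-weight dl-PCB TEQ against
0.1 pg-TEQ/g w.w. and the ndl indicator sum against 1 ng/g w.w. — the EU
maximum levels for foods for infants and young children — under the upper
bound by default. A value exactly at the level complies (the levels are
phrased as maxima). Fractions of the limit are invariant to whether the
sample was stored on the wet or lipid basis.

## The synthetic cohort generator

`generate()` emits mothers, infants and milk samples with the statistical
structure the analysis assumes, so parameter-recovery tests can close the
loop. The stated world of the default configuration:

* **Cohort**: 96 mothers, complete 17-stage panels (dropout is exposed via
  `dropout_prob` but defaults to 0, since real panel attrition patterns
  vary too much to pick one defensibly). Covariates are drawn from the
  questionnaire marginals (62.5% male infants, 75% never-smokers, 83.3%
  urban residence, 62.5% primiparous, near-universal fish consumption).
* **Concentration model**: lipid-basis log-concentration = log(baseline) +
  slope·day + covariate effects + mother effect + noise. Log-normality
  gives non-negative concentrations, multiplicative covariate effects and
  roughly stable CVs across the decline, matching how stage tables of such
  data behave (CVs ~5–20%). Day-7 baselines are set so the three group
  sums at day 7 are ≈ 20 (ndl), 3.8 (non-ortho) and 14.9 (mono-ortho)
  ng/g lipid.
* **Sampling design**: weekly stages are single collections; monthly
  stages pool four weekly aliquots (the concentration is the mean of four
  draws over the preceding three weeks), mirroring the stated collection
  protocol of monthly composite samples.
* **Decline slopes** are parameterised by *target trend correlations* —
  the pooled log-scale Pearson r between collection day and concentration
  (ndl targets −0.45…−0.10, dioxin-like targets −0.53…−0.19). The closed
  form (see below) is inverted to obtain the per-day slope for each
  congener. We encode the correlation structure rather than the raw
  fold-change of printed stage tables because the two are mutually
  inconsistent under any monotone model: a 50-fold decline with modest
  scatter would force |r| > 0.9. Reported trend correlations of ~0.3–0.5
  are the quantity the recovery tests measure, so they take precedence;
  the printed stage table is served verbatim by `table2_fixture()` for
  exact-reproduction tests instead.
* **Covariate effects** encode the qualitative ordination findings such
  cohorts report: fish consumption raises 77, 81, 118, 189 (+0.35 log
  units per frequency code), smoking raises 156, 118, 189 (+0.30 per
  smoking code), urban residence raises 123 and 167 (+0.40). Effects are
  centred so baselines stay geometric means for the average mother.
* **Variance components**: between-mother SD 0.30 and within-sample SD
  0.35 on the log scale, i.e. between-mother CV ≈ 31% and within ≈ 36% —
  mid-range for biomonitoring of lipophilic compounds.
* **Composition**: lipid declines linearly from ≈4.6% at day 7 toward
  ≈2.4% beyond a year, protein 1.49% → 0.84%, lactose near 7% with a
  slight decline, dry matter = components + ~0.25% minerals + noise, all
  clipped to plausibility; the dry-matter balance invariant holds by
  construction. Wet-weight values are lipid-basis values × lipid fraction,
  so the basis-conversion identity is exact by construction.
* **Censoring**: values below the configured wet-weight LOD (default
  0.1 pg/g, i.e. 0.1 ng/kg; LOQ = LOD·10/3.3) are flagged. At the default
  LOD almost nothing is censored — realistic for GC-MS of milk — and the
  censoring machinery is exercised in tests by raising the LOD.

### The implied trend correlation

For congener *j* with slope $s_j$, the pooled log-scale correlation with
collection day implied by the model is

$$r_j = \frac{s_j\,\sigma_d}{\sqrt{s_j^2 \sigma_d^2 + \sigma_m^2 +
\overline{\sigma_\varepsilon^2} + \sigma_{\mathrm{cov},j}^2}}$$

where $\sigma_d$ is the SD of the per-stage effective draw days,
$\sigma_m$ the between-mother SD, $\overline{\sigma_\varepsilon^2}$ the
average per-sample noise variance (aliquot averaging divides the monthly
noise variance by 4, via the delta method), and $\sigma_{\mathrm{cov},j}^2$
the variance contributed by covariate effects on congener *j*.
`implied_trend_r()` evaluates this; the recovery tests require estimated
correlations within ±0.15 of it, with the configured negative sign, across
seeds. Because the default slopes are obtained by inverting this formula at
the target correlations, the implied values equal the targets — the check
is that *estimation on generated data* recovers them, not that the algebra
is circular.

### What a green test does not establish

The generator emulates the marginal and correlation structure the analysis
consumes. It does **not** model analytical batch effects, injection
replicates, maternal body-burden depletion across parity, seasonal diet, or
realistic panel attrition. A green recovery test therefore establishes that
the estimators recover the stated generative structure at the stated size —
not that the pipeline is robust to every failure mode of real monitoring
data.

## Numerical choices

* CSV round trips format doubles as `%.17g`, which reproduces IEEE doubles
  bit-exactly through text.
* Sample SD uses the n−1 denominator everywhere.
* Degenerate cases: a constant vector has CV 0; a mean of 0 flags CV as
  undefined rather than dividing; correlation on a constant vector is an
  error, not NA; an exactly collinear calibration fit has intercept SE 0
  (so LOD = 0), which is correct for synthetic exact data and harmless for
  real data.
* RDA keeps eigenvalues above `max(eig)·1e-12` — axes beyond the design
  rank are numerical noise.
* Seeds: `generate()` takes an explicit seed; identical seeds give
  byte-identical cohorts.

## Known limitations

* The K–S normality p-values are approximate (estimated parameters).
* RDA axis significance (permutation tests) is out of scope; score tables
  are computed, figure styling is not.
* Intake scenarios are point scenarios; no uncertainty propagation beyond
  the configured volume/weight ranges.
* Censored values are substituted, not modelled (no MLE for left-censored
  log-normals); all three bounds are reported instead.
* The growth model is a two-slope ramp, not a growth chart.
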