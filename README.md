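# milkteq

Exposure assessment of polychlorinated biphenyls (PCBs) in human milk, for
biomonitoring studies that follow mothers across lactation. The package is
aimed at analysts who receive congener-level GC-MS concentration tables
plus a maternal questionnaire and need to turn them into toxic
equivalents, lactation-stage trends, covariate ordinations, and infant
risk figures — with every step testable against a built-in synthetic
cohort generator.

## What it computes

* **Toxic equivalents.** For the 12 dioxin-like congeners (non-ortho 77,
  81, 126, 169; mono-ortho 105, 114, 118, 123, 156, 157, 167, 189),

  TEQ = Σᵢ cᵢ · TEFᵢ  (pg-TEQ/g),

  under the WHO 2005 TEF scheme by default (126 → 0.1, 169 → 0.03,
  81 → 0.0003, 77 → 0.0001, mono-ortho → 0.00003). Schemes are swappable
  data.
* **Basis and censoring.** Wet-weight ↔ lipid-basis conversion through the
  sample's lipid percentage; left-censored values substituted at 0,
  limit/2 or limit (lower/middle/upper bound). LOD/LOQ from calibration
  curves as 3.3·s/slope and 10·s/slope (s = intercept standard error).
* **Lactation statistics.** 17-stage schedule (weekly through day 28,
  monthly to month 12, then >1 year); per-stage mean ± SD and CV; grand
  summaries across stage means; Pearson correlations with Guilford
  strength labels; ANOVA/Levene/K–S/Tukey battery.
* **Redundancy analysis.** Constrained ordination (least-squares fit +
  eigendecomposition, correlation-biplot scaling) of congener profiles on
  maternal covariates; cross-checked against `vegan::rda` in the tests.
* **Risk.** Infant daily/weekly pg-TEQ/kg bw intake vs the tolerable
  weekly intake (2 pg-TEQ/kg bw/week), and screening against the EU
  maximum levels for foods for infants and young children
  (0.1 pg-TEQ/g w.w. dioxin-like; 1 ng/g w.w. ndl indicator sum).
* **Synthetic cohorts.** A seeded generator (96 mothers × 17 stages by
  default) with log-normal declining concentrations, mother effects,
  fish/smoking/residence covariate effects and LOD censoring, plus the
  closed-form trend correlation it implies — used by the
  parameter-recovery tests.

## Worked example

```r
library(milkteq)

ds <- generate(generator_config(n_mothers = 8), seed = 42)
#> Synthetic cohort: 8 mothers, 136 milk samples, 18 congeners

s <- ds$samples[[2]]          # a day-7 sample from mother M001
compute_teq(s, bound = "middle")
#> TEQ 6.463 pg-TEQ/g (wet_weight, middle bound, scheme who2005)
#>   top contributors: PCB 126 (4.195), PCB 169 (2.232), PCB 118 (0.01931)

compliance_check(s)
#> Sample M001_S02: dl-TEQ 6.463 pg-TEQ/g w.w. (6463% of limit, NON-COMPLIANT)
#>   ndl sum 0.8287 ng/g w.w. (82.87% of limit, compliant)

lactation_trend(ds$samples, q_congener(153, log = TRUE))
#> r = -0.194 (n = 136, p = 0.0239): negligible negative correlation

sc <- intake_scenario("female", default_sex_volumes()[["female"]], 4.2)
daily_intake(compute_teq(s, bound = "middle")$teq, sc)
#> Intake: 1155 pg-TEQ/kg bw/day = 8084 pg-TEQ/kg bw/week (404200% of TWI, EXCEEDED)
```

Reading the numbers: early-lactation milk carries the highest dioxin-like
burden, so this day-7 sample exceeds the 0.1 pg-TEQ/g maximum level by a
wide margin while its ndl indicator sum stays under the 1 ng/g level; the
TEQ is dominated by PCB 126 (TEF 0.1) as usual. The per-congener decline
over the full lactation (here PCB 153, r = −0.19) is weak on a
per-congener log scale even when the early-to-late fall is substantial.
The intake figure is the conservative point estimate for a 4.2 kg infant
drinking 750.5 mL/day of *this* milk — early-stage milk at peak TEQ, hence
far above the 2 pg-TEQ/kg bw/week guideline.

A file-based workflow is available through the CLI:

```sh
Rscript -e 'milkteq::milkteq_cli()' simulate --n 96 --seed 1 --out-dir cohort/
Rscript -e 'milkteq::milkteq_cli()' teq --in cohort/samples.csv --bound upper --out teq.csv
Rscript -e 'milkteq::milkteq_cli()' summarize --in cohort/samples.csv --out stages.csv
Rscript -e 'milkteq::milkteq_cli()' rda --in cohort/samples.csv --covariates cohort/covariates.csv --out ord
Rscript -e 'milkteq::milkteq_cli()' compliance --in cohort/samples.csv --out screen.csv
```

## Documentation

`vignettes/milkteq-methods.Rmd` describes the models, conventions
(censoring bounds, SD/CV definitions, Guilford bands, RDA scaling), the
synthetic generator's stated world and its limits, and the numerical
choices.
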