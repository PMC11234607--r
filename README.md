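# linkbias

Tools for studying how record-linkage errors distort epidemiological
inference when administrative health databases are joined at different
identifier levels.

## The problem

Registries and claims databases held by different agencies can be linked
exactly when a unique personal number (directly identifiable
information, **DII**) may be shared. When privacy law forbids that,
agencies join on composite keys built from quasi-identifiers — name,
date of birth, sex (indirectly identifiable information, **III**). III
keys are imperfect, producing **missed matches** (the same person fails
to join, shrinking the cohort — possibly selectively) and **false
matches** (different people share a key and are joined). Both propagate
into descriptive statistics, incidence rates, hazard ratios and subgroup
effects, and the damage concentrates in small strata.

`linkbias` is a simulation laboratory for this problem. It

1. **generates** paired registry/claims cohorts with known ground truth —
   five cancer strata of very different sizes, each with a
   stratum-specific treatment contrast and proportional-hazards fracture
   outcomes (`scenario_config()`, `generate_population()`,
   `simulate_outcomes()`, `emit_source_tables()`);
2. **corrupts** identifiers with configurable missed-match, false-match
   and DII-miss rates, optionally covariate- or outcome-dependent
   (`error_model()`, `corrupt_identifiers()`);
3. **links** the tables deterministically at both levels and audits the
   result against the truth (`link_tables()`, `account()`,
   `linkage_accounting()`, `linkage_rate()`);
4. **analyses** each linked cohort with a standard battery — descriptive
   tables, rule-based group comparisons, person-years incidence with
   exact Poisson intervals, simple/adjusted Cox models, subgroup effects
   (`analyze_cohort()`, `compare_groups()`, `incidence_rate()`,
   `fit_cox()`, `subgroup_effects()`);
5. **scores** the concordance of the III-level results against the
   DII-level gold standard with arcsine effect sizes and a three-tier
   good/poor/insufficient verdict grid (`cohens_h()`, `cohens_f()`,
   `hr_effect_size()`, `classify_study_level()`, `concordance_report()`).

The core quantities are Cohen's h for proportions,

    h = | 2·arcsin√p1 − 2·arcsin√p2 |,

Cohen's f = √(R²/(1−R²)) for model explanatory power, and a documented
ratio convention mapping each hazard/rate ratio r to r/(1+r) before
applying h. Effect sizes are binned none/very small/small/medium/large
at 0.01/0.2/0.5/0.8, and each stratum × analysis cell is classified
top-down: significantly opposite directions or effect ≥ 0.8 →
insufficient (X); effect in [0.5, 0.8) or opposite directions without
joint significance → poor (△); otherwise good (○).

## Worked example

```r
library(linkbias)

cfg <- scenario_config(seed = 42)           # 5 strata, 51,500 people
em  <- error_model(miss_rate = 0.287,       # III corruption rates
                   collision_rate = 0.002,
                   dii_miss_rate = 0.003, seed = 43)
run <- run_pipeline(cfg, em, output_dir = "study")

run$accounting$III
#> Linkage flow
#>   truth pairs                 51500
#>   linked rows                 36460  (70.8% of truth pairs)
#>   false matches                 114  (0.2%)
#>   missed matches              15154  (29.4%)
#>   linkage rate vs reference  71.0%
```

The III-level join loses ~29% of the cohort and gains 0.2% false rows;
its size is 71.0% of the DII cohort — the configured error regime.
The verdict grid then shows where inference survives:

```r
run$concordance$grid
#>                  BC CC GC PC TC
#> descriptive      ○  ○  ○  ○  ○
#> group_comparison ○  ○  ○  ○  ○
#> incidence        △  ○  ○  ○  ○
#> cox              △  ○  ○  ○  ○
#> subgroup         △  -  -  ○  -
```

Most cells are good, but the breast stratum is flagged poor: its
aromatase-inhibitor arm's adjusted hazard ratio falls on opposite sides
of 1 at the two levels (0.98 under III vs 1.01 under DII) without being
significant in either — exactly the opposite-direction rule:

```r
it <- run$concordance$items
it[it$method == "cox" & it$stratum == "BC", c("item", "est_iii", "est_dii", "effect", "level")]
#>      item   est_iii   est_dii  effect level
#>   AI-only 0.9796757 1.0076075 0.01406  poor
#>    AI-TAM 0.6173690 0.5442350 0.06076  good
#>  TAM-only 0.8312709 0.8267903 0.00269  good
```

Individual pieces work standalone:

```r
cohens_h(0.172, 0.099)        # share of low-comorbidity patients, III vs DII
#> cohens_h = 0.2151 (small)
incidence_rate(10, 1e5)       # exact Poisson interval
#> 10 events / 100000.0 PY: 10.00 (4.80-18.39) per 1e+05 PY
linkage_rate(652004, 914399)  # cohort-size ratio as a one-decimal %
#> [1] 71.3
```

A thin command-line wrapper over the same pipeline lives in
`inst/scripts/run_linkage_study.R` (YAML config in, artifact directory
out).

## Methods

The data-generating model, error mechanisms, linkage tie-break, test
selection rules, effect-size conventions and classifier are documented
in the methods vignette, `vignettes/linkage-error-impact.Rmd`.
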