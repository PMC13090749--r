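# ednacongr

Quantifying congruence between independently produced taxonomic assignments
of riverine fish eDNA metabarcoding datasets.

When metabarcoding datasets from many studies are reanalyzed under one common
bioinformatic workflow, the reanalyzed species lists rarely match the
originally published ones exactly. `ednacongr` measures that (dis)agreement
and explains it. For ecologists and molecular biodiversity researchers
comparing assignment tables across studies, the package provides:

* **Hierarchical pool correction** — restrict assignments to basin-, country-
  or continent-scale local species pools supplied as explicit tables.
* **Coverage auditing** — for each dataset: the proportion of the local pool
  represented in the barcode reference database, and the proportion of
  assigned taxa that are local, at species and genus resolution.
* **Species-identity congruence** — the four-category partition (shared,
  unique to the reanalysis, unique-to-original but local, unique-to-original
  non-local) and the overlap statistics

  $$p_{sp} = \frac{N_{shared}}{N_{species\ in\ reanalysis}}, \qquad
  p_{read} = \frac{N_{reads\ on\ shared\ species}}{N_{reads\ in\ reanalysis}},$$

  plus per-species relative-abundance indices
  $a_{i,d} = \sum_s R_{i,s} / \sum_s\sum_j R_{j,s}$ and
  $b_{i,d} = \tfrac1{n_d}\sum_s R_{i,s}/\sum_j R_{j,s}$.
* **Community comparison** — Jaccard distances over dataset species profiles
  with in-package PERMANOVA, ANOSIM, multivariate-dispersion and db-RDA
  permutation tests (exact enumeration mode for small n) and Kruskal NMDS.
* **Explanatory models** — beta regression of the overlap proportions on read
  depth, sampling year, richness and reference-database type; a
  negative-binomial random-intercept GLMM for richness pairs; beta mixed
  models for the abundance indices (via `glmmTMB`); Kruskal–Wallis/Dunn tests
  with compact letter displays.
* **A synthetic collection generator** with nested pools, regionally varying
  reference-database coverage, a logit-linear congruence model, and a
  ground-truth record, so every stage is testable by parameter recovery.
* **Name harmonization** through an explicit synonym table (no live
  taxonomic-backbone lookups), with exact round-trip recovery.

## Worked example

```r
library(ednacongr)
library(dplyr)

cfg <- sim_config(seed = 1)          # 50 datasets, six continents
col <- sim_collection(cfg)

cr <- congruence_report(col)         # per-dataset identity congruence
summarise(cr, mean_p_sp = mean(p_sp, na.rm = TRUE),
              median_p_sp = median(p_sp, na.rm = TRUE),
              mean_p_read = mean(p_read, na.rm = TRUE))
#> # A tibble: 1 × 3
#>   mean_p_sp median_p_sp mean_p_read
#>       <dbl>       <dbl>       <dbl>
#> 1     0.597       0.551       0.761

species_totals(col)                  # corrected species totals per scale
#> # A tibble: 5 × 2
#>   scale     n_species
#>   <chr>         <int>
#> 1 original        520
#> 2 global          599
#> 3 continent       564
#> 4 country         467
#> 5 basin           442
```

The mean shared-species proportion (~60%) says that a typical simulated
dataset recovers about six in ten of its basin-corrected reanalyzed species
in the original assignment; the corrected totals shrink monotonically as the
pool narrows from uncorrected (global) through continent and country to
basin — the structural signature of nested pool correction.

Fitting the explanatory beta regression and the community tests:

```r
cr2 <- cr |> filter(!is.na(p_sp)) |> mutate(year_c = year - min(year))
fit <- fit_beta_glm(cr2, p_sp ~ log(median_fish_reads) + year_c +
                          richness + refdb_type)
tidy(fit)
#> # A tibble: 5 × 5
#>   term                   estimate std.error statistic       p.value
#>   <chr>                     <dbl>     <dbl>     <dbl>         <dbl>
#> 1 (Intercept)            -1.52      0.751      -2.02  0.0435
#> 2 log(median_fish_reads)  0.104     0.0702      1.48  0.139
#> 3 year_c                  0.181     0.0303      5.98  0.00000000218
#> 4 richness                0.00565   0.00977     0.578 0.563
#> 5 refdb_typeglobal        0.0702    0.183       0.384 0.701

ct <- community_tests(col, n_perm = 999, seed = 1)
ct$tests |> filter(grouping == "continent", method == "PERMANOVA")
#> # A tibble: 1 × 7
#>   grouping  method    statistic stat_name    r2 p.value n_perm
#>   <chr>     <chr>         <dbl> <chr>     <dbl>   <dbl>  <dbl>
#> 1 continent PERMANOVA      7.65 pseudo-F  0.210   0.001    999
```

The positive, significant `year_c` coefficient is the embedded
improving-over-time effect recovered from the simulated collection; the
PERMANOVA row says continental identity structures community composition
(R² ≈ 0.21) while assignment type does not.

`run_pipeline(col, run_config(seed = 1, out = "results/"))` chains all
stages — coverage, congruence, abundance, community tests, models, grouped
tests — and writes CSV tables plus a machine-readable `report.json`.

## Package layout

| module | contents |
|---|---|
| `R/simulate.R`, `R/config.R` | synthetic collection generator + config |
| `R/taxonomy.R` | synonym tables, name standardization, harmonization |
| `R/coverage.R` | pool coverage and local-assignment audits |
| `R/congruence.R` | four-category partition, overlap + abundance indices |
| `R/community.R` | Jaccard, PERMANOVA, ANOSIM, PCoA, dispersion, db-RDA, NMDS |
| `R/models.R`, `R/group_tests.R` | beta/NB(-mixed) regressions, rank tests, letters |
| `R/io.R` | collection readers/writers, pipeline, report |

See the methods vignette (`vignettes/congruence-methods.Rmd`) for the models,
their assumptions, and the design decisions.
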