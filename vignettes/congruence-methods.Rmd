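---
title: "Quantifying congruence between eDNA taxonomic assignments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying congruence between eDNA taxonomic assignments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ednacongr)
library(dplyr)
```

## The problem

When a riverine fish eDNA metabarcoding dataset is reanalyzed under a common
bioinformatic workflow, how much do the resulting taxonomic assignments agree
with the ones the original study published? `ednacongr` provides the full
quantitative apparatus for that question: hierarchical local-species-pool
correction, reference-database coverage auditing, a four-category
species-identity classification with overlap statistics, distance-based
community comparisons with permutation inference, and the regression stages
that explain why congruence varies across datasets. A synthetic collection
generator with a ground-truth record makes every stage testable by parameter
recovery.

## Local pools and coverage

Each dataset carries local species pools at three nested scales — basin,
country, continent — supplied as explicit tables (we do not resolve basins
geodesically; the mapping is an input). Two complementary proportions are
audited per dataset, scale, and taxonomic resolution:

* **coverage** — the share of the local pool represented in the barcode
  reference database for the dataset's primer;
* **local-assignment proportion** — the share of taxa in the uncorrected
  ("global") assignment that belong to the pool.

At genus resolution both sets are collapsed to genera *before* intersecting,
so a genus counts as covered as soon as any congeneric species has a barcode.
This is the only reading under which genus-level coverage is well defined.
The full pool is used as the coverage denominator; we do not exclude pool
species that lack barcodes everywhere, since that information is not part of
the inputs.

## The four-category classification and overlap statistics

With the reanalysis corrected to the basin pool, every species falls in
exactly one of: shared; unique to the reanalysis; unique to the original but
basin-local ("extra local species"); unique to the original and not local.
Two dataset-level responses summarize agreement:

$$p_{sp} = \frac{N_{\text{shared}}}{N_{\text{species in reanalysis}}},
\qquad
p_{read} = \frac{N_{\text{reads on shared species}}}{N_{\text{reads in reanalysis}}}.$$

Two per-species indices summarize relative abundance within a dataset $d$
with read counts $R_{i,s}$ at sites $s$:

$$a_{i,d} = \frac{\sum_s R_{i,s}}{\sum_s \sum_j R_{j,s}}, \qquad
b_{i,d} = \frac{1}{n_d} \sum_s \frac{R_{i,s}}{\sum_j R_{j,s}},$$

both summing to one over species; $p_{read}$ is algebraically the sum of
$a_{i,d}$ over shared species, which the test suite checks on random tables.

Three denominator conventions are genuinely ambiguous in this design, and we
fix them as follows (each is a package choice, not a mathematical necessity):

* $p_{sp}$ uses the **basin-corrected** reanalyzed species count, because the
  identity comparison itself is defined against the basin-corrected
  reanalysis. The uncorrected variant can be obtained by passing
  `scale = "global"` pools.
* $p_{read}$ uses all reads of the basin-corrected table, with unresolved
  names excluded (they cannot be matched across assignments).
* $b_{i,d}$ drops sites with zero total reads and decrements $n_d$, avoiding
  0/0; $a_{i,d}$ uses the grand total and is unaffected.

Species matching is exact canonical-binomial equality at species rank.
Genus-level agreement is reported separately by the coverage module and never
silently substituted. Original assignments provided only as richness tables
take part in the richness comparison but not in identity comparison.

## Name harmonization

All comparisons run on canonical binomials. A two-column synonym table
(variant, canonical) drives harmonization: whitespace/Unicode normalization,
case-insensitive lookup, merging of rows that canonicalize identically (read
counts are summed, so totals are conserved). Names absent from the table that
do not look like a canonical binomial become *unresolved*: they are retained
under a flag (or dropped on request) and excluded from species-level
statistics. There is no fuzzy matching and no live taxonomic-backbone lookup;
the synonym table is the single source of truth, which makes the
noise-injection/harmonization round trip exactly invertible — a property the
acceptance suite verifies bit-exactly.

## Community structure

Dataset-level species profiles (original, global reanalysis, basin
reanalysis) form a binary occurrence matrix; distances are presence/absence
Jaccard. The permutation machinery is implemented in the package rather than
delegated, so its null behaviour is fully specified:

* free permutation of group labels (the design has no blocking structure);
* $p = (1 + \#\{T_{perm} \ge T_{obs}\})/(1 + n_{perm})$, so $p \ge
  1/(n_{perm}+1)$ and $p = 0$ is impossible;
* an `exact = TRUE` mode enumerates all distinct label assignments for
  $n \le 10$, used to validate the Monte-Carlo estimator.

PERMANOVA uses the classical pseudo-F on sums of squared distances; ANOSIM
the rank statistic $R = (\bar r_{between} - \bar r_{within})/(M/2)$. PCoA
keeps negative eigenvalues; the dispersion test measures distances to group
centroids with the imaginary-axis correction
$\sqrt{\max(0, |re|^2 - |im|^2)}$, needed because Jaccard matrices are
non-Euclidean, and permutes labels with full recomputation of centroid
distances. db-RDA regresses the positive-eigenvalue PCoA axes on group
indicators without Lingoes/Cailliez correction — a documented dialect choice;
with Euclidean input it coincides with classic RDA, which the tests verify
against an independent implementation. NMDS minimizes Kruskal stress-1 by
alternating pool-adjacent-violators monotone regression (primary tie
treatment) with Guttman-transform updates, best of `n_restarts` starts (first
start from PCoA); the stress trace is non-increasing by construction. NMDS
dimensionality defaults to 2 and is exposed as an option.

## Regression stages

* **Richness.** Reanalyzed per-site richness on original per-site richness,
  negative-binomial (NB2) family, log link, dataset random intercept,
  Laplace-fitted via `glmmTMB` — the standard engine for exactly this model
  class. Marginal and conditional R² follow the Nakagawa decomposition with
  the lognormal observation-level variance $\ln(1 + 1/\bar\nu + 1/\theta)$; we
  state this as our dialect since several variants circulate.
* **Overlap proportions.** $p_{sp}$ and $p_{read}$ on log median fish reads,
  sampling year (centered at the collection minimum), reanalyzed richness and
  reference-database type (global = reference level), beta likelihood with
  logit mean link, fitted by direct maximum likelihood (BFGS with analytic
  gradients, Wald inference from the numerical Hessian). Each dataset is one
  observation, so no random effect enters. Exact 0s and 1s occur; all
  responses are smoothed with $y' = (y(n-1) + 0.5)/n$ first.
* **Abundance indices.** $a$ or $b$ on the shared/unique flag plus
  reference-database type and year, beta family with a dataset random
  intercept via `glmmTMB`. A beta family is our choice for these
  (0,1)-valued indices; a logit-normal alternative would be defensible and
  can be emulated by transforming the response. The shared-vs-unique
  contrast is the coefficient of interest. For the beta family the
  observation-level R² variance term is the delta-method logit-scale variance
  $1/((1+\phi)\mu(1-\mu))$ averaged over fitted means.
* **Grouped tests.** Kruskal–Wallis with a hand-implemented Dunn post-hoc
  (tie-corrected rank z), unadjusted by default with an optional `p.adjust`
  method (the adjustment convention is left open in this literature), and a
  compact letter display built by insert–absorb over the pairwise
  significance graph. Two-group contrasts use the Wilcoxon rank-sum test;
  categorical contingency uses Fisher's exact test. Non-convergent model fits
  are returned flagged (`converged = FALSE`) with diagnostics, never as
  exceptions, so a pipeline run always completes.

A sensitivity filter removes datasets whose median per-site fish reads fall
below a threshold, replicating the robustness check in which low-read
datasets drive the read-depth effect.

## The synthetic collection generator

The generator emulates the statistical structure the analysis assumes,
starting at assigned read tables (no raw reads, PCR/primer bias, or ASV error
profiles — out of scope by design). Defaults describe the study conditions:

* 50 datasets weighted over six continents as in the compiled studies
  (Asia 15 : Europe 17 : North America 12 : South America 9 : Oceania 4 :
  Africa 1), years 2014–2023, 3–30 sites each (real collections run to 200
  sites; we scale down to keep tables small), nested pools of 50/200/800
  species (basin/country/continent, 2 countries per continent, 2 basins per
  country).
* Reference databases per barcode cover each continent's pool with
  probability 0.35 (Africa), 0.45 (South America), 0.60 (Oceania), 0.75
  (Asia), 0.80 (Europe), 0.85 (North America) — low coverage in Africa and
  South America mirrors the documented geographic bias of barcode archives.
* Per-site read totals are lognormal around a per-dataset median (log-mean
  `log(2e4)`), scaled down from the tens-of-thousands-to-millions range of
  real runs; read counts are multinomial per site over lognormal species
  abundance effects — the simplest model reproducing compositional
  structure.
* The expected shared-species proportion follows
  $\mathrm{logit}(\mu_d) = \beta_0 + \beta_{reads}\, z_{reads} +
  \beta_{year}(year - year_{min}) + \beta_{rich}\, z_{rich} +
  \beta_{cov}(cov_d - \overline{cov})$, with beta noise at precision $\phi$;
  each detected species is then independently shared. Defaults
  $\beta_0 = -0.3$, $\beta_{reads} = 0.3$, $\beta_{year} = 0.15$,
  $\beta_{rich} = -0.02$, $\beta_{cov} = 2$, $\phi = 30$ put the mean
  shared-species proportion near 60% and embed the year and coverage effects
  the analysis is meant to detect. The logit-linear form mirrors the beta
  GLM of the analysis stage; it is a modeling choice, not an empirical claim
  about any particular collection. The explicit coverage coefficient is the
  generator's mechanism for making poorly covered regions less congruent —
  without it, coverage would act only through richness and could not produce
  the regional pattern.
* Species unique to the reanalysis carry a log-abundance shift
  $\delta = -1$; original assignments add missed basin-pool species at rate
  0.05 (global-reference datasets) or 0.25 (custom), and a Poisson(2) number
  of off-basin false positives, so all four identity categories are
  populated. Uncorrected assignments gain Poisson(3) off-basin and
  Poisson(0.75) off-continent reference-database species, so global totals
  strictly exceed continent-corrected ones.
* Species labels receive synonym noise at rate 0.1 against a complete
  generated synonym table (one variant per canonical name).

A single seed determines everything; per-dataset streams are derived from it,
so appending datasets never perturbs earlier ones, and the `truth` record
stores coefficients, per-dataset memberships, realized coverage and the
canonical-name map for recovery tests. The config also accepts `nesting`
fractions from which country/basin pool sizes are derived; sizes and
fractions are redundant given enforced nesting, so sizes are primary.

What the generator does *not* emulate: sequencing error, primer bias,
compositional zero-inflation beyond occupancy thinning, spatial
autocorrelation among sites, and taxonomic misassignment structure beyond
uniform off-basin noise. Passing recovery tests therefore demonstrates the
statistical machinery is correct and calibrated under the stated model — not
that any real collection satisfies that model.

## Numerical choices

* Beta MLE: BFGS on $(\beta, \log\phi)$ with analytic gradients, initialized
  from the logit-linear least-squares fit; relative tolerance $10^{-14}$;
  separation or a singular Hessian yields a flagged fit.
* Permutation ties: statistics are compared with a $10^{-12}$ slack so exact
  ties count as at least as extreme.
* PCoA axes with $|\lambda|$ below $10^{-9}\max|\lambda|$ are dropped as
  numerically null.
* NMDS stops when the relative stress improvement falls below $10^{-7}$ or
  after 200 iterations.
* Proportion smoothing uses the observation count of the fitted model.
* When per-site richness is underdispersed the NB2 dispersion diverges
  ($\theta \to \infty$, a singular boundary for the NB Hessian); the richness
  GLMM then refits in the Poisson limit and reports $\theta = \infty$, which
  is the correct boundary MLE rather than a failure.
* Seeded functions restore the caller's RNG stream (`seed = NULL` draws from
  the current stream), so simulation loops remain independent of inner
  seeding.

## Problem sizes used by the validation suite

The test and acceptance suites exercise the framework at the scale of the
study design: 1,000 random partitions and read tables for the algebraic
identities; collections of 50 datasets for end-to-end sign patterns;
100 replicate collections of 200 datasets for year-effect recovery and 1,000
direct draws of 200-dataset congruence tables for size control; 200
replicates of a 50-dataset × 20-site design for NB-GLMM coverage; 2,000
exchangeable-null draws for permutation-test size. These sizes are the
package's validation design and are chosen to give Monte-Carlo standard
errors well inside the asserted bands.

## Known limitations

Identity comparison requires species lists on both sides; genus-only original
records participate only at genus resolution. The beta family for abundance
indices is an assumption, as is free permutation in the community tests.
Coverage audits take the reference-database taxon list as given — in-silico
amplification is out of scope. Real collections violate the generator's
independence assumptions in ways the recovery tests cannot detect.
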