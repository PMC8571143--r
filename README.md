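# entroTME

Immune infiltrate diversity analysis for multiplex immunofluorescence
tissue microarrays (TMAs), with survival biomarker evaluation.

Follicular lymphoma outcome is shaped by the non-neoplastic immune cells
around the tumour. Rather than tracking single cell subsets, entroTME
summarises the whole microenvironment: each combination of marker
positivity over five immune stains (CD4, CD8, CD68, FOXP3, PD-1) is a
distinct phenotype — `2^5 = 32` codes plus the reserved `DAPI_ONLY` and
`CD21_ONLY` classes — and diversity is quantified with Shannon's entropy,
in nats:

* **Phenotype entropy** `H = -Σ_i p_i ln p_i` over the phenotype
  proportions of a core (reserved classes excluded);
* **Interaction entropy** `H_int = -Σ_{i≤j} p_ij ln p_ij` over the
  proportions of unordered phenotype-pair co-occurrences within 30 µm
  (cells expressing only DAPI excluded).

Around these indices the package provides the full working pipeline:
threshold-based cell scoring (nucleus for FOXP3, membrane for the other
stains), phenotype assignment, per-core densities, the immune infiltrate
ratio, the CD21+ follicular dendritic meshwork area fraction from
annotation polygons, median-of-triplicate patient aggregation,
intra-patient coefficient of variation, Cox proportional-hazards models
(univariable and FLIPI-adjusted), Kaplan–Meier curves with Greenwood
confidence intervals, the Contal–O'Quigley maximally selected log-rank
cutpoint with a Brownian-bridge adjusted p-value, POD24 association tests,
and Bonferroni correction. A deterministic synthetic TMA generator with
known ground truth (point patterns, follicle enrichment, bimodal
intensities, linked Weibull survival) makes every stage testable without
any imaging data.

## Worked example

Simulate a 40-patient cohort, score and phenotype the cells, profile each
core, and test the diversity indices as survival biomarkers:

```r
library(entroTME)
library(dplyr)

cfg     <- sim_config(seed = 42, n_patients = 40)
cohort  <- simulate_cohort(cfg)
panel   <- default_panel(threshold = sim_thresholds(cfg))

cells    <- cohort$cells |> score_cells(panel) |> assign_phenotypes(panel)
profiles <- profile_cores(cells, annotations = cohort$annotations)
profiles |> select(core_id, n_cells, phenotype_entropy,
                   interaction_entropy, immune_ratio) |> head(3)
#> # A tibble: 3 × 5
#>   core_id n_cells phenotype_entropy interaction_entropy immune_ratio
#>   <chr>     <int>             <dbl>               <dbl>        <dbl>
#> 1 P001_c1    2067              2.15                3.72        0.700
#> 2 P001_c2    2050              2.22                3.91        0.683
#> 3 P001_c3    2001              2.18                3.86        0.652
```

Each row is one 1.2 mm core: ~2000 cells, a phenotype entropy of ~2.2 nats
(a moderately diverse mixture; the theoretical maximum is ln 32 ≈ 3.47),
an interaction entropy near 3.9 nats over the pair types, and about 0.7
immune cells per DAPI-only cell. Aggregate to patients and fit
FLIPI-adjusted Cox models (hazard ratios are per nat, so they look extreme
when a feature only spans a fraction of a nat across patients):

```r
patients <- aggregate_patients(profiles)
surv     <- inner_join(patients, cohort$clinical, by = "patient_id")
fit      <- cox_fit(surv, "os", c("phenotype_entropy", "interaction_entropy"),
                    adjust_flipi = TRUE)
tidy(fit) |> filter(term == feature) |>
  select(feature, hr, ci_low, ci_high, p, n, n_events)
#> # A tibble: 2 × 7
#>   feature                   hr      ci_low ci_high      p     n n_events
#> 1 phenotype_entropy   0.000453 0.000000481   0.427 0.0276    28        6
#> 2 interaction_entropy 0.0244   0.000756     0.787  0.0362    28        6
```

Both indices come out protective (HR < 1), as simulated (the generator's
log-HR is −1.5 per standardised unit of true entropy); 28 of 40 patients
carry a FLIPI score and are retained. The optimal dichotomisation point,
with its scanning-bias-adjusted p-value:

```r
contal_oquigley_cutpoint(surv$phenotype_entropy, surv$os_months, surv$os_event)
#> <div_cutpoint> Contal-O'Quigley maximally selected log-rank cutpoint
#>   n = 40, events = 9, candidate cuts = 33
#>   cut = 1.96526 (72.5% of subjects above)
#>   q = 1.7491, p_logrank = 0.0001401, p_adjusted = 0.004402
```

The adjusted p is ~30× larger than the naive log-rank p at the selected
cut — the price of scanning 33 candidate cuts. File-level stages
(`run_score()`, `run_diversity()`, `run_survival()`, `run_all()`) mirror
these functions for batch use, and `inst/cli/entrotme` exposes them as
shell subcommands.

## Package layout

* `R/` — panel/scoring/phenotyping (`marker_panel`, `score_cells`,
  `assign_phenotypes`), geometry (`core_geometry`, `cd21_area_fraction`),
  per-core features (`profile_cores`, `count_interactions`,
  `shannon_entropy`), cohort statistics (`cox_fit`, `km_curves`,
  `contal_oquigley_cutpoint`, `pod24_tests`, `bonferroni_adjust`),
  synthetic data (`sim_config`, `simulate_cohort`), and the file pipeline
  (`run_*`).
* `vignettes/immune-diversity.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator scope, numerical decisions.
* `tests/testthat/` — unit, property and acceptance tests.
* `inst/cli/entrotme` — command-line front end.
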