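---
title: "Quantifying immune infiltrate diversity in multiplex immunofluorescence TMAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune infiltrate diversity in multiplex immunofluorescence TMAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroTME)
library(dplyr)
```

## The problem

Follicular lymphoma (FL) is an indolent B-cell lymphoma whose clinical course
is strongly shaped by the non-neoplastic cells around the tumour — T-helper
cells, cytotoxic T cells, regulatory T cells, macrophages, follicular
dendritic meshworks. Individual cell subsets have been studied as prognostic
markers with conflicting results; a *holistic* summary of the immune
microenvironment may carry more information than any single subset. entroTME
implements such a summary: it treats every combination of marker positivity
as a distinct cell "species" and quantifies the diversity of the species
mixture — and of their spatial co-occurrences — with Shannon's entropy, then
evaluates the resulting indices as survival biomarkers.

The package starts downstream of image analysis. Its input is a *cell table*:
one row per segmented cell with centroid coordinates (µm) and per-compartment
median stain intensities for a 7-colour panel (DAPI, CD4, CD8, CD68, FOXP3,
PD-1, CD21), plus tissue/artefact/CD21-meshwork annotation polygons and a
clinical table. Nuclear segmentation, membrane reconstruction and spectral
unmixing are upstream concerns of the imaging platform, not of this package.

## From intensities to phenotypes

**Scoring.** Each marker is called positive when the median intensity on its
*designated compartment* — the nucleus for the transcription factor FOXP3,
the membrane for all other stains — is at or above a single per-marker
threshold. Thresholds are inputs (chosen by annotators on the imaging
platform); the package applies them, it does not select them. Two
conventions are fixed deliberately:

* the rule is *closed* (intensity `>=` threshold is positive), so behaviour
  at the boundary is deterministic and documented;
* DAPI is not thresholded — segmentation is DAPI-driven, so every segmented
  cell is treated as DAPI-positive.

**Phenotyping.** The five immune stains (CD4, CD8, CD68, FOXP3, PD-1) define
`2^5 = 32` combination codes such as `CD4+CD8-CD68-FOXP3+PD-1-` (a Treg).
Each cell receives exactly one label. Cells with no positive immune stain
fall into two reserved classes — `DAPI_ONLY` (CD21-negative) and `CD21_ONLY`
(CD21-positive) — which may contain tumour B cells and are therefore
excluded from the diversity analysis. A cell positive for CD21 *and* an
immune stain keeps its immune combination code: CD21 marks dendritic
meshwork, it is not part of the phenotype code. Note one identity that
follows from the rule: the all-negative combination code never appears as a
label, because such cells are by definition `DAPI_ONLY` or `CD21_ONLY`.

## The diversity indices

**Phenotype entropy.** With `p_i` the proportion of included cells carrying
label `i`,

    H = -sum_i p_i ln(p_i)        (nats)

`H` is 0 for a monoculture and `ln(32) ≈ 3.466` at the (unreachable in
practice) uniform mixture over all 32 codes. Degenerate samples (fewer than
two included cells) report 0 with a warning rather than an error, so a bad
core cannot sink a cohort run.

**Interaction entropy.** Two cells *interact* when their centroids lie
within a fixed radius — 30 µm by default, roughly a 3–4-cell neighbourhood.
Every unordered pair of distinct cells within the radius contributes one
count to its unordered label pair `{i, j}` (self-pairs `{i, i}` are the
pairs of distinct same-label cells); the closed rule counts a pair at
exactly 30 µm. Shannon's index applied to the pair-type proportions
`p_ij` gives the interaction entropy

    H_int = -sum_{i<=j} p_ij ln(p_ij)

Only `DAPI_ONLY` cells are excluded from interaction counting by default
(`CD21_ONLY` cells participate); the exclusion sets of both indices are
configurable, and the asymmetry follows the methodology the package
implements. Whether pairs are counted once or twice does not matter for the
entropy — proportions are identical under either convention — which is why
the entropy, not the raw counts, is the tested surface.

Internally the counter bins cells into a uniform grid with radius-sized
cells and only tests pairs in adjacent bins. This is purely an
optimisation: the distance filter decides membership, so the counts are
*bit-identical* to a naive all-pairs scan, and the test suite enforces that
equality on random cores.

**Densities and ratios.** Cell-subset densities (cells/mm²) use a compact
subset notation: `"CD68+"` counts every CD68-positive cell regardless of
other markers (to stay comparable with single-plex studies);
`"CD4+CD68-"` requires every stated sign (T-helper cells are CD4+ cells
that are not macrophages). The default reported subsets are
`CD4+CD68-`, `CD4+FOXP3+`, `CD8+`, `CD68+`, `CD4+CD68-PD-1+`, `CD8+PD-1+`.
The *immune infiltrate ratio* divides cells positive for at least one
immune stain by `DAPI_ONLY` cells; it is undefined (an error) without
DAPI-only cells. The CD21 meshwork *area fraction* is the union of meshwork
annotations clipped to the analysable tissue (tissue polygon minus artefact
exclusions), divided by the analysable tissue area; polygon boolean
operations use the Clipper library (polyclip), and cells exactly on a
polygon boundary count as inside (closed polygons, deterministic
filtering).

## Patient-level statistics

Cores are sampled in triplicate; the patient's value of each feature is the
**median** over available cores (mean-of-middle for even counts).
Reproducibility across replicates is summarised by the intra-patient
coefficient of variation, `100 * sd / mean` over a patient's cores
(patients need at least two cores and a positive mean to contribute); the
cohort summary is the **median** CoV across patients — the central tendency
is deliberately robust because CoV is ratio-distributed.

The survival layer is deliberately conventional and built on the survival
package:

* **Cox proportional hazards**, one model per feature with the feature
  continuous (HR per unit), optionally adjusted for the ordinal FLIPI score
  (0–5); Efron tie handling, because simulated and real follow-up are
  recorded in whole months and ties are common. Missing FLIPI leads to
  listwise deletion with retained counts reported.
* **Kaplan–Meier** curves with Greenwood-variance 95% confidence intervals
  and the log-rank test.
* **POD24** (progression within 24 months): Mann–Whitney U comparison of
  each feature between POD24 groups plus univariable and FLIPI-adjusted
  logistic regression (Wald intervals).
* **Bonferroni**: the family is the set of features tested in one run (10
  by default), so the per-test threshold at `alpha = 0.05` is 0.005; a p
  exactly at the threshold is significant (closed rule).

**Optimal cutpoint.** For dichotomised Kaplan–Meier display the package
implements the Contal–O'Quigley maximally selected log-rank statistic: every
distinct observed feature value that leaves at least 10% (configurable) of
subjects in each group is a candidate cut; at each cut the two-sample
log-rank score is computed; the selected cut maximises the absolute
standardised score

    q = max_c |S_c| / (s * sqrt(D - 1)),
    s^2 = (1/(D-1)) * sum_{i=1}^{D} (1 - a_i)^2,   a_i = sum_{j<=i} 1/(D-j+1)

with `D` the number of events. The adjusted p-value is the Brownian-bridge
supremum tail probability `2 * sum_j (-1)^{j+1} exp(-2 j^2 q^2)` (series
truncated below 1e-12; for `q < 0.2` the value is 1 to double precision,
where the alternating series itself converges too slowly to be usable).
This correction matters: scanning all cuts and reporting the best naive
log-rank p is strongly anti-conservative, and the package's simulations
(see `scripts/acceptance.R`) demonstrate both the near-nominal size of the
adjusted p and the inflation of the naive minimum p. Because the
standardisation constant is a rank-based construction whose software
conventions vary, the implementation is validated against a *permutation
null* of the supremum statistic — the authoritative internal oracle — not
against any particular historical implementation. Ties at the selected cut
go to the "low" group, consistent with cuts being observed values.

## The synthetic cohort generator

Real patient-level data for this methodology are not redistributable, so the
package ships a generator that emulates the study design with known ground
truth; every pipeline stage is testable against it without any download.
Per patient and core:

* **Geometry**: circular cores of 1.2 mm diameter, in triplicate, with the
  tissue polygon emitted as the core disc.
* **Cells**: Poisson counts at a configurable density (default 1800
  cells/mm², about 2000 cells per core), positions uniform in the disc.
* **Phenotypes**: drawn from per-patient proportions; the cohort-level
  mixture (62% reserved-class cells, an immune compartment led by
  T-helper cells, CD8 T cells, macrophages, Tregs and PD-1+ subsets) is
  Dirichlet-perturbed per patient with concentration
  `1 / patient_effect_sd^2` (default sd 0.15), creating realistic
  between-patient heterogeneity.
* **Follicles**: three 250 µm discs per core; labels positive for both CD4
  and PD-1 are enriched fourfold inside them by acceptance re-weighting
  (thinning), reproducing the follicular colocalisation of PD-1 with CD4
  and giving the interaction counter spatial structure to chew on. The
  follicle discs are emitted as the CD21 meshwork annotations, which makes
  the area-fraction ground truth analytic.
* **Intensities**: a two-component log-normal per marker — negative
  `lnN(1.0, 0.25)`, positive `lnN(2.0, 0.25)` — i.e. components separated
  by four log-scale standard deviations, with the designated compartment
  drawn from the label's component and the other compartment always
  negative. Bimodality is the minimal structure that makes thresholding
  meaningful; `sim_thresholds()` returns the log-midpoint operating point.
* **Outcomes**: overall survival from a Weibull proportional-hazards model
  (shape 1.2, scale 300 months) whose log hazard is `beta` times the
  patient's standardised true phenotype entropy (default `beta = -1.5`,
  higher diversity protective); independent uniform censoring with the
  bound calibrated so the expected censored fraction equals the configured
  rate (default 0.75, matching a mostly-censored indolent-lymphoma
  cohort); monthly rounding so ties exercise the Efron correction. PFS
  (scale 100 months) and POD24 are generated for the rituximab arm only;
  treatment probabilities are 52/28/20% and FLIPI is drawn 0–5 with 20%
  missingness.

Determinism is a design requirement: every draw comes from a sub-stream
seeded by a hash of `(seed, purpose, patient, core)`, so output is fully
reproducible, and adding a patient never perturbs existing patients' data.
Cohort-level constants (feature standardisation, the censoring bound) are
computed from a fixed-size reference draw on a dedicated sub-stream for the
same reason.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optical effects (bleed-through, autofluorescence),
segmentation errors beyond intensity-component overlap, marker-marker
intensity correlations, irregular tissue and artefact shapes, non-disc
follicles, informative censoring, and covariate-dependent treatment
assignment. Recovery results on synthetic cohorts bound estimator behaviour
under the stated model, not under every failure mode of real staining.

## Numerical and design choices

* Coordinates are continuous µm, image convention (origin top-left, y
  downward); all distances Euclidean between centroids; no edge correction
  at core boundaries.
* Entropies are reported in nats.
* Empty/degenerate cores log warnings and report entropy 0; an empty
  phenotype distribution is a valid state.
* At 4-sd intensity component separation the per-marker mis-call
  probability at the midpoint threshold is `1 - pnorm(2) ≈ 0.023`; exact
  phenotype labels compound this over 5–6 markers, so expected exact-label
  recovery is about 88% (≈ `0.977^5` for immune cells, `0.977^6` for
  reserved classes). This is a property of the stated separation, not of
  the implementation; near-perfect label recovery requires ≥ ~5-sd
  separation.
* The Mann–Whitney test uses the exact distribution where possible and the
  normal approximation with ties, as in standard practice.
* Problem sizes in the shipped checks are chosen to keep the default test
  run comfortably interactive: grid-vs-naive equivalence on 100 random
  cores of up to 500 cells; cutpoint size under a 500-cohort null of 100
  subjects each; Cox recovery over 200 cohorts of 500 patients
  (clinical-level generation); end-to-end determinism on a 24-patient,
  reduced-density cohort — determinism is size-independent.

## Limitations

Single fixed thresholds per marker cannot capture genuinely bimodal
positive populations (e.g. PD-1-high follicular helper vs PD-1-low
exhausted T cells); the package scores what it is given. The interaction
radius is a single global setting per run, not a multi-radius curve. FLIPI
arrives as an ordinal score; it is never reconstructed from raw clinical
variables. And the cutpoint machinery is for display and triage — the Cox
analyses treat features as continuous precisely to avoid leaning on any
particular dichotomisation.
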