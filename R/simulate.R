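# Synthetic TMA cohort generator with known ground truth.
#
# Emulates the study design: 1.2 mm circular cores in triplicate per
# patient; cells as a Poisson point pattern in the core disc; categorical
# phenotypes drawn from Dirichlet-perturbed patient-level proportions over
# the 32 combination codes plus the DAPI_ONLY / CD21_ONLY reserved classes;
# follicle discs enriching selected labels (PD-1+CD4+ colocalisation) by
# acceptance re-weighting; bimodal log-normal marker intensities
# recoverable by midpoint thresholds; and Weibull proportional-hazards
# survival whose log hazard is linear in the patient's true diversity
# feature, with independent uniform censoring.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default phenotype proportions of the synthetic cohort
#'
#' A follicular-lymphoma-like composition: the majority of cells are
#' DAPI-only (tumour B cells and other unstained cells), a small CD21-only
#' class, and an immune compartment dominated by CD4 T-helper cells, CD8
#' T cells, CD68 macrophages, Tregs (CD4+FOXP3+) and PD-1-expressing
#' subsets. Labels not listed have proportion zero.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_phenotype_proportions <- function() {
  c(
    "DAPI_ONLY" = 0.600,
    "CD21_ONLY" = 0.030,
    "CD4+CD8-CD68-FOXP3-PD-1-" = 0.130,
    "CD4-CD8+CD68-FOXP3-PD-1-" = 0.080,
    "CD4-CD8-CD68+FOXP3-PD-1-" = 0.050,
    "CD4+CD8-CD68-FOXP3+PD-1-" = 0.035,
    "CD4+CD8-CD68-FOXP3-PD-1+" = 0.040,
    "CD4-CD8+CD68-FOXP3-PD-1+" = 0.015,
    "CD4+CD8-CD68-FOXP3+PD-1+" = 0.010,
    "CD4-CD8-CD68+FOXP3-PD-1+" = 0.005,
    "CD4+CD8-CD68+FOXP3-PD-1-" = 0.005
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator; the output is
#' fully determined by `(config, seed)`. Defaults mirror the study design:
#' 127 patients, triplicate 1.2 mm cores, roughly 2000 cells per core,
#' three 250 um follicles per core in which CD4+PD-1+ phenotypes are
#' enriched fourfold, log-normal intensity components separated by four
#' standard deviations on the log scale, and Weibull proportional-hazards
#' overall survival with log-HR -1.5 per standardised unit of true
#' phenotype entropy and 75% independent uniform censoring.
#'
#' @param seed Integer master seed; all sub-streams derive from it.
#' @param n_patients Number of patients.
#' @param cores_per_patient Replicate cores per patient (default 3).
#' @param core_diameter_um Core diameter in micrometres (default 1200).
#' @param cell_density_per_mm2 Expected cells per mm^2 of core area.
#' @param phenotype_proportions Named proportions over phenotype labels.
#' @param follicle List: `count`, `radius_um`, `enrichment` (named label ->
#'   acceptance multiplier; `NULL` selects all CD4+PD-1+ codes at 4).
#' @param intensity List: `neg_meanlog`, `neg_sdlog`, `pos_meanlog`,
#'   `pos_sdlog` of the log-normal negative/positive components.
#' @param survival List: `shape`, `scale_months` (Weibull baseline),
#'   `beta` (named log-HRs per feature), `standardise` (use the
#'   standardised true feature in the linear predictor), `censoring_rate`
#'   (target censored fraction in `[0, 1]`), `pfs_scale_months`.
#' @param patient_effect_sd Dispersion of per-patient phenotype
#'   proportions; the Dirichlet concentration is `1 / patient_effect_sd^2`.
#' @param treatment_probs Named probabilities over treatments.
#' @param flipi_probs Probabilities of FLIPI scores 0-5.
#' @param flipi_missing_rate Fraction of patients with missing FLIPI.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 127L,
                       cores_per_patient = 3L,
                       core_diameter_um = 1200,
                       cell_density_per_mm2 = 1800,
                       phenotype_proportions = default_phenotype_proportions(),
                       follicle = list(count = 3L, radius_um = 250, enrichment = NULL),
                       intensity = list(neg_meanlog = 1.0, neg_sdlog = 0.25,
                                        pos_meanlog = 2.0, pos_sdlog = 0.25),
                       survival = list(shape = 1.2, scale_months = 300,
                                       beta = c(phenotype_entropy = -1.5),
                                       standardise = TRUE,
                                       censoring_rate = 0.75,
                                       pfs_scale_months = 100),
                       patient_effect_sd = 0.15,
                       treatment_probs = c(rituximab = 0.52, radiotherapy = 0.28,
                                           surveillance = 0.20),
                       flipi_probs = c(0.14, 0.30, 0.33, 0.13, 0.07, 0.03),
                       flipi_missing_rate = 0.2) {
  levs <- phenotype_levels(default_panel())
  unknown <- setdiff(names(phenotype_proportions), levs)
  if (length(unknown)) {
    abort_config(sprintf("unknown phenotype label(s) in proportions: %s",
                         paste(unknown, collapse = ", ")))
  }
  if (any(phenotype_proportions < 0)) abort_config("phenotype proportions must be non-negative")
  if (abs(sum(phenotype_proportions) - 1) > 1e-8) {
    abort_config("phenotype proportions must sum to 1")
  }
  stopifnot_scalar_num(core_diameter_um, "core_diameter_um", positive = TRUE)
  stopifnot_scalar_num(cell_density_per_mm2, "cell_density_per_mm2", positive = TRUE)
  stopifnot_scalar_num(patient_effect_sd, "patient_effect_sd", positive = TRUE)
  if (is.null(follicle$enrichment)) {
    cd4pd1 <- grep("CD4\\+.*PD-1\\+", levs, value = TRUE)
    follicle$enrichment <- stats::setNames(rep(4, length(cd4pd1)), cd4pd1)
  }
  if (follicle$count > 0) stopifnot_scalar_num(follicle$radius_um, "follicle$radius_um", positive = TRUE)
  sv <- survival
  if (sv$censoring_rate < 0 || sv$censoring_rate > 1) {
    abort_config("survival$censoring_rate must be in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         cores_per_patient = as.integer(cores_per_patient),
         core_diameter_um = core_diameter_um,
         cell_density_per_mm2 = cell_density_per_mm2,
         phenotype_proportions = phenotype_proportions,
         follicle = follicle, intensity = intensity, survival = sv,
         patient_effect_sd = patient_effect_sd,
         treatment_probs = treatment_probs, flipi_probs = flipi_probs,
         flipi_missing_rate = flipi_missing_rate),
    class = "sim_config"
  )
}

#' Positivity thresholds matching a simulation's intensity model
#'
#' The midpoint (on the log scale) between the negative and positive
#' intensity components, the natural operating point for scoring simulated
#' cells.
#'
#' @param config A [sim_config()].
#' @return Named threshold vector for [default_panel()].
#' @export
sim_thresholds <- function(config) {
  mid <- exp((config$intensity$neg_meanlog + config$intensity$pos_meanlog) / 2)
  c(CD4 = mid, CD8 = mid, CD68 = mid, FOXP3 = mid, `PD-1` = mid, CD21 = mid)
}

# which markers are positive under a label (for intensity generation)
label_marker_positive <- function(labels, marker) {
  if (marker == "CD21") return(labels == "CD21_ONLY")
  if (marker == "DAPI") return(rep(TRUE, length(labels)))
  grepl(paste0(marker, "+"), labels, fixed = TRUE)
}

# per-patient Dirichlet draw around the configured proportions
draw_patient_proportions <- function(config, patient_id) {
  conc <- 1 / config$patient_effect_sd^2
  base <- config$phenotype_proportions
  with_seed(derive_seed(config$seed, "props", patient_id), {
    g <- stats::rgamma(length(base), shape = base * conc, rate = 1)
    if (sum(g) <= 0) base else stats::setNames(g / sum(g), names(base))
  })
}

# plug-in entropy of a proportion vector after removing reserved labels
true_phenotype_entropy <- function(props,
                                   exclusions = c("DAPI_ONLY", "CD21_ONLY")) {
  shannon_entropy(props[!names(props) %in% exclusions])
}

#' Generate one synthetic TMA core
#'
#' Cell count is Poisson with mean density x core area; positions are
#' uniform in the core disc, except that labels with a follicle enrichment
#' multiplier are thinned (acceptance re-weighting) towards the follicle
#' discs. Marker intensities are drawn from the positive or negative
#' log-normal component according to the cell's label on the marker's
#' designated compartment; the other compartment is always drawn from the
#' negative component.
#'
#' @param config A [sim_config()].
#' @param patient_id Patient identifier string.
#' @param core_index Replicate index (1-based).
#' @param patient_props Optional per-patient proportions (drawn from the
#'   patient's Dirichlet stream when omitted).
#' @return List with `cells` (intensity table rows), `annotations`
#'   (tissue + cd21_meshwork polygons) and `truth` (generating proportions
#'   and their plug-in entropy).
#' @export
simulate_core <- function(config, patient_id, core_index,
                          patient_props = NULL) {
  if (is.null(patient_props)) patient_props <- draw_patient_proportions(config, patient_id)
  R <- config$core_diameter_um / 2
  area_mm2 <- pi * R^2 / 1e6
  core_id <- sprintf("%s_c%d", patient_id, core_index)
  panel <- default_panel()
  with_seed(derive_seed(config$seed, "core", patient_id, core_index), {
    n <- stats::rpois(1L, config$cell_density_per_mm2 * area_mm2)
    labels <- sample(names(patient_props), n, replace = TRUE, prob = patient_props)
    # follicle discs (kept fully inside the core)
    nf <- config$follicle$count
    fr <- config$follicle$radius_um
    if (nf > 0) {
      rr <- (R - fr) * sqrt(stats::runif(nf)); th <- stats::runif(nf, 0, 2 * pi)
      fx <- R + rr * cos(th); fy <- R + rr * sin(th)
    } else fx <- fy <- numeric(0)
    runif_disc <- function(m) {
      rad <- R * sqrt(stats::runif(m)); ang <- stats::runif(m, 0, 2 * pi)
      list(x = R + rad * cos(ang), y = R + rad * sin(ang))
    }
    in_follicle <- function(x, y) {
      if (!length(fx)) return(rep(FALSE, length(x)))
      inside <- rep(FALSE, length(x))
      for (k in seq_along(fx)) {
        inside <- inside | ((x - fx[k])^2 + (y - fy[k])^2 <= fr^2)
      }
      inside
    }
    enr <- config$follicle$enrichment
    mult <- ifelse(labels %in% names(enr), enr[labels], 1)
    x <- y <- numeric(n)
    pending <- seq_len(n)
    while (length(pending)) {
      pos <- runif_disc(length(pending))
      w <- ifelse(in_follicle(pos$x, pos$y), mult[pending], 1)
      acc <- stats::runif(length(pending)) <= w / pmax(mult[pending], 1)
      x[pending[acc]] <- pos$x[acc]
      y[pending[acc]] <- pos$y[acc]
      pending <- pending[!acc]
    }
    # intensities: designated compartment from the label's component,
    # opposite compartment from the negative component
    it <- config$intensity
    cells <- tibble::tibble(
      cell_id = sprintf("%s_%05d", core_id, seq_len(n)),
      core_id = core_id, patient_id = patient_id,
      x_um = x, y_um = y
    )
    cells[["DAPI:nucleus"]] <- stats::rlnorm(n, it$pos_meanlog, it$pos_sdlog)
    for (m in names(panel$compartment)) {
      pos_m <- label_marker_positive(labels, m)
      meanlog <- ifelse(pos_m, it$pos_meanlog, it$neg_meanlog)
      sdlog <- ifelse(pos_m, it$pos_sdlog, it$neg_sdlog)
      desig <- paste0(m, ":", panel$compartment[[m]])
      other <- paste0(m, ":", setdiff(c("nucleus", "membrane"), panel$compartment[[m]]))
      cells[[desig]] <- stats::rlnorm(n, meanlog, sdlog)
      cells[[other]] <- stats::rlnorm(n, it$neg_meanlog, it$neg_sdlog)
    }
    ann <- dplyr::bind_rows(
      tibble::tibble(core_id = core_id, role = "tissue",
                     polygon = list(circle_poly(R, R, R))),
      if (length(fx)) dplyr::bind_rows(lapply(seq_along(fx), function(k) {
        tibble::tibble(core_id = core_id, role = "cd21_meshwork",
                       polygon = list(circle_poly(fx[k], fy[k], fr)))
      }))
    )
    list(
      cells = cells,
      annotations = ann,
      truth = list(core_id = core_id, patient_id = patient_id,
                   labels = labels, proportions = patient_props,
                   true_entropy = true_phenotype_entropy(patient_props),
                   follicles = list(x = fx, y = fy, r = fr))
    )
  })
}

# reference draw of event times used to fix cohort-independent constants
# (feature standardisation and the uniform censoring bound), so adding a
# patient never perturbs existing patients' outcomes
reference_constants <- function(config, n_ref = 2000L) {
  sv <- config$survival
  with_seed(derive_seed(config$seed, "reference"), {
    conc <- 1 / config$patient_effect_sd^2
    base <- config$phenotype_proportions
    f <- vapply(seq_len(n_ref), function(i) {
      g <- stats::rgamma(length(base), shape = base * conc, rate = 1)
      true_phenotype_entropy(stats::setNames(g / sum(g), names(base)))
    }, numeric(1))
    mu <- mean(f); sdv <- stats::sd(f)
    z <- if (isTRUE(sv$standardise)) (f - mu) / sdv else f
    beta <- sv$beta[["phenotype_entropy"]] %||% 0
    lp <- beta * z
    u <- stats::runif(n_ref)
    t_ref <- sv$scale_months * (-log(u) / exp(lp))^(1 / sv$shape)
    cmax <- if (sv$censoring_rate <= 0) Inf else if (sv$censoring_rate >= 1) 0 else {
      fn <- function(m) mean(pmin(t_ref, m)) / m - sv$censoring_rate
      stats::uniroot(fn, lower = 1e-6, upper = max(t_ref) * 1e3,
                     extendInt = "downX")$root
    }
    list(feature_mean = mu, feature_sd = sdv, cens_max = cmax)
  })
}

#' Generate a full synthetic cohort with linked clinical outcomes
#'
#' Per patient: `cores_per_patient` cores (optional), a treatment arm,
#' a FLIPI score with missingness, and survival outcomes from a Weibull
#' proportional-hazards model whose linear predictor is the configured
#' log-HR times the patient's (standardised) true phenotype entropy, with
#' independent uniform censoring calibrated to the configured censored
#' fraction. PFS and POD24 are generated for the rituximab arm only;
#' POD24 is a progression event within 24 months, defined only for
#' patients with at least 24 months of follow-up or an earlier event.
#'
#' Every random draw comes from a sub-stream derived from `(seed, patient,
#' core)`, so the output is fully deterministic and adding a patient never
#' changes the data of existing patients.
#'
#' @param config A [sim_config()].
#' @param cells Generate cell tables and annotations (set `FALSE` for a
#'   clinical-only cohort where the true features stand in for measured
#'   ones, e.g. in estimator-calibration studies).
#' @return Object of class `sim_cohort`: tibbles `cells`, `annotations`,
#'   `clinical`, `truth`, plus the `config`.
#' @export
simulate_cohort <- function(config, cells = TRUE) {
  if (!inherits(config, "sim_config")) abort_config("config must be a sim_config")
  # re-validate key invariants in case the config was edited after construction
  pp <- config$phenotype_proportions
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-8) {
    abort_config("phenotype proportions must be non-negative and sum to 1")
  }
  ref <- reference_constants(config)
  sv <- config$survival
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  truth_rows <- list(); clin_rows <- list()
  cell_tabs <- list(); ann_tabs <- list()
  for (pid in ids) {
    props <- draw_patient_proportions(config, pid)
    f <- true_phenotype_entropy(props)
    z <- if (isTRUE(sv$standardise)) (f - ref$feature_mean) / ref$feature_sd else f
    beta <- sv$beta[["phenotype_entropy"]] %||% 0
    lp <- beta * z
    clin <- with_seed(derive_seed(config$seed, "clinical", pid), {
      treatment <- sample(names(config$treatment_probs), 1, prob = config$treatment_probs)
      flipi <- sample(0:5, 1, prob = config$flipi_probs)
      if (stats::runif(1) < config$flipi_missing_rate) flipi <- NA_integer_
      t_os <- sv$scale_months * (-log(stats::runif(1)) / exp(lp))^(1 / sv$shape)
      cens <- if (is.infinite(ref$cens_max)) Inf
              else if (ref$cens_max == 0) stats::runif(1, 0, sv$scale_months)
              else stats::runif(1, 0, ref$cens_max)
      all_censored <- sv$censoring_rate >= 1
      os_event <- if (all_censored) 0L else as.integer(t_os <= cens)
      os_months <- max(1, round(if (all_censored) cens else min(t_os, cens)))
      if (treatment == "rituximab") {
        t_prog <- sv$pfs_scale_months * (-log(stats::runif(1)) / exp(lp))^(1 / sv$shape)
        t_pfs <- min(t_prog, t_os)
        pfs_event <- if (all_censored) 0L else as.integer(t_pfs <= cens)
        pfs_months <- max(1, round(if (all_censored) cens else min(t_pfs, cens)))
        pod24 <- if (pfs_event == 1L && pfs_months <= 24) TRUE
                 else if (os_months >= 24) FALSE else NA
      } else {
        pfs_months <- NA_real_; pfs_event <- NA_integer_; pod24 <- NA
      }
      tibble::tibble(
        patient_id = pid, treatment = treatment, flipi = flipi,
        os_months = os_months, os_event = os_event,
        pfs_months = pfs_months, pfs_event = pfs_event,
        pod24 = pod24, followup_months = os_months
      )
    })
    clin_rows[[pid]] <- clin
    truth_rows[[pid]] <- tibble::tibble(
      patient_id = pid,
      true_phenotype_entropy = f,
      z_phenotype_entropy = z,
      log_hazard = lp,
      proportions = list(props)
    )
    if (cells) {
      for (k in seq_len(config$cores_per_patient)) {
        core <- simulate_core(config, pid, k, patient_props = props)
        cell_tabs[[core$truth$core_id]] <- core$cells
        ann_tabs[[core$truth$core_id]] <- core$annotations
      }
    }
  }
  structure(
    list(
      cells = if (cells) dplyr::bind_rows(cell_tabs) else NULL,
      annotations = if (cells) dplyr::bind_rows(ann_tabs) else NULL,
      clinical = dplyr::bind_rows(clin_rows),
      truth = dplyr::bind_rows(truth_rows),
      config = config,
      reference = ref
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d patients, %s cells\n",
              nrow(x$clinical),
              if (is.null(x$cells)) "no" else format(nrow(x$cells), big.mark = ",")))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits the cell table CSV, GeoJSON annotations, clinical CSV and a
#' ground-truth JSON into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = cohort$config$seed,
               config_hash = config_hash(unclass(cohort$config)))
  paths <- c(
    cells = file.path(dir, "cells.csv"),
    annotations = file.path(dir, "annotations.geojson"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.json"),
    panel = file.path(dir, "panel.yaml")
  )
  # matching scoring config: midpoint thresholds for the intensity model
  thr <- sim_thresholds(cohort$config)
  pnl <- default_panel(threshold = thr)
  yaml::write_yaml(
    list(markers = lapply(stats::setNames(nm = names(pnl$compartment)), function(m) {
      list(compartment = unname(pnl$compartment[[m]]),
           threshold = unname(thr[[m]]))
    })),
    paths["panel"]
  )
  if (!is.null(cohort$cells)) write_cell_table(cohort$cells, paths["cells"], meta)
  if (!is.null(cohort$annotations)) write_annotations(cohort$annotations, paths["annotations"])
  write_meta_csv(cohort$clinical, paths["clinical"], meta)
  truth <- cohort$truth
  truth$proportions <- lapply(truth$proportions, as.list)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         config_hash = config_hash(unclass(cohort$config)),
         patients = truth),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
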