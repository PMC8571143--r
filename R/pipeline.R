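# File-level pipeline: simulate -> score -> diversity -> survival.
# Each stage reads and writes the package's CSV/GeoJSON dialects so
# intermediate results are inspectable; every output carries a metadata
# header (package version, seed, config hash) sufficient to reproduce it.

#' Score and phenotype a cell table file
#'
#' @param cell_table Path to the input cell-table CSV.
#' @param out Path for the scored output CSV.
#' @param panel A [marker_panel()] or path to a panel YAML/JSON config.
#' @param quiet Suppress progress notices.
#' @return `out`, invisibly.
#' @export
run_score <- function(cell_table, out, panel = default_panel(), quiet = FALSE) {
  if (is.character(panel)) panel <- read_panel_config(panel)
  cells <- read_cell_table(cell_table, panel)
  cells <- score_cells(cells, panel)
  cells <- assign_phenotypes(cells, panel)
  if (!quiet) {
    for (m in names(panel$compartment)) {
      frac <- mean(cells[[paste0(m, "_pos")]])
      message(sprintf("  %-6s positive fraction: %.3f", m, frac))
    }
  }
  write_cell_table(cells, out, meta = list(
    stage = "score",
    panel_hash = config_hash(unclass(panel)),
    n_cells = nrow(cells)
  ))
  invisible(out)
}

#' Compute per-core diversity features from a scored cell table
#'
#' @param scored_table Path to a scored cell table (from [run_score()]).
#' @param out Path for the per-core features CSV.
#' @param annotations Optional path to a GeoJSON annotation file.
#' @param tissue_area_mm2 Fallback per-core area when no annotations.
#' @param radius_um Interaction radius (recorded in the output header).
#' @param interactions_out Optional path for the long-format interaction
#'   counts CSV (`core_id`, `label_i`, `label_j`, `n`, `p`).
#' @param ... Passed to [profile_cores()].
#' @return `out`, invisibly.
#' @export
run_diversity <- function(scored_table, out, annotations = NULL,
                          tissue_area_mm2 = NULL, radius_um = 30,
                          interactions_out = NULL, ...) {
  cells <- read_cell_table(scored_table)
  pos_cols <- grep("_pos$", names(cells), value = TRUE)
  if (!length(pos_cols) || !"phenotype" %in% names(cells)) {
    abort_data("input is not a scored cell table (run score first)",
               class = "entrotme_state_error")
  }
  ann <- if (!is.null(annotations)) read_annotations(annotations) else NULL
  profiles <- profile_cores(cells, annotations = ann,
                            tissue_area_mm2 = tissue_area_mm2,
                            radius_um = radius_um, ...)
  write_core_features(profiles, out, meta = list(
    stage = "diversity", radius_um = radius_um, n_cores = nrow(profiles)
  ))
  if (!is.null(interactions_out)) {
    long <- dplyr::bind_rows(lapply(unique(cells$core_id), function(cid) {
      ic <- count_interactions(cells[cells$core_id == cid, ], radius_um = radius_um)
      if (nrow(ic)) tibble::add_column(ic, core_id = cid, .before = 1)
    }))
    write_meta_csv(long, interactions_out,
                   meta = list(stage = "diversity", radius_um = radius_um))
  }
  invisible(out)
}

#' Patient-level survival and association analysis
#'
#' Aggregates per-core features to patients (median of replicates), joins
#' the clinical table, and runs the full statistical layer: univariable
#' Cox models for OS (all patients) and PFS (subset selected by
#' `pfs_subset`), FLIPI-adjusted multivariable models, Contal-O'Quigley
#' optimal cutpoints for the diversity indices with Kaplan-Meier log-rank
#' p-values, POD24 Mann-Whitney and logistic models, intra-patient CoV,
#' and Bonferroni flags over the feature family.
#'
#' @param features Path to the per-core features CSV.
#' @param clinical Path to the clinical CSV.
#' @param out_dir Output directory for result CSVs and the run log.
#' @param feature_cols Feature columns to analyse; defaults to the
#'   diversity indices, immune ratio, CD21 area fraction and densities
#'   found in the file.
#' @param cutpoint_features Features receiving cutpoint/KM analysis.
#' @param alpha Family-wise significance level for Bonferroni.
#' @param min_group_frac Minimum group fraction for candidate cuts.
#' @param pfs_subset,pod24_subset Filter expressions (strings evaluated in
#'   the clinical table) selecting the PFS/POD24 analysis cohorts.
#' @return Named vector of written file paths, invisibly.
#' @export
run_survival <- function(features, clinical, out_dir,
                         feature_cols = NULL,
                         cutpoint_features = c("phenotype_entropy", "interaction_entropy"),
                         alpha = 0.05, min_group_frac = 0.1,
                         pfs_subset = "treatment == 'rituximab'",
                         pod24_subset = "treatment == 'rituximab'") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof <- read_meta_csv(features)
  clin <- read_clinical_table(clinical)
  if (is.null(feature_cols)) {
    cand <- c("phenotype_entropy", "interaction_entropy", "immune_ratio",
              "cd21_area_fraction", grep("^density_", names(prof), value = TRUE))
    feature_cols <- cand[cand %in% names(prof)]
    feature_cols <- feature_cols[vapply(feature_cols,
                                        function(f) !all(is.na(prof[[f]])), logical(1))]
  }
  patients <- aggregate_patients(prof, features = feature_cols)
  data <- dplyr::inner_join(patients, clin, by = "patient_id")
  log_lines <- c(
    sprintf("patients with cores: %d", nrow(patients)),
    sprintf("patients with clinical data: %d", nrow(clin)),
    sprintf("patients analysed: %d", nrow(data)),
    sprintf("features: %s", paste(feature_cols, collapse = ", "))
  )
  pfs_data <- data[with(data, eval(parse(text = pfs_subset))) %in% TRUE &
                     !is.na(data$pfs_months), , drop = FALSE]
  pod_data <- data[with(data, eval(parse(text = pod24_subset))) %in% TRUE, , drop = FALSE]

  uni_os <- cox_fit(data, "os", feature_cols, adjust_flipi = FALSE)
  uni <- dplyr::mutate(tidy(uni_os), endpoint = "os", model = "univariable")
  if (nrow(pfs_data) && sum(pfs_data$pfs_event, na.rm = TRUE) > 0) {
    uni_pfs <- cox_fit(pfs_data, "pfs", feature_cols, adjust_flipi = FALSE)
    uni <- dplyr::bind_rows(uni, dplyr::mutate(tidy(uni_pfs),
                                               endpoint = "pfs", model = "univariable"))
  } else {
    log_lines <- c(log_lines, "PFS analysis skipped: no eligible events")
  }
  fam <- bonferroni_adjust(uni$p[uni$term == uni$feature & uni$endpoint == "os"], alpha)
  uni$p_bonferroni_threshold <- fam$threshold[1]
  uni$bonferroni_significant <- uni$p <= fam$threshold[1]

  multi <- NULL
  if ("flipi" %in% names(data) && any(!is.na(data$flipi))) {
    mult_os <- cox_fit(data, "os", feature_cols, adjust_flipi = TRUE)
    multi <- dplyr::mutate(tidy(mult_os), endpoint = "os", model = "flipi_adjusted")
    n_flipi <- sum(!is.na(data$flipi))
    log_lines <- c(log_lines,
                   sprintf("multivariable OS: %d of %d patients with FLIPI", n_flipi, nrow(data)))
    if (nrow(pfs_data) && sum(!is.na(pfs_data$flipi)) > 2 &&
        sum(pfs_data$pfs_event[!is.na(pfs_data$flipi)], na.rm = TRUE) > 0) {
      mult_pfs <- cox_fit(pfs_data, "pfs", feature_cols, adjust_flipi = TRUE)
      multi <- dplyr::bind_rows(multi, dplyr::mutate(tidy(mult_pfs),
                                                     endpoint = "pfs", model = "flipi_adjusted"))
    }
    multi$p_bonferroni_threshold <- fam$threshold[1]
    multi$bonferroni_significant <- multi$p <= fam$threshold[1]
  } else {
    log_lines <- c(log_lines, "multivariable analysis skipped: no FLIPI data")
  }

  cuts <- dplyr::bind_rows(lapply(cutpoint_features, function(f) {
    cp <- contal_oquigley_cutpoint(data[[f]], data$os_months, data$os_event,
                                   min_group_frac = min_group_frac)
    grp <- split_at_cutpoint(data[[f]], cp$cut_value)
    km <- km_curves(dplyr::mutate(data, .grp = grp), "os", ".grp")
    tibble::tibble(
      feature = f, endpoint = "os", cut = cp$cut_value,
      q_statistic = cp$q_statistic, p_logrank = cp$p_logrank,
      p_adjusted = cp$p_adjusted,
      group_fraction_high = cp$group_fraction_high,
      km_logrank_p = km$logrank_p,
      n = cp$n, n_events = cp$n_events
    )
  }))

  pod <- NULL
  if (nrow(pod_data) && sum(!is.na(pod_data$pod24)) > 0 &&
      length(unique(stats::na.omit(pod_data$pod24))) == 2) {
    pod <- pod24_tests(pod_data, feature_cols, adjust_flipi = TRUE)
  } else {
    log_lines <- c(log_lines, "POD24 analysis skipped: outcome missing or single-class")
  }

  cov <- dplyr::bind_rows(lapply(feature_cols, function(f) {
    cc <- suppressMessages(intra_patient_cov(prof, f))
    tibble::tibble(feature = f, n_patients = nrow(cc),
                   median_cov_pct = attr(cc, "cohort_median_cov"))
  }))

  meta <- list(stage = "survival", alpha = alpha, min_group_frac = min_group_frac)
  paths <- c(univariable = file.path(out_dir, "univariable.csv"),
             multivariable = file.path(out_dir, "multivariable.csv"),
             cutpoints = file.path(out_dir, "cutpoints.csv"),
             pod24 = file.path(out_dir, "pod24.csv"),
             cov = file.path(out_dir, "cov.csv"),
             log = file.path(out_dir, "run_log.txt"))
  write_meta_csv(uni, paths["univariable"], meta)
  if (!is.null(multi)) write_meta_csv(multi, paths["multivariable"], meta)
  write_meta_csv(cuts, paths["cutpoints"], meta)
  if (!is.null(pod)) write_meta_csv(pod, paths["pod24"], meta)
  write_meta_csv(cov, paths["cov"], meta)
  writeLines(log_lines, paths["log"])
  invisible(paths)
}

#' Simulate a synthetic cohort to disk
#'
#' @param config A [sim_config()] (validated before any file is written).
#' @param out_dir Output directory.
#' @param cells Generate cell-level data.
#' @return Named vector of file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, cells = TRUE) {
  if (!inherits(config, "sim_config")) abort_config("config must be a sim_config")
  cohort <- simulate_cohort(config, cells = cells)
  write_cohort(cohort, out_dir)
}

#' Run the full pipeline end to end
#'
#' `simulate -> score -> diversity -> survival` on a synthetic cohort,
#' with thresholds at the midpoint of the simulation's intensity
#' components. Deterministic: the same config yields byte-identical output
#' files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; sub-directory `results/` receives the
#'   statistical outputs.
#' @param radius_um Interaction radius.
#' @param quiet Suppress notices.
#' @return Named vector of result paths, invisibly.
#' @export
run_all <- function(config, out_dir, radius_um = 30, quiet = TRUE) {
  sim_paths <- run_simulate(config, out_dir)
  panel <- default_panel(threshold = sim_thresholds(config))
  scored <- file.path(out_dir, "cells_scored.csv")
  feats <- file.path(out_dir, "core_features.csv")
  if (quiet) {
    suppressMessages(run_score(sim_paths["cells"], scored, panel, quiet = TRUE))
    suppressWarnings(suppressMessages(
      run_diversity(scored, feats, annotations = sim_paths["annotations"],
                    radius_um = radius_um)))
    res <- suppressMessages(run_survival(feats, sim_paths["clinical"],
                                         file.path(out_dir, "results")))
  } else {
    run_score(sim_paths["cells"], scored, panel)
    run_diversity(scored, feats, annotations = sim_paths["annotations"],
                  radius_um = radius_um)
    res <- run_survival(feats, sim_paths["clinical"], file.path(out_dir, "results"))
  }
  invisible(c(sim_paths, scored = scored, features = feats, res))
}
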