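small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_patients = 4, cell_density_per_mm2 = 300, ...)
}

test_that("simulation is deterministic and streams are independent per patient", {
  co1 <- simulate_cohort(small_cfg(seed = 5))
  co2 <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(co1$cells, co2$cells)
  expect_identical(co1$clinical, co2$clinical)
  # different seed -> different data
  co3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(co1$cells$x_um, co3$cells$x_um))
  # adding a patient leaves existing patients untouched
  co5 <- simulate_cohort(sim_config(seed = 5, n_patients = 5,
                                    cell_density_per_mm2 = 300))
  ids4 <- co1$clinical$patient_id
  expect_identical(co1$cells, co5$cells[co5$cells$patient_id %in% ids4, ])
  expect_identical(co1$clinical, co5$clinical[co5$clinical$patient_id %in% ids4, ])
})

test_that("core structure matches the configured design", {
  cfg <- small_cfg(seed = 2)
  co <- simulate_cohort(cfg)
  expect_equal(length(unique(co$cells$core_id)), 4 * 3)  # triplicates
  R <- cfg$core_diameter_um / 2
  r2 <- (co$cells$x_um - R)^2 + (co$cells$y_um - R)^2
  expect_true(all(r2 <= R^2 + 1e-6))
  # tissue + follicle annotations per core
  ann <- co$annotations
  expect_equal(sum(ann$role == "tissue"), 12)
  expect_equal(sum(ann$role == "cd21_meshwork"), 12 * cfg$follicle$count)
  # follicle discs make the cd21 area fraction analytic (non-overlap not
  # guaranteed, so it is bounded by count * (r_f / R)^2)
  g <- core_geometry(ann)
  expect_true(all(g$cd21_area_fraction > 0))
  expect_true(all(g$cd21_area_fraction <= 3 * (250 / 600)^2 + 0.01))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(phenotype_proportions = c(DAPI_ONLY = 0.5)), "sum to 1")
  expect_error(sim_config(phenotype_proportions = c(BAD = 1)), "unknown")
  bad <- small_cfg()
  bad$phenotype_proportions["DAPI_ONLY"] <- 0.9
  expect_error(simulate_cohort(bad), "sum to 1")
  expect_error(sim_config(cell_density_per_mm2 = -5), "positive")
})

test_that("empirical phenotype proportions converge to the configured ones", {
  cfg <- sim_config(seed = 3, n_patients = 1, cores_per_patient = 1,
                    cell_density_per_mm2 = 4000,
                    patient_effect_sd = 1e-4)  # pin patient props to the base
  core <- simulate_core(cfg, "P001", 1)
  labs <- core$truth$labels
  n <- length(labs)
  base <- cfg$phenotype_proportions
  for (l in names(base)[base > 0.02]) {
    p_hat <- mean(labs == l)
    expect_lt(abs(p_hat - base[[l]]),
              3 * sqrt(base[[l]] * (1 - base[[l]]) / n) + 3 * 1e-3)
  }
})

test_that("midpoint thresholds recover most generated labels", {
  cfg <- sim_config(seed = 4, n_patients = 2, cell_density_per_mm2 = 1200)
  co <- simulate_cohort(cfg)
  truth_labels <- unlist(lapply(co$truth$patient_id, function(pid) {
    lapply(1:3, function(k) simulate_core(cfg, pid, k)$truth$labels)
  }))
  panel <- default_panel(threshold = sim_thresholds(cfg))
  cells <- assign_phenotypes(score_cells(co$cells, panel), panel)
  recovery <- mean(cells$phenotype == truth_labels)
  # 4-sd component separation: per-marker error 1 - pnorm(2), label error
  # compounds over 5-6 markers -> expect ~0.88 exact-label recovery
  expect_gt(recovery, 0.84)
  analytic <- {
    e <- 1 - stats::pnorm(2)
    base <- cfg$phenotype_proportions
    reserved <- names(base) %in% c("DAPI_ONLY", "CD21_ONLY")
    sum(base[reserved]) * (1 - e)^6 + sum(base[!reserved]) * (1 - e)^5
  }
  expect_equal(recovery, analytic, tolerance = 0.03)
})

test_that("without enrichment each label's positions pass a CSR quadrat check", {
  cfg <- sim_config(seed = 19, n_patients = 1, cores_per_patient = 1,
                    cell_density_per_mm2 = 3000,
                    follicle = list(count = 0L, radius_um = 250, enrichment = NULL))
  core <- simulate_core(cfg, "P001", 1)
  cells <- core$cells
  R <- cfg$core_diameter_um / 2
  half <- R / sqrt(2)  # inscribed square
  quadrat_p <- function(idx) {
    x <- cells$x_um[idx]; y <- cells$y_um[idx]
    inside <- abs(x - R) < half & abs(y - R) < half
    gx <- cut(x[inside], seq(R - half, R + half, length.out = 5))
    gy <- cut(y[inside], seq(R - half, R + half, length.out = 5))
    counts <- as.vector(table(gx, gy))
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }
  expect_gt(quadrat_p(seq_len(nrow(cells))), 0.01)
  big_labels <- names(sort(table(core$truth$labels), decreasing = TRUE))[1:3]
  for (l in big_labels) {
    expect_gt(quadrat_p(which(core$truth$labels == l)), 0.01)
  }
})

test_that("follicle enrichment concentrates CD4+PD-1+ cells in the meshwork discs", {
  cfg <- sim_config(seed = 20, n_patients = 1, cores_per_patient = 1,
                    cell_density_per_mm2 = 3000)
  core <- simulate_core(cfg, "P001", 1)
  fol <- core$truth$follicles
  in_fol <- rep(FALSE, nrow(core$cells))
  for (k in seq_along(fol$x)) {
    in_fol <- in_fol | ((core$cells$x_um - fol$x[k])^2 +
                          (core$cells$y_um - fol$y[k])^2 <= fol$r^2)
  }
  enriched <- grepl("CD4\\+.*PD-1\\+", core$truth$labels)
  frac_enriched <- mean(in_fol[enriched])
  frac_other <- mean(in_fol[!enriched])
  expect_gt(frac_enriched, 1.5 * frac_other)
})

test_that("plug-in entropy is biased low at small n and converges with n", {
  base <- default_phenotype_proportions()
  keep <- !(names(base) %in% c("DAPI_ONLY", "CD21_ONLY"))
  p <- base[keep] / sum(base[keep])
  h_true <- shannon_entropy(p)
  mean_plugin <- function(n, reps = 200) {
    withr::with_seed(40 + n, {
      mean(vapply(seq_len(reps), function(i) {
        shannon_entropy(table(sample(names(p), n, TRUE, prob = p)))
      }, numeric(1)))
    })
  }
  h50 <- mean_plugin(50); h500 <- mean_plugin(500); h5000 <- mean_plugin(5000)
  expect_lt(h50, h_true)
  expect_lt(h50, h500)
  expect_lt(h500, h5000)
  expect_lt(abs(h5000 - h_true), 0.01)
})

test_that("survival linkage produces the configured censoring and POD24 logic", {
  cfg <- sim_config(seed = 21, n_patients = 400)
  co <- simulate_cohort(cfg, cells = FALSE)
  cl <- co$clinical
  expect_equal(mean(cl$os_event == 0), cfg$survival$censoring_rate, tolerance = 0.07)
  # PFS only for the rituximab arm
  expect_true(all(is.na(cl$pfs_months[cl$treatment != "rituximab"])))
  rit <- cl[cl$treatment == "rituximab", ]
  expect_true(any(!is.na(rit$pfs_months)))
  # POD24 flag consistency with PFS and follow-up
  flagged <- rit[!is.na(rit$pod24) & rit$pod24, ]
  expect_true(all(flagged$pfs_event == 1 & flagged$pfs_months <= 24))
  unflagged <- rit[!is.na(rit$pod24) & !rit$pod24, ]
  expect_true(all(unflagged$followup_months >= 24 |
                    (unflagged$pfs_event == 1 & unflagged$pfs_months > 24)))
  undefined <- rit[is.na(rit$pod24), ]
  expect_true(all(undefined$followup_months < 24))
})

test_that("full censoring yields a clean downstream fit error", {
  cfg <- small_cfg(seed = 22,
                   survival = list(shape = 1.2, scale_months = 300,
                                   beta = c(phenotype_entropy = -1.5),
                                   standardise = TRUE, censoring_rate = 1,
                                   pfs_scale_months = 100))
  co <- simulate_cohort(cfg, cells = FALSE)
  expect_true(all(co$clinical$os_event == 0))
  d <- dplyr::inner_join(co$clinical, co$truth, by = "patient_id")
  expect_error(cox_fit(d, "os", "true_phenotype_entropy"),
               class = "entrotme_fit_error")
})
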