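#' Default density subsets reported per core
#'
#' The six immune cell subsets whose densities are reported alongside the
#' diversity indices: T-helper cells (CD4+CD68-), Tregs (CD4+FOXP3+),
#' cytotoxic T cells (CD8+), macrophages (CD68+), and the PD-1-expressing
#' subsets CD4+CD68-PD-1+ and CD8+PD-1+.
#'
#' @return Character vector of subset specifications.
#' @export
default_density_subsets <- function() {
  c("CD4+CD68-", "CD4+FOXP3+", "CD8+", "CD68+", "CD4+CD68-PD-1+", "CD8+PD-1+")
}

#' Per-core diversity profile
#'
#' Bundles the per-core feature extraction: phenotype Shannon entropy,
#' spatial-interaction entropy at the given radius, immune infiltrate
#' ratio, cell-subset densities, and (when annotations are supplied) tissue
#' area and CD21+ meshwork area fraction. One row per core.
#'
#' Cells are first restricted to the analysable tissue region when
#' annotations are available. Degenerate cores (fewer than two included
#' cells or no counted pairs) get entropy 0 with a warning.
#'
#' @param cells Scored and phenotyped cell tibble (may span many cores);
#'   must have `core_id`, and `patient_id` is carried through if present.
#' @param annotations Optional annotation tibble (see [read_annotations()]).
#'   When omitted, `tissue_area_mm2` must be given.
#' @param tissue_area_mm2 Named vector of per-core areas (or a single value
#'   recycled to all cores); ignored when `annotations` is supplied.
#' @param panel A [marker_panel()].
#' @param radius_um Interaction radius in micrometres.
#' @param phenotype_exclusions Labels excluded from phenotype entropy.
#' @param interaction_exclusions Labels excluded from interaction counting.
#' @param density_subsets Character vector of subset specifications.
#' @return A tibble with one row per core: identifiers, `n_cells`,
#'   `n_cells_included`, `phenotype_entropy`, `interaction_entropy`,
#'   `n_pairs`, `immune_ratio`, one `density_<subset>` column per subset,
#'   `tissue_area_mm2`, `cd21_area_fraction`.
#' @export
profile_cores <- function(cells, annotations = NULL, tissue_area_mm2 = NULL,
                          panel = default_panel(), radius_um = 30,
                          phenotype_exclusions = c("DAPI_ONLY", "CD21_ONLY"),
                          interaction_exclusions = "DAPI_ONLY",
                          density_subsets = default_density_subsets()) {
  if (!"phenotype" %in% names(cells)) {
    abort_data("cells must be phenotyped (run assign_phenotypes first)",
               class = "entrotme_state_error")
  }
  geom <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    cells <- filter_cells_to_tissue(cells, annotations)
    geom <- core_geometry(annotations)
  } else if (is.null(tissue_area_mm2)) {
    abort_config("either `annotations` or `tissue_area_mm2` must be supplied")
  }
  core_ids <- unique(cells$core_id)
  rows <- lapply(core_ids, function(cid) {
    cc <- cells[cells$core_id == cid, , drop = FALSE]
    area <- if (!is.null(geom)) {
      g <- geom[geom$core_id == cid, ]
      if (!nrow(g)) abort_data(sprintf("no annotations for core %s", cid))
      g$tissue_area_mm2
    } else if (!is.null(names(tissue_area_mm2))) {
      a <- tissue_area_mm2[[cid]]
      if (is.null(a)) abort_data(sprintf("no tissue area for core %s", cid))
      a
    } else tissue_area_mm2[[1]]
    pd <- phenotype_distribution(cc, exclusions = phenotype_exclusions)
    n_inc <- attr(pd, "n_cells")
    if (n_inc < 2L) {
      warning(sprintf("core %s: %d included cell(s); phenotype entropy set to 0",
                      cid, n_inc), call. = FALSE)
    }
    ic <- count_interactions(cc, radius_um = radius_um, exclude = interaction_exclusions)
    if (attr(ic, "n_pairs") < 2L) {
      warning(sprintf("core %s: %d interaction pair(s); interaction entropy set to 0",
                      cid, attr(ic, "n_pairs")), call. = FALSE)
    }
    dens <- vapply(density_subsets, function(s) cell_density(cc, s, area, panel),
                   numeric(1))
    names(dens) <- paste0("density_", density_subsets)
    out <- tibble::tibble(
      core_id = cid,
      n_cells = nrow(cc),
      n_cells_included = n_inc,
      phenotype_entropy = shannon_entropy(pd),
      interaction_entropy = interaction_entropy(ic),
      n_pairs = attr(ic, "n_pairs"),
      immune_ratio = immune_ratio(cc, panel),
      !!!as.list(dens),
      tissue_area_mm2 = area,
      cd21_area_fraction = if (!is.null(geom)) {
        geom$cd21_area_fraction[geom$core_id == cid]
      } else NA_real_
    )
    if ("patient_id" %in% names(cc)) {
      out <- tibble::add_column(out, patient_id = cc$patient_id[1], .before = 1)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Write per-core features and interaction counts
#'
#' @param profiles Tibble from [profile_cores()].
#' @param path Output CSV path.
#' @param meta Metadata header entries.
#' @return `path`, invisibly.
#' @export
write_core_features <- function(profiles, path, meta = list()) {
  write_meta_csv(profiles, path, meta)
}
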