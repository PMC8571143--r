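#' Read a per-cell measurement table
#'
#' The cell table is a CSV with one row per segmented cell: `cell_id`,
#' `core_id`, `patient_id`, centroid coordinates `x_um`, `y_um` (micrometres,
#' image convention: origin top-left, y increasing downward), and one median
#' intensity column per marker/compartment pair named `"<MARKER>:<compartment>"`
#' (e.g. `"FOXP3:nucleus"`, `"CD4:membrane"`). One file may hold many cores.
#' Lines starting with `#` are metadata and are skipped.
#'
#' Every marker scored by the panel must have a column for its designated
#' compartment; other intensity columns are carried along but ignored by
#' scoring. Unrecognised columns trigger a notice, not an error.
#'
#' @param path CSV file path.
#' @param panel A [marker_panel()] declaring required intensity columns;
#'   with `NULL` only the identifier/coordinate columns are required (e.g.
#'   when re-reading an already-scored table).
#' @return A tibble of cell records.
#' @export
read_cell_table <- function(path, panel = NULL) {
  if (!file.exists(path)) abort_data(sprintf("cell table not found: %s", path))
  df <- read_meta_csv(path)
  required <- c("cell_id", "core_id", "x_um", "y_um",
                if (!is.null(panel)) paste0(names(panel$compartment), ":", panel$compartment))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_data(sprintf("cell table missing required column(s): %s",
                       paste(missing, collapse = ", ")),
               class = "entrotme_format_error")
  }
  known <- c("cell_id", "core_id", "patient_id", "x_um", "y_um", "phenotype",
             grep("^[^:]+:(nucleus|membrane)$", names(df), value = TRUE),
             grep("_pos$", names(df), value = TRUE))
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    message(sprintf("ignoring unrecognised column(s): %s", paste(unknown, collapse = ", ")))
  }
  int_cols <- grep("^[^:]+:(nucleus|membrane)$", names(df), value = TRUE)
  for (cc in int_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) abort_data(sprintf("intensity column %s is not numeric", cc),
                                   class = "entrotme_format_error")
    bad <- which(v < 0)
    if (length(bad)) {
      abort_data(sprintf("negative intensity in column %s at row %d", cc, bad[1]))
    }
  }
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    abort_data("non-finite cell coordinates")
  }
  df$cell_id <- as.character(df$cell_id)
  df$core_id <- as.character(df$core_id)
  if ("patient_id" %in% names(df)) df$patient_id <- as.character(df$patient_id)
  df
}

#' Write a per-cell measurement table
#'
#' @param cells Cell tibble (possibly scored/phenotyped).
#' @param path Output CSV path.
#' @param meta Named list of metadata written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, meta = list()) {
  write_meta_csv(cells, path, meta)
}

#' Read tissue/artefact/CD21 annotations from GeoJSON
#'
#' Expects a `FeatureCollection` whose features carry `core_id` and
#' `role` properties (`role` one of `tissue`, `exclusion`, `cd21_meshwork`)
#' and `Polygon` or `MultiPolygon` geometry with coordinates in micrometres.
#'
#' @param path GeoJSON file path.
#' @return A tibble with columns `core_id`, `role` and a `polygon`
#'   list-column of `list(x, y)` vertex sets.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("annotation file not found: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_data("annotation file is not a GeoJSON FeatureCollection",
               class = "entrotme_format_error")
  }
  rows <- list()
  for (feat in gj$features) {
    props <- feat$properties
    role <- props$role %||% abort_data("annotation feature missing 'role' property",
                                       class = "entrotme_format_error")
    if (!role %in% c("tissue", "exclusion", "cd21_meshwork")) {
      abort_data(sprintf("unknown annotation role '%s'", role),
                 class = "entrotme_format_error")
    }
    cid <- as.character(props$core_id %||% abort_data(
      "annotation feature missing 'core_id' property", class = "entrotme_format_error"))
    geom <- feat$geometry
    ring_to_poly <- function(ring) {
      x <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
      y <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
      n <- length(x)
      if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
      list(x = x, y = y)
    }
    polys <- switch(geom$type,
      Polygon = list(ring_to_poly(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) ring_to_poly(p[[1]])),
      abort_data(sprintf("unsupported geometry type '%s'", geom$type),
                 class = "entrotme_format_error")
    )
    for (p in polys) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        core_id = cid, role = role, polygon = list(p)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(core_id = character(), role = character(), polygon = list()))
  }
  dplyr::bind_rows(rows)
}

#' Write an annotation tibble as GeoJSON
#'
#' @param annotations Tibble with `core_id`, `role`, `polygon` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  feats <- purrr::pmap(annotations, function(core_id, role, polygon, ...) {
    ring <- lapply(seq_along(polygon$x), function(i) list(polygon$x[i], polygon$y[i]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    list(
      type = "Feature",
      properties = list(core_id = core_id, role = role),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the clinical table
#'
#' CSV with one row per patient: `patient_id`, `treatment` (`rituximab`,
#' `radiotherapy` or `surveillance`), ordinal `flipi` (0-5, may be missing),
#' `os_months`/`os_event`, `pfs_months`/`pfs_event` (rituximab subset only),
#' `pod24` (logical, defined only with at least 24 months of follow-up) and
#' `followup_months`.
#'
#' @param path CSV file path.
#' @return A tibble of patient records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("clinical table not found: %s", path))
  df <- read_meta_csv(path)
  required <- c("patient_id", "treatment", "os_months", "os_event")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_data(sprintf("clinical table missing required column(s): %s",
                       paste(missing, collapse = ", ")),
               class = "entrotme_format_error")
  }
  df$patient_id <- as.character(df$patient_id)
  if (any(df$os_months < 0, na.rm = TRUE)) abort_data("negative os_months")
  if (!all(df$os_event %in% c(0, 1, NA))) abort_data("os_event must be 0/1")
  if ("pfs_months" %in% names(df) && any(df$pfs_months < 0, na.rm = TRUE)) {
    abort_data("negative pfs_months")
  }
  if ("flipi" %in% names(df) && !all(is.na(df$flipi) | (df$flipi %in% 0:5))) {
    abort_data("flipi must be an integer 0-5 or missing")
  }
  df
}
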