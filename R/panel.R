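#' Define a marker panel with compartments and positivity thresholds
#'
#' A marker panel describes the stains measured on each segmented cell, the
#' cell compartment (nucleus or membrane) on which each stain is scored, and
#' the single positivity threshold applied to the median intensity on that
#' compartment. The default panel is the 7-colour follicular-lymphoma panel:
#' DAPI (nuclear counterstain), CD4, CD8, CD68, FOXP3, PD-1 and CD21, with
#' FOXP3 scored on the nucleus and all other stains on the membrane.
#'
#' Phenotyping uses the five immune stains (CD4, CD8, CD68, FOXP3, PD-1);
#' DAPI and CD21 are reserved: segmentation is DAPI-driven so every cell is
#' treated as DAPI-positive (no DAPI threshold is applied), and CD21 marks
#' follicular dendritic meshwork rather than a phenotyping stain.
#'
#' @param markers Character vector of marker names, in panel order.
#' @param phenotyping_markers Subset of `markers` used for combinatorial
#'   phenotype codes.
#' @param compartment Named character vector mapping each scored marker to
#'   `"nucleus"` or `"membrane"`.
#' @param threshold Named numeric vector of non-negative positivity
#'   thresholds (arbitrary intensity units), one per scored marker.
#' @return An object of class `marker_panel`.
#' @examples
#' panel <- default_panel(threshold = c(
#'   CD4 = 5, CD8 = 5, CD68 = 5, FOXP3 = 5, `PD-1` = 5, CD21 = 5
#' ))
#' panel
#' @export
marker_panel <- function(markers, phenotyping_markers, compartment, threshold) {
  if (!is.character(markers) || !length(markers)) {
    abort_config("`markers` must be a non-empty character vector")
  }
  if (!all(phenotyping_markers %in% markers)) {
    abort_config("`phenotyping_markers` must be a subset of `markers`")
  }
  scored <- setdiff(markers, "DAPI")
  missing_cmp <- setdiff(scored, names(compartment))
  if (length(missing_cmp)) {
    abort_config(sprintf("missing compartment for marker(s): %s",
                         paste(missing_cmp, collapse = ", ")))
  }
  if (!all(compartment[scored] %in% c("nucleus", "membrane"))) {
    abort_config("compartments must be 'nucleus' or 'membrane'")
  }
  missing_thr <- setdiff(scored, names(threshold))
  if (length(missing_thr)) {
    abort_config(sprintf("missing threshold for marker(s): %s",
                         paste(missing_thr, collapse = ", ")))
  }
  if (any(threshold[scored] < 0)) abort_config("thresholds must be non-negative")
  structure(
    list(
      markers = markers,
      phenotyping_markers = phenotyping_markers,
      compartment = compartment[scored],
      threshold = threshold[scored]
    ),
    class = "marker_panel"
  )
}

#' @rdname marker_panel
#' @export
default_panel <- function(threshold = c(CD4 = 1, CD8 = 1, CD68 = 1,
                                        FOXP3 = 1, `PD-1` = 1, CD21 = 1)) {
  marker_panel(
    markers = c("DAPI", "CD4", "CD8", "CD68", "FOXP3", "PD-1", "CD21"),
    phenotyping_markers = c("CD4", "CD8", "CD68", "FOXP3", "PD-1"),
    compartment = c(CD4 = "membrane", CD8 = "membrane", CD68 = "membrane",
                    FOXP3 = "nucleus", `PD-1` = "membrane", CD21 = "membrane"),
    threshold = threshold
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  cat("  markers:     ", paste(x$markers, collapse = ", "), "\n")
  cat("  phenotyping: ", paste(x$phenotyping_markers, collapse = ", "), "\n")
  for (m in names(x$compartment)) {
    cat(sprintf("  %-6s %-8s threshold %.4g\n", m, x$compartment[[m]], x$threshold[[m]]))
  }
  invisible(x)
}

#' Read a marker panel from a YAML or JSON configuration file
#'
#' The file maps marker names to `{compartment, threshold}`; an optional
#' `phenotyping_markers` entry overrides the default five-stain list.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [marker_panel()].
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("panel config not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- cfg$markers %||% cfg[setdiff(names(cfg), "phenotyping_markers")]
  nms <- names(entries)
  pheno <- unlist(cfg$phenotyping_markers) %||%
    intersect(c("CD4", "CD8", "CD68", "FOXP3", "PD-1"), nms)
  compartment <- vapply(entries, function(e) e$compartment %||% "membrane", character(1))
  threshold <- vapply(entries, function(e) as.numeric(e$threshold), numeric(1))
  names(compartment) <- names(threshold) <- nms
  marker_panel(
    markers = union("DAPI", nms),
    phenotyping_markers = pheno,
    compartment = compartment,
    threshold = threshold
  )
}

# canonical ordered phenotype code, e.g. "CD4+CD8-CD68-FOXP3+PD-1-"
make_code <- function(pos_matrix, markers) {
  stopifnot(ncol(pos_matrix) == length(markers))
  parts <- vapply(seq_along(markers), function(j) {
    paste0(markers[j], ifelse(pos_matrix[, j], "+", "-"))
  }, character(nrow(pos_matrix)))
  if (nrow(pos_matrix) == 1L) paste(parts, collapse = "") else apply(parts, 1, paste, collapse = "")
}

#' Enumerate all phenotype labels of a panel
#'
#' With five phenotyping stains there are `2^5 = 32` combination codes; the
#' two reserved classes `DAPI_ONLY` (no phenotyping stain, CD21-negative) and
#' `CD21_ONLY` (no phenotyping stain, CD21-positive) complete the label set.
#'
#' @param panel A [marker_panel()].
#' @param include_reserved Include `DAPI_ONLY` and `CD21_ONLY`.
#' @return Character vector of labels in canonical order.
#' @export
phenotype_levels <- function(panel = default_panel(), include_reserved = TRUE) {
  k <- length(panel$phenotyping_markers)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k))[, k:1, drop = FALSE])
  codes <- make_code(grid, panel$phenotyping_markers)
  if (include_reserved) c(codes, "DAPI_ONLY", "CD21_ONLY") else codes
}
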