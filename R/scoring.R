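#' Score marker positivity by thresholding median intensities
#'
#' Each marker is called positive when the cell's median intensity on the
#' marker's designated compartment (nucleus for FOXP3, membrane for the other
#' stains under the default panel) is greater than or equal to the panel
#' threshold; the closed rule makes a cell exactly at threshold positive.
#' Intensities measured on the other compartment never influence the call.
#' DAPI positivity is implied by segmentation (nuclear detection is
#' DAPI-driven) and no DAPI threshold is applied.
#'
#' Scoring is idempotent: re-scoring a scored table with the same panel
#' reproduces the same calls.
#'
#' @param cells Cell tibble from [read_cell_table()].
#' @param panel A [marker_panel()].
#' @return The cell tibble with one logical `"<MARKER>_pos"` column per
#'   panel marker (including `DAPI_pos`, always `TRUE`).
#' @export
score_cells <- function(cells, panel = default_panel()) {
  for (m in names(panel$compartment)) {
    col <- paste0(m, ":", panel$compartment[[m]])
    if (!col %in% names(cells)) {
      abort_data(sprintf("missing intensity column for scoring: %s", col))
    }
    v <- cells[[col]]
    if (anyNA(v)) abort_data(sprintf("missing intensity values in column %s", col))
    cells[[paste0(m, "_pos")]] <- v >= panel$threshold[[m]]
  }
  if ("DAPI" %in% panel$markers) cells$DAPI_pos <- rep(TRUE, nrow(cells))
  cells
}

#' Assign a combinatorial phenotype label to each scored cell
#'
#' The label is the positivity vector over the phenotyping stains in panel
#' order, written `CD4+CD8-CD68-FOXP3+PD-1-` style; with five stains there
#' are `2^5 = 32` combination codes. Two reserved classes capture cells with
#' no phenotyping stain: `DAPI_ONLY` when CD21 is also negative and
#' `CD21_ONLY` when only CD21 is positive. A cell positive for CD21 and at
#' least one phenotyping stain keeps its combination code (CD21 is not part
#' of the code).
#'
#' @param cells Scored cell tibble (see [score_cells()]).
#' @param panel A [marker_panel()].
#' @return The cell tibble with a `phenotype` character column.
#' @export
assign_phenotypes <- function(cells, panel = default_panel()) {
  pos_cols <- paste0(panel$phenotyping_markers, "_pos")
  missing <- setdiff(pos_cols, names(cells))
  if (length(missing)) {
    abort_data("cells must be scored before phenotyping (run score_cells first)",
               class = "entrotme_state_error")
  }
  pos <- as.matrix(cells[pos_cols])
  if (anyNA(pos)) abort_data("positivity calls contain missing values",
                             class = "entrotme_state_error")
  if (nrow(cells) == 0L) {
    cells$phenotype <- character(0)
    return(cells)
  }
  code <- make_code(pos, panel$phenotyping_markers)
  none <- rowSums(pos) == 0L
  cd21 <- if ("CD21_pos" %in% names(cells)) cells$CD21_pos else rep(FALSE, nrow(cells))
  code[none & !cd21] <- "DAPI_ONLY"
  code[none & cd21] <- "CD21_ONLY"
  cells$phenotype <- code
  cells
}

# parse a subset specification like "CD4+CD68-PD-1+" into a named logical
# vector (TRUE = must be positive, FALSE = must be negative)
parse_subset <- function(spec, panel = default_panel()) {
  known <- setdiff(panel$markers, "DAPI")
  # match longest marker names first so "PD-1" is not read as "PD" + "-1"
  known <- known[order(nchar(known), decreasing = TRUE)]
  out <- logical(0)
  rest <- spec
  while (nzchar(rest)) {
    hit <- NA_character_
    for (m in known) {
      if (startsWith(rest, m)) { hit <- m; break }
    }
    if (is.na(hit)) abort_config(sprintf("cannot parse subset '%s' near '%s'", spec, rest))
    rest <- substr(rest, nchar(hit) + 1L, nchar(rest))
    sign <- substr(rest, 1L, 1L)
    if (!sign %in% c("+", "-")) {
      abort_config(sprintf("marker %s in subset '%s' must be followed by + or -", hit, spec))
    }
    out[[hit]] <- sign == "+"
    rest <- substr(rest, 2L, nchar(rest))
  }
  if (!length(out)) abort_config("empty subset specification")
  out
}

# logical index of cells matching a subset spec ("CD8+", "CD4+CD68-", ...)
match_subset <- function(cells, spec, panel = default_panel()) {
  req <- parse_subset(spec, panel)
  keep <- rep(TRUE, nrow(cells))
  for (m in names(req)) {
    col <- paste0(m, "_pos")
    if (!col %in% names(cells)) {
      abort_data(sprintf("cells are not scored for marker %s", m),
                 class = "entrotme_state_error")
    }
    keep <- keep & (cells[[col]] == req[[m]])
  }
  keep
}
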