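#' Phenotype composition of a sample
#'
#' Tabulates phenotype labels into counts and proportions, after removing
#' excluded labels. By default the two reserved classes are excluded:
#' `DAPI_ONLY` and `CD21_ONLY` cells may include tumour B-cell subsets and
#' are not part of the immune-infiltrate diversity analysis. An empty
#' distribution (no included cells) is a valid result, not an error.
#'
#' @param cells Phenotyped cell tibble for one sample (see
#'   [assign_phenotypes()]), or a character vector of labels.
#' @param exclusions Labels to drop before normalising.
#' @return A tibble `phenotype`, `n`, `p` (proportions sum to 1 when any
#'   cell remains) with attribute `n_cells` = total included cells.
#' @export
phenotype_distribution <- function(cells, exclusions = c("DAPI_ONLY", "CD21_ONLY")) {
  labels <- if (is.character(cells)) cells else {
    if (!"phenotype" %in% names(cells)) {
      abort_data("cells must be phenotyped (run assign_phenotypes first)",
                 class = "entrotme_state_error")
    }
    cells$phenotype
  }
  labels <- labels[!labels %in% exclusions]
  tab <- table(labels)
  total <- sum(tab)
  out <- tibble::tibble(
    phenotype = as.character(names(tab)),
    n = as.integer(tab),
    p = if (total > 0) as.integer(tab) / total else numeric(length(tab))
  )
  attr(out, "n_cells") <- as.integer(total)
  attr(out, "exclusions") <- exclusions
  out
}

#' Shannon entropy of a discrete distribution (nats)
#'
#' Computes `-sum(p_i * ln(p_i))` over classes with positive proportion,
#' with the convention `0 * ln(0) = 0`. Samples with zero or one member
#' have entropy 0. Reported in nats (natural logarithm), the unit used for
#' the diversity indices throughout the package.
#'
#' @param dist A [phenotype_distribution()] tibble (column `p`), or a
#'   numeric vector of counts or proportions (normalised internally).
#' @return Entropy in nats, a single non-negative number.
#' @examples
#' shannon_entropy(rep(1 / 32, 32)) # ln(32)
#' shannon_entropy(c(0.5, 0.25, 0.25))
#' @export
shannon_entropy <- function(dist) {
  p <- if (is.data.frame(dist)) dist$p else as.numeric(dist)
  if (any(p < 0, na.rm = TRUE)) abort_data("proportions must be non-negative")
  p <- p[!is.na(p) & p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  ent <- -sum(p * log(p))
  if (ent <= 0) 0 else ent  # avoids IEEE -0 for a single class
}

#' Density of a cell subset in cells per mm^2
#'
#' Counts cells matching a marker-positivity subset specification and
#' divides by the tissue area. Marker-level subsets such as `"CD68+"` count
#' every CD68-positive cell regardless of other markers; compound subsets
#' such as `"CD4+CD68-"` require every stated sign.
#'
#' @param cells Scored cell tibble for one sample.
#' @param subset Subset specification string, e.g. `"CD8+"`, `"CD4+CD68-"`,
#'   `"CD4+CD68-PD-1+"`.
#' @param area_mm2 Tissue area of the sample in mm^2 (positive).
#' @param panel A [marker_panel()].
#' @return Cells per mm^2.
#' @export
cell_density <- function(cells, subset, area_mm2, panel = default_panel()) {
  stopifnot_scalar_num(area_mm2, "area_mm2")
  if (area_mm2 <= 0) abort_data("tissue area must be positive")
  sum(match_subset(cells, subset, panel)) / area_mm2
}

#' Total immune infiltrate ratio
#'
#' The number of cells expressing at least one of the phenotyping stains
#' (CD4, CD8, CD68, FOXP3, PD-1 under the default panel) divided by the
#' number of non-immune cells expressing only DAPI. `CD21_ONLY` cells count
#' in neither term. Undefined (an error) when the sample has no DAPI-only
#' cells.
#'
#' @param cells Phenotyped cell tibble for one sample.
#' @param panel A [marker_panel()].
#' @return A non-negative ratio.
#' @export
immune_ratio <- function(cells, panel = default_panel()) {
  if (!"phenotype" %in% names(cells)) {
    abort_data("cells must be phenotyped (run assign_phenotypes first)",
               class = "entrotme_state_error")
  }
  n_dapi <- sum(cells$phenotype == "DAPI_ONLY")
  if (n_dapi == 0L) {
    abort_data("immune ratio undefined: no DAPI-only cells in sample",
               class = "entrotme_ratio_error")
  }
  n_immune <- sum(!cells$phenotype %in% c("DAPI_ONLY", "CD21_ONLY"))
  n_immune / n_dapi
}
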