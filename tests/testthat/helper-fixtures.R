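# fixtures built in code: toy panels, cell tables and scored/labelled cells

toy_panel <- function(thr = 4) {
  default_panel(threshold = c(CD4 = thr, CD8 = thr, CD68 = thr,
                              FOXP3 = thr, `PD-1` = thr, CD21 = thr))
}

# raw intensity table for n cells; all intensities default to `lo`
toy_cell_table <- function(n = 3, lo = 1, core_id = "core1", patient_id = "p1") {
  df <- tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(n)),
    core_id = core_id,
    patient_id = patient_id,
    x_um = seq_len(n) * 10,
    y_um = seq_len(n) * 5
  )
  for (m in c("DAPI", "CD4", "CD8", "CD68", "FOXP3", "PD-1", "CD21")) {
    for (cp in c("nucleus", "membrane")) {
      if (m == "DAPI" && cp == "membrane") next
      df[[paste0(m, ":", cp)]] <- rep(lo, n)
    }
  }
  df
}

# cells with given phenotype labels and positions, with consistent _pos
# columns derived from the label text (independent of score_cells)
cells_from_labels <- function(labels, x = NULL, y = NULL,
                              core_id = "core1", patient_id = "p1") {
  n <- length(labels)
  if (is.null(x)) x <- seq_len(n) * 1000
  if (is.null(y)) y <- rep(0, n)
  df <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    core_id = core_id, patient_id = patient_id,
    x_um = x, y_um = y, phenotype = labels
  )
  for (m in c("CD4", "CD8", "CD68", "FOXP3", "PD-1")) {
    df[[paste0(m, "_pos")]] <- grepl(paste0(m, "+"), labels, fixed = TRUE)
  }
  df$CD21_pos <- labels == "CD21_ONLY"
  df$DAPI_pos <- TRUE
  df
}

# independent truth-table oracle for the labelling rule: builds the expected
# label from a 6-long positivity vector (CD4, CD8, CD68, FOXP3, PD-1, CD21)
expected_label <- function(cd4, cd8, cd68, foxp3, pd1, cd21) {
  if (!any(c(cd4, cd8, cd68, foxp3, pd1))) {
    if (cd21) "CD21_ONLY" else "DAPI_ONLY"
  } else {
    paste0("CD4", if (cd4) "+" else "-",
           "CD8", if (cd8) "+" else "-",
           "CD68", if (cd68) "+" else "-",
           "FOXP3", if (foxp3) "+" else "-",
           "PD-1", if (pd1) "+" else "-")
  }
}

# random phenotyped core on a rectangle, for interaction-counter checks
random_core <- function(n, seed, extent = 500, labels = c("A", "B", "C")) {
  withr::with_seed(seed, {
    cells_from_labels(
      sample(labels, n, replace = TRUE),
      x = stats::runif(n, 0, extent),
      y = stats::runif(n, 0, extent)
    )
  })
}

# brute-force pair-type counting oracle: all n^2/2 distances, direct tally
oracle_interactions <- function(cells, radius, exclude = "DAPI_ONLY") {
  keep <- !cells$phenotype %in% exclude
  x <- cells$x_um[keep]; y <- cells$y_um[keep]; lab <- cells$phenotype[keep]
  out <- list()
  n <- length(x)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
          key <- paste(sort(c(lab[i], lab[j])), collapse = "|")
          out[[key]] <- (out[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  unlist(out) %||% stats::setNames(integer(0), character(0))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# interaction tibble -> named count vector keyed "label_i|label_j"
counts_as_vector <- function(ic) {
  stats::setNames(ic$n, paste(ic$label_i, ic$label_j, sep = "|"))
}

unit_square <- function(side = 1, x0 = 0, y0 = 0) {
  list(x = c(x0, x0 + side, x0 + side, x0), y = c(y0, y0, y0 + side, y0 + side))
}
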