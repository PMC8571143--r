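# Polygon helpers. Polygons are lists with numeric x, y vertex vectors in
# micrometres (closed implicitly; last vertex connects to first). Boolean
# operations go through polyclip (Clipper); areas via the shoelace formula on
# its oriented output, so holes subtract correctly.

shoelace_area <- function(p) {
  x <- p$x; y <- p$y
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

poly_area <- function(polys) {
  if (!length(polys)) return(0)
  sum(vapply(polys, shoelace_area, numeric(1)))
}

as_polylist <- function(p) {
  if (is.null(p)) return(list())
  if (!is.null(p$x)) list(p) else p
}

poly_op <- function(A, B, op) {
  A <- as_polylist(A); B <- as_polylist(B)
  if (op == "union" && !length(A)) return(B)
  if (!length(A)) return(list())
  if (!length(B)) return(if (op %in% c("minus", "union")) A else list())
  polyclip::polyclip(A, B, op = op, fillA = "nonzero", fillB = "nonzero")
}

poly_union_all <- function(polys) {
  polys <- as_polylist(polys)
  if (length(polys) <= 1L) return(polys)
  Reduce(function(a, b) poly_op(a, list(b), "union"), polys[-1], init = polys[1])
}

check_simple_polygon <- function(p, what = "polygon") {
  # Clipper's simplification splits a self-intersecting ring into several
  # output rings; flag that as a geometry error for input annotations.
  simp <- polyclip::polysimplify(list(p), filltype = "nonzero")
  if (length(simp) != 1L) {
    abort_data(sprintf("self-intersecting %s", what), class = "entrotme_geometry_error")
  }
  invisible(TRUE)
}

# Closed point-in-polygon: boundary points count as inside.
points_in_poly <- function(x, y, poly) {
  res <- polyclip::pointinpolygon(list(x = x, y = y), poly)
  res != 0L
}

points_in_region <- function(x, y, polys) {
  polys <- as_polylist(polys)
  if (!length(polys)) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (p in polys) inside <- inside | points_in_poly(x, y, p)
  inside
}

# regular polygon approximating a circle; used by the simulator's core discs
circle_poly <- function(cx, cy, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Tissue geometry summaries per core
#'
#' Computes, for each core in an annotation table, the analysable tissue area
#' (tissue polygon minus artefact exclusions) and the CD21+ follicular
#' dendritic meshwork area fraction: the area of the union of the meshwork
#' annotations clipped to the analysable tissue, divided by the analysable
#' tissue area. Coordinates are in micrometres; areas are reported in mm^2.
#'
#' @param annotations Annotation tibble from [read_annotations()] (columns
#'   `core_id`, `role`, `polygon`).
#' @return A tibble with one row per core: `core_id`, `tissue_area_mm2`,
#'   `cd21_area_fraction`.
#' @export
core_geometry <- function(annotations) {
  stopifnot(all(c("core_id", "role", "polygon") %in% names(annotations)))
  annotations |>
    dplyr::group_by(.data$core_id) |>
    dplyr::group_modify(function(df, key) {
      tissue <- df$polygon[df$role == "tissue"]
      if (!length(tissue)) abort_data(sprintf("core %s has no tissue polygon", key$core_id))
      for (p in df$polygon) check_simple_polygon(p)
      excl <- df$polygon[df$role == "exclusion"]
      cd21 <- df$polygon[df$role == "cd21_meshwork"]
      net <- poly_op(poly_union_all(tissue), poly_union_all(excl), "minus")
      area <- poly_area(net)
      if (area <= 0) abort_data(sprintf("core %s has non-positive tissue area", key$core_id))
      cd21_net <- poly_op(poly_union_all(cd21), net, "intersection")
      tibble::tibble(
        tissue_area_mm2 = area / 1e6,
        cd21_area_fraction = poly_area(cd21_net) / area
      )
    }) |>
    dplyr::ungroup()
}

#' CD21+ meshwork area fraction of a single core
#'
#' @param tissue Tissue polygon (`list(x, y)`) or list of polygons, in um.
#' @param cd21 List of CD21 meshwork polygons (possibly empty).
#' @param exclusions List of artefact-exclusion polygons (possibly empty).
#' @return Fraction in `[0, 1]`.
#' @export
cd21_area_fraction <- function(tissue, cd21 = list(), exclusions = list()) {
  for (p in as_polylist(tissue)) check_simple_polygon(p, "tissue polygon")
  for (p in as_polylist(cd21)) check_simple_polygon(p, "cd21 polygon")
  net <- poly_op(poly_union_all(as_polylist(tissue)),
                 poly_union_all(as_polylist(exclusions)), "minus")
  area <- poly_area(net)
  if (area <= 0) abort_data("non-positive tissue area", class = "entrotme_geometry_error")
  poly_area(poly_op(poly_union_all(as_polylist(cd21)), net, "intersection")) / area
}

#' Filter cells to the analysable tissue region of their core
#'
#' Keeps cells whose centroid lies inside the core's tissue polygon and
#' outside every artefact-exclusion polygon. Cells exactly on a polygon
#' boundary count as inside (closed polygons), so the filter is
#' deterministic.
#'
#' @param cells Cell tibble with `core_id`, `x_um`, `y_um`.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return The filtered cell tibble.
#' @export
filter_cells_to_tissue <- function(cells, annotations) {
  keep <- rep(TRUE, nrow(cells))
  for (cid in unique(cells$core_id)) {
    idx <- which(cells$core_id == cid)
    ann <- annotations[annotations$core_id == cid, ]
    if (!nrow(ann)) next
    tissue <- ann$polygon[ann$role == "tissue"]
    excl <- ann$polygon[ann$role == "exclusion"]
    inside <- points_in_region(cells$x_um[idx], cells$y_um[idx], tissue)
    if (length(excl)) {
      inside <- inside & !points_in_region(cells$x_um[idx], cells$y_um[idx], excl)
    }
    keep[idx] <- inside
  }
  cells[keep, , drop = FALSE]
}
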