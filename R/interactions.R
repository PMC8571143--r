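# Spatial co-occurrence ("interaction") counting.
#
# Two cells interact when their centroid Euclidean distance is <= the radius
# (closed rule; default 30 um, a 3-4 cell neighbourhood). Each unordered pair
# of distinct cells contributes exactly once; same-label pairs are the
# self-interaction type {i, i}. No edge correction is applied at core
# boundaries.

# unordered candidate/actual neighbour pairs (i < j, original indices)
neighbour_pairs_naive <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  hit <- which(upper.tri(d2) & d2 <= r * r, arr.ind = TRUE)
  cbind(i = hit[, 1L], j = hit[, 2L])
}

# Uniform-grid acceleration: bin cells into radius-sized cells and only test
# pairs in the same or adjacent bins, visiting each unordered bin pair once
# via the half-neighbourhood offsets (0,0), (1,0), (-1,1), (0,1), (1,1).
# The distance filter decides membership, so results are identical to the
# naive all-pairs scan.
neighbour_pairs_grid <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  bx <- floor(x / r); by <- floor(y / r)
  bx <- bx - min(bx); by <- by - min(by)
  W <- max(bx) + 3  # key stride; +-1 offsets never wrap
  key <- (bx + 1) + (by + 1) * W
  ord <- order(key, seq_len(n))
  ks <- key[ord]
  out_i <- list(); out_j <- list(); m <- 0L
  for (off in list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
    dkey <- off[1] + off[2] * W
    target <- ks + dkey
    hi <- findInterval(target, ks)
    lo <- findInterval(target - 0.5, ks) + 1L
    cnt <- pmax(hi - lo + 1L, 0L)
    if (dkey == 0) {
      # same bin: only positions after i
      lo <- pmax(lo, seq_len(n) + 1L)
      cnt <- pmax(hi - lo + 1L, 0L)
    }
    if (!sum(cnt)) next
    a <- rep.int(seq_len(n), cnt)
    b <- rep.int(lo, cnt) + sequence(cnt) - 1L
    m <- m + 1L
    out_i[[m]] <- a; out_j[[m]] <- b
  }
  if (!m) return(cbind(i = integer(0), j = integer(0)))
  a <- unlist(out_i, use.names = FALSE)
  b <- unlist(out_j, use.names = FALSE)
  ia <- ord[a]; jb <- ord[b]
  keep <- (x[ia] - x[jb])^2 + (y[ia] - y[jb])^2 <= r * r
  ia <- ia[keep]; jb <- jb[keep]
  cbind(i = pmin(ia, jb), j = pmax(ia, jb))
}

#' Count phenotype co-occurrences within a radius
#'
#' Enumerates every unordered pair of distinct cells whose centroids lie
#' within `radius_um` of one another (closed rule: a pair at exactly the
#' radius counts) and tabulates the unordered label pairs. Cells whose label
#' is in `exclude` are ignored; by default only `DAPI_ONLY` cells are
#' excluded from interaction counting. Proportions are normalised over all
#' counted pairs.
#'
#' @param cells Phenotyped cell tibble for one sample, with `x_um`, `y_um`.
#' @param radius_um Interaction radius in micrometres (default 30).
#' @param exclude Labels excluded from counting (default `"DAPI_ONLY"`).
#' @param method `"grid"` (uniform-grid accelerated, default) or `"naive"`
#'   (all-pairs reference); both give identical counts.
#' @return A tibble `label_i`, `label_j` (with `label_i <= label_j`), `n`,
#'   `p`, with attribute `n_pairs` = total counted pairs.
#' @export
count_interactions <- function(cells, radius_um = 30, exclude = "DAPI_ONLY",
                               method = c("grid", "naive")) {
  method <- match.arg(method)
  stopifnot_scalar_num(radius_um, "radius_um")
  if (radius_um <= 0) abort_data("interaction radius must be positive")
  if (!"phenotype" %in% names(cells)) {
    abort_data("cells must be phenotyped (run assign_phenotypes first)",
               class = "entrotme_state_error")
  }
  keep <- !cells$phenotype %in% exclude
  x <- cells$x_um[keep]; y <- cells$y_um[keep]
  lab <- cells$phenotype[keep]
  pairs <- if (method == "grid") {
    neighbour_pairs_grid(x, y, radius_um)
  } else {
    neighbour_pairs_naive(x, y, radius_um)
  }
  levs <- sort(unique(lab))
  li <- match(lab[pairs[, "i"]], levs)
  lj <- match(lab[pairs[, "j"]], levs)
  a <- pmin(li, lj); b <- pmax(li, lj)
  L <- length(levs)
  keycount <- tabulate((a - 1L) * L + b, nbins = L * L)
  hit <- which(keycount > 0L)
  ai <- (hit - 1L) %/% L + 1L
  bj <- (hit - 1L) %% L + 1L
  n <- keycount[hit]
  total <- sum(n)
  out <- tibble::tibble(
    label_i = if (length(hit)) levs[ai] else character(0),
    label_j = if (length(hit)) levs[bj] else character(0),
    n = as.integer(n),
    p = if (total > 0) n / total else numeric(length(n))
  )
  out <- dplyr::arrange(out, .data$label_i, .data$label_j)
  attr(out, "n_pairs") <- as.integer(total)
  attr(out, "radius_um") <- radius_um
  out
}

#' Shannon entropy of the spatial-interaction distribution (nats)
#'
#' Applies the Shannon index to the proportions of unordered phenotype-pair
#' co-occurrence types: `-sum_{i <= j} p_ij ln(p_ij)`. Samples with zero or
#' one counted pair have interaction entropy 0.
#'
#' @param counts A [count_interactions()] tibble (columns `n`, `p`) or a
#'   numeric vector of pair-type counts.
#' @return Entropy in nats.
#' @export
interaction_entropy <- function(counts) {
  n <- if (is.data.frame(counts)) counts$n else as.numeric(counts)
  if (sum(n) <= 1) return(0)
  shannon_entropy(n)
}
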