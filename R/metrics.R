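#' Label connected patches
#'
#' Maximal connected components of the foreground under 4- or 8-neighbor
#' connectivity, labeled 1..NP in raster scan order. The default 8-neighbor
#' rule matches the connectivity used by the local connected fractal
#' dimension.
#'
#' @param mask A [binary_landscape()].
#' @param connectivity 4 or 8 (default 8).
#' @return A list of class `patch_labeling`: `labels` (integer matrix, 0 =
#'   background), `np` (patch count), `sizes` (cells per patch),
#'   `cell_size`.
#' @examples
#' bl <- binary_landscape(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' label_patches(bl, connectivity = 8)$np  # 1: diagonal cells touch
#' label_patches(bl, connectivity = 4)$np  # 2
#' @export
label_patches <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "binary_landscape"))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  labels <- cc_label(mask$grid, as.integer(connectivity))
  np <- max(labels)
  sizes <- if (np > 0) tabulate(labels[labels > 0], nbins = np) else integer(0)
  structure(
    list(labels = labels, np = np, sizes = sizes, cell_size = mask$cell_size),
    class = "patch_labeling"
  )
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf("<patch_labeling> %d patches, %d labeled cells\n",
              x$np, sum(x$sizes)))
  invisible(x)
}

#' Deforested area in hectares
#'
#' @param mask A [binary_landscape()].
#' @return Foreground count times the cell area, in hectares.
#' @examples
#' deforested_area(binary_landscape(matrix(TRUE, 1, 1), cell_size = 30)) # 0.09
#' @export
deforested_area <- function(mask) {
  stopifnot(inherits(mask, "binary_landscape"))
  fg_count(mask) * mask$cell_size^2 / 1e4
}

#' Period-over-period area ratio
#'
#' The proportion between the current cumulative deforested area and the
#' previous one.
#'
#' @param da_now,da_prev Deforested areas (same units).
#' @return `da_now / da_prev`, or `NA` when the previous area is zero.
#' @examples
#' round(da_ratio(103006, 18503), 2)  # 5.57
#' @export
da_ratio <- function(da_now, da_prev) {
  if (is.na(da_prev) || da_prev <= 0) return(NA_real_)
  da_now / da_prev
}

#' Patch density
#'
#' @param np Number of patches.
#' @param landscape_area_ha Total landscape area in hectares.
#' @return Patches per 100 ha.
#' @export
patch_density <- function(np, landscape_area_ha) {
  if (landscape_area_ha <= 0) abort("`landscape_area_ha` must be positive")
  np / landscape_area_ha * 100
}

#' Edge density
#'
#' Total foreground-background boundary length (rook cell-edge segments
#' times the cell size) per unit landscape area. Image-border edges of
#' foreground cells are excluded by default.
#'
#' @param mask A [binary_landscape()].
#' @param landscape_area_ha Total landscape area in hectares; defaults to
#'   the raster extent.
#' @param count_border Count the image border along foreground cells as
#'   edge (default `FALSE`).
#' @return Edge density in metres per hectare.
#' @export
edge_density <- function(mask, landscape_area_ha = NULL, count_border = FALSE) {
  stopifnot(inherits(mask, "binary_landscape"))
  if (is.null(landscape_area_ha)) landscape_area_ha <- landscape_area(mask)
  if (landscape_area_ha <= 0) abort("`landscape_area_ha` must be positive")
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  n_edges <- 0L
  if (nc > 1) n_edges <- n_edges + sum(g[, -nc] != g[, -1])
  if (nr > 1) n_edges <- n_edges + sum(g[-nr, ] != g[-1, ])
  if (count_border) {
    n_edges <- n_edges + sum(g[1, ]) + sum(g[nr, ]) + sum(g[, 1]) + sum(g[, nc])
  }
  n_edges * mask$cell_size / landscape_area_ha
}

#' Landscape extent in hectares
#' @param mask A [binary_landscape()].
#' @return Total raster area in hectares.
#' @export
landscape_area <- function(mask) {
  stopifnot(inherits(mask, "binary_landscape"))
  prod(dim(mask$grid)) * mask$cell_size^2 / 1e4
}

# Minimum Euclidean distance between two coordinate matrices (rows =
# points), computed in column chunks to bound memory.
min_cross_dist <- function(a, b, chunk = 2048L) {
  best <- Inf
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Mean Euclidean nearest-neighbor distance between patches
#'
#' For each patch, the minimum center-to-center Euclidean distance between
#' any of its cells and any cell of a different patch; the mean over
#' patches, in metres. Only patch boundary cells enter the search (the
#' minimum between distinct patches is always attained there).
#'
#' @param labeling A `patch_labeling` from [label_patches()], or a
#'   [binary_landscape()] (labeled with the default connectivity).
#' @param cell_size Cell size in metres; taken from `labeling` if absent.
#' @return Mean distance in metres, or `NA` when fewer than two patches.
#' @export
enn_mn <- function(labeling, cell_size = NULL) {
  if (inherits(labeling, "binary_landscape")) labeling <- label_patches(labeling)
  stopifnot(inherits(labeling, "patch_labeling"))
  if (is.null(cell_size)) cell_size <- labeling$cell_size
  if (labeling$np < 2) return(NA_real_)
  lab <- labeling$labels
  nr <- nrow(lab); nc <- ncol(lab)
  # boundary cells: labeled cells with an 8-neighbor (or image border) of a
  # different label
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  boundary <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    boundary <- boundary | (ctr > 0 & nb != ctr)
  }
  cells <- which(boundary, arr.ind = TRUE)
  labs <- lab[boundary]
  dists <- vapply(seq_len(labeling$np), function(i) {
    own <- cells[labs == i, , drop = FALSE]
    other <- cells[labs != i, , drop = FALSE]
    min_cross_dist(own, other)
  }, numeric(1))
  mean(dists) * cell_size
}

#' Clumpiness index
#'
#' Adjacency-based aggregation index of the foreground class. With `g_ii`
#' the like (foreground-foreground) rook adjacencies and `sum_gik` all rook
#' adjacencies involving foreground (ordered-pair double-count convention),
#' `G = g_ii / sum_gik` and `P` the foreground proportion:
#' `CLUMPY = (G - P) / P` when `G < P` and `P < 0.5`, else
#' `(G - P) / (1 - P)`. Ranges from -1 (maximally disaggregated, e.g. a
#' checkerboard) through 0 (spatially random) to 1 (maximally clumped).
#'
#' @param mask A [binary_landscape()].
#' @return The index, or `NA` for an empty or fully foreground mask.
#' @export
clumpy <- function(mask) {
  stopifnot(inherits(mask, "binary_landscape"))
  g <- mask$grid
  P <- mean(g)
  if (P == 0 || P == 1) return(NA_real_)
  nr <- nrow(g); nc <- ncol(g)
  like <- 0L; total <- 0L
  if (nc > 1) {
    h_pairs <- g[, -nc] & g[, -1]
    like <- like + 2L * sum(h_pairs)
    total <- total + sum(g[, -nc]) + sum(g[, -1])
  }
  if (nr > 1) {
    v_pairs <- g[-nr, ] & g[-1, ]
    like <- like + 2L * sum(v_pairs)
    total <- total + sum(g[-nr, ]) + sum(g[-1, ])
  }
  if (total == 0) return(NA_real_)
  G <- like / total
  if (G < P && P < 0.5) (G - P) / P else (G - P) / (1 - P)
}

#' Patch-level fragmentation metrics of a binary landscape
#'
#' One row of the standard metric set for a deforestation mask: deforested
#' area DA (ha), number of patches NP, patch density PD (per 100 ha), edge
#' density ED (m/ha), mean Euclidean nearest-neighbor distance ENN_MN (m,
#' missing when NP < 2), and the clumpiness index CLUMPY.
#'
#' @inheritParams edge_density
#' @param connectivity Patch connectivity, 4 or 8.
#' @return A one-row tibble with columns `DA`, `NP`, `PD`, `ED`, `ENN_MN`,
#'   `CLUMPY`, `landscape_area`.
#' @export
landscape_metrics <- function(mask, landscape_area_ha = NULL,
                              connectivity = 8, count_border = FALSE) {
  stopifnot(inherits(mask, "binary_landscape"))
  if (is.null(landscape_area_ha)) landscape_area_ha <- landscape_area(mask)
  lp <- label_patches(mask, connectivity)
  tibble(
    DA = deforested_area(mask),
    NP = lp$np,
    PD = patch_density(lp$np, landscape_area_ha),
    ED = edge_density(mask, landscape_area_ha, count_border),
    ENN_MN = if (lp$np >= 2) enn_mn(lp) else NA_real_,
    CLUMPY = clumpy(mask),
    landscape_area = landscape_area_ha
  )
}

#' Metrics table for a cumulative series
#'
#' Applies [landscape_metrics()] to every step of a growth series and adds
#' the period label `CP` and the period-over-period area `Ratio`, giving the
#' standard cumulative-period metrics table.
#'
#' @param series A [growth_series()].
#' @inheritParams landscape_metrics
#' @return A tibble with columns `CP`, `DA`, `Ratio`, `NP`, `PD`, `ED`,
#'   `ENN_MN`, `CLUMPY`.
#' @export
metrics_series <- function(series, landscape_area_ha = NULL,
                           connectivity = 8, count_border = FALSE) {
  stopifnot(inherits(series, "growth_series"))
  rows <- purrr::map(series$landscapes, landscape_metrics,
                     landscape_area_ha = landscape_area_ha,
                     connectivity = connectivity,
                     count_border = count_border)
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    CP = series$labels,
    Ratio = dplyr::if_else(dplyr::lag(.data$DA) > 0,
                           .data$DA / dplyr::lag(.data$DA), NA_real_),
    .before = 1
  )
  dplyr::relocate(out, "CP", "DA", "Ratio", "NP", "PD", "ED", "ENN_MN",
                  "CLUMPY")
}
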