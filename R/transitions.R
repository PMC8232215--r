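#' Cross-tabulate class transitions between two rasters
#'
#' Counts cells per ordered (class at time A, class at time B) pair. The
#' marginals of the table equal the per-map class histograms.
#'
#' @param a,b Aligned [categorical_raster()] objects (same shape, cell size
#'   and georeference).
#' @param period Optional period label attached to the result.
#' @return A tibble with columns `from_class`, `to_class`, `n` (one row per
#'   observed pair) and attribute `period`.
#' @examples
#' a <- categorical_raster(matrix(c(1L, 2L, 1L, 2L), 2, 2))
#' b <- categorical_raster(matrix(c(1L, 2L, 3L, 3L), 2, 2))
#' crosstab_rasters(a, b)
#' @export
crosstab_rasters <- function(a, b, period = NULL) {
  stopifnot(inherits(a, "categorical_raster"), inherits(b, "categorical_raster"))
  if (!identical(dim(a$grid), dim(b$grid))) abort("rasters have different shapes")
  if (!isTRUE(all.equal(a$cell_size, b$cell_size))) {
    abort("rasters have different cell sizes")
  }
  if (!identical(a$origin, b$origin)) abort("rasters have different georeferences")
  tab <- table(from_class = as.vector(a$grid), to_class = as.vector(b$grid))
  out <- as_tibble(tab)
  out <- dplyr::mutate(out,
                       from_class = as.integer(.data$from_class),
                       to_class = as.integer(.data$to_class))
  out <- dplyr::filter(out, .data$n > 0)
  out <- dplyr::arrange(out, .data$from_class, .data$to_class)
  attr(out, "period") <- period
  out
}

#' Binary mask of one class transition
#'
#' Foreground exactly where `a` holds `from_class` and `b` holds
#' `to_class` — e.g. the forest-to-agriculture transition that defines
#' deforestation. The foreground count equals the matching cross-tabulation
#' entry.
#'
#' @inheritParams crosstab_rasters
#' @param from_class,to_class Class ids present in the respective legends.
#' @return A [binary_landscape()].
#' @export
transition_mask <- function(a, b, from_class, to_class) {
  stopifnot(inherits(a, "categorical_raster"), inherits(b, "categorical_raster"))
  if (!identical(dim(a$grid), dim(b$grid))) abort("rasters have different shapes")
  if (!as.character(from_class) %in% names(a$legend)) {
    abort(sprintf("unknown `from_class` %s", from_class))
  }
  if (!as.character(to_class) %in% names(b$legend)) {
    abort(sprintf("unknown `to_class` %s", to_class))
  }
  binary_landscape(a$grid == from_class & b$grid == to_class,
                   a$cell_size, a$origin)
}

#' Accumulate period masks into a cumulative series
#'
#' Element k of the result is the union of masks 1..k, turning per-period
#' transition masks into the cumulative deforestation images the fractal
#' analysis runs on. Idempotent: accumulating an already cumulative series
#' returns it unchanged.
#'
#' @param masks List of aligned [binary_landscape()] objects in
#'   chronological order, or a [growth_series()].
#' @param labels Optional step labels (e.g. `"1985-1995"`).
#' @return A [growth_series()].
#' @export
accumulate_masks <- function(masks, labels = NULL) {
  if (inherits(masks, "growth_series")) {
    if (is.null(labels)) labels <- masks$labels
    masks <- masks$landscapes
  }
  if (!length(masks)) abort("`masks` must be non-empty")
  ok <- vapply(masks, inherits, logical(1), "binary_landscape")
  if (!all(ok)) abort("all elements must be binary_landscape objects")
  for (i in seq_along(masks)[-1]) check_aligned(masks[[1]], masks[[i]], "masks")
  acc <- masks[[1]]$grid
  out <- vector("list", length(masks))
  out[[1]] <- masks[[1]]
  for (i in seq_along(masks)[-1]) {
    acc <- acc | masks[[i]]$grid
    out[[i]] <- binary_landscape(acc, masks[[1]]$cell_size, masks[[1]]$origin)
  }
  growth_series(out, labels)
}
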