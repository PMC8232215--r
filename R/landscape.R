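#' Binary landscape container
#'
#' A `binary_landscape` is a rectangular boolean lattice in which `TRUE`
#' marks deforested (foreground) cells and `FALSE` remaining forest or other
#' background, together with the physical side length of a cell in metres.
#' This internal polarity is fixed regardless of any on-disk 0/1 coding;
#' converters live in the I/O layer (see [write_mask()]).
#'
#' @param grid Logical matrix (`TRUE` = deforested). Integer/numeric 0-1
#'   matrices are accepted and coerced.
#' @param cell_size Cell side length in metres (default 30, the resolution
#'   of the Landsat-derived land-cover products the method targets).
#' @param origin Optional georeference tag: a list with elements `xll`,
#'   `yll` (lower-left corner coordinates) and optionally `crs` (a label).
#'
#' @return An object of class `binary_landscape`.
#' @examples
#' bl <- binary_landscape(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' fg_count(bl)
#' @export
binary_landscape <- function(grid, cell_size = 30, origin = NULL) {
  if (is.numeric(grid) || is.integer(grid)) {
    if (!all(grid %in% c(0, 1))) {
      abort("numeric `grid` must contain only 0 and 1")
    }
    storage.mode(grid) <- "logical"
  }
  if (!is.matrix(grid) || !is.logical(grid)) {
    abort("`grid` must be a logical matrix")
  }
  if (nrow(grid) < 1 || ncol(grid) < 1) abort("`grid` must be non-empty")
  if (anyNA(grid)) abort("`grid` must not contain NA")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number")
  }
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size), origin = origin),
    class = "binary_landscape"
  )
}

#' @export
print.binary_landscape <- function(x, ...) {
  cat(sprintf(
    "<binary_landscape> %d x %d cells, %g m/cell, %d foreground (%.1f%%)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, fg_count(x),
    100 * mean(x$grid)
  ))
  invisible(x)
}

#' @export
dim.binary_landscape <- function(x) dim(x$grid)

#' Number of foreground (deforested) cells
#' @param x A [binary_landscape()].
#' @return Integer count.
#' @export
fg_count <- function(x) {
  stopifnot(inherits(x, "binary_landscape"))
  sum(x$grid)
}

#' @describeIn binary_landscape Coerce to a tibble with one row per cell
#'   (`row`, `col`, `deforested`).
#' @param x,... Method arguments.
#' @exportS3Method tibble::as_tibble
as_tibble.binary_landscape <- function(x, ...) {
  idx <- which(x$grid | !x$grid, arr.ind = TRUE)  # all cells, column-major
  tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    deforested = as.vector(x$grid)
  )
}

check_aligned <- function(a, b, what = "landscapes") {
  if (!identical(dim(a$grid), dim(b$grid))) {
    abort(sprintf("%s have different shapes", what))
  }
  if (!isTRUE(all.equal(a$cell_size, b$cell_size))) {
    abort(sprintf("%s have different cell sizes", what))
  }
  invisible(TRUE)
}

#' Categorical land-use/land-cover raster
#'
#' Integer class lattice with a legend mapping class ids to labels, used as
#' the input for transition detection.
#'
#' @param grid Integer matrix of class ids.
#' @param legend Named character vector or named list: names are class ids
#'   (as character), values are labels. Defaults to the observed ids.
#' @param cell_size Cell side length in metres.
#' @param origin Optional georeference tag (see [binary_landscape()]).
#' @return An object of class `categorical_raster`.
#' @examples
#' cr <- categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2),
#'                          legend = c(`1` = "forest", `2` = "agriculture"))
#' @export
categorical_raster <- function(grid, legend = NULL, cell_size = 30,
                               origin = NULL) {
  if (!is.matrix(grid)) abort("`grid` must be a matrix")
  storage.mode(grid) <- "integer"
  if (anyNA(grid)) abort("`grid` must not contain NA")
  ids <- sort(unique(as.vector(grid)))
  if (is.null(legend)) {
    legend <- setNames(as.character(ids), as.character(ids))
  }
  legend <- unlist(legend)
  missing_ids <- setdiff(ids, as.integer(names(legend)))
  if (length(missing_ids)) {
    abort(sprintf(
      "classes present in `grid` but absent from `legend`: %s",
      paste(missing_ids, collapse = ", ")
    ))
  }
  structure(
    list(grid = grid, legend = legend, cell_size = as.numeric(cell_size),
         origin = origin),
    class = "categorical_raster"
  )
}

#' @export
print.categorical_raster <- function(x, ...) {
  cat(sprintf(
    "<categorical_raster> %d x %d cells, %g m/cell, %d classes\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, length(x$legend)
  ))
  invisible(x)
}

#' @export
dim.categorical_raster <- function(x) dim(x$grid)

#' Cumulative growth series of binary landscapes
#'
#' An ordered list of aligned [binary_landscape()] objects whose foreground
#' is monotone non-decreasing (each step contains the previous), as produced
#' by accumulating per-period deforestation masks or by [simulate_growth()].
#'
#' @param landscapes List of aligned `binary_landscape` objects in
#'   chronological order.
#' @param labels Character step labels (default `"t1"`, `"t2"`, ...).
#' @param check Verify the cumulative-union invariant (default `TRUE`).
#' @return An object of class `growth_series` (a list with elements
#'   `landscapes` and `labels`).
#' @export
growth_series <- function(landscapes, labels = NULL, check = TRUE) {
  if (!length(landscapes)) abort("`landscapes` must be non-empty")
  ok <- vapply(landscapes, inherits, logical(1), "binary_landscape")
  if (!all(ok)) abort("all elements must be binary_landscape objects")
  if (is.null(labels)) labels <- paste0("t", seq_along(landscapes))
  if (length(labels) != length(landscapes)) {
    abort("`labels` must match the number of steps")
  }
  for (i in seq_along(landscapes)[-1]) {
    check_aligned(landscapes[[i - 1]], landscapes[[i]], "series steps")
    if (check && any(landscapes[[i - 1]]$grid & !landscapes[[i]]$grid)) {
      abort(sprintf(
        "cumulative-union invariant violated between steps %d and %d", i - 1, i
      ))
    }
  }
  structure(list(landscapes = landscapes, labels = as.character(labels)),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  counts <- vapply(x$landscapes, fg_count, numeric(1))
  cat(sprintf("<growth_series> %d steps (%s), foreground %s\n",
              length(x$landscapes),
              paste(x$labels, collapse = ", "),
              paste(counts, collapse = " -> ")))
  invisible(x)
}

#' @export
length.growth_series <- function(x) length(x$landscapes)
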