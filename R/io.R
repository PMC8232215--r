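#' @title Raster and LCFD text I/O
#' @description Readers and writers for the plain-text ESRI ASCII grid
#'   format and the per-pixel LCFD list. On disk, binary deforestation masks
#'   follow the historical coding of the source maps — 0 marks forest loss
#'   and 1 the background — unless the `polarity` flag says otherwise; in
#'   memory the polarity is always `TRUE` = deforested.
#' @name raster-io
NULL

write_ascii_grid_impl <- function(values, cell_size, origin, path,
                                  nodata = -9999) {
  xll <- if (!is.null(origin$xll)) origin$xll else 0
  yll <- if (!is.null(origin$yll)) origin$yll else 0
  header <- c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  vals <- values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

read_ascii_grid_impl <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  values <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }))
  if (!is.null(header$nodata_value)) {
    values[values == header$nodata_value] <- NA
  }
  if (!is.null(header$nrows) && nrow(values) != header$nrows) {
    abort(sprintf("corrupt grid: %d rows read, %d declared",
                  nrow(values), header$nrows))
  }
  list(values = values, header = header)
}

#' Write a binary mask as an ASCII grid
#'
#' @param mask A [binary_landscape()].
#' @param path Output file path.
#' @param polarity `"legacy"` (default): 0 = deforested, 1 = background, the
#'   coding of the source products; `"standard"`: 1 = deforested.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path, polarity = c("legacy", "standard")) {
  stopifnot(inherits(mask, "binary_landscape"))
  polarity <- match.arg(polarity)
  vals <- if (polarity == "legacy") 1L - mask$grid * 1L else mask$grid * 1L
  write_ascii_grid_impl(vals, mask$cell_size, mask$origin, path)
}

#' Read a binary mask from an ASCII grid
#'
#' @param path File written by [write_mask()] (or any 0/1 ASCII grid).
#' @inheritParams write_mask
#' @return A [binary_landscape()] (internal polarity `TRUE` = deforested).
#' @export
read_mask <- function(path, polarity = c("legacy", "standard")) {
  polarity <- match.arg(polarity)
  gr <- read_ascii_grid_impl(path)
  vals <- gr$values
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    abort("mask file must contain only 0 and 1")
  }
  grid <- if (polarity == "legacy") vals == 0 else vals == 1
  origin <- list(xll = gr$header$xllcorner %||% 0,
                 yll = gr$header$yllcorner %||% 0)
  binary_landscape(grid, gr$header$cellsize %||% 30, origin)
}

#' Write / read a categorical raster as an ASCII grid
#'
#' @param raster A [categorical_raster()].
#' @param path File path.
#' @return `write_categorical` the path invisibly; `read_categorical` a
#'   [categorical_raster()] (legend defaults to the observed class ids).
#' @export
write_categorical <- function(raster, path) {
  stopifnot(inherits(raster, "categorical_raster"))
  write_ascii_grid_impl(raster$grid, raster$cell_size, raster$origin, path)
}

#' @rdname write_categorical
#' @export
read_categorical <- function(path) {
  gr <- read_ascii_grid_impl(path)
  if (anyNA(gr$values)) abort("categorical raster must not contain NODATA")
  origin <- list(xll = gr$header$xllcorner %||% 0,
                 yll = gr$header$yllcorner %||% 0)
  categorical_raster(matrix(as.integer(gr$values), nrow(gr$values)),
                     cell_size = gr$header$cellsize %||% 30, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the per-pixel LCFD list
#'
#' The text list holds one row per deforested pixel with `X` the column
#' index, `Y` the row index (raster scan order, 1-based) and the LCFD value.
#'
#' @param map An [lcfd_map()] result.
#' @param path File path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `write_lcfd_text` the path invisibly; `read_lcfd_text` a tibble
#'   with columns `X`, `Y`, `LCFD`.
#' @export
write_lcfd_text <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "lcfd_map"))
  tb <- tidy(map)
  readr::write_delim(
    tibble(X = tb$col, Y = tb$row, LCFD = tb$lcfd), path, delim = sep
  )
  invisible(path)
}

#' @rdname write_lcfd_text
#' @export
read_lcfd_text <- function(path, sep = "\t") {
  readr::read_delim(path, delim = sep, col_types = "iid", progress = FALSE)
}

#' Write / read an LCFD raster (ASCII grid with NODATA background)
#'
#' @inheritParams write_lcfd_text
#' @return `write_lcfd_raster` the path invisibly; `read_lcfd_raster` an
#'   [lcfd_map()] object.
#' @export
write_lcfd_raster <- function(map, path) {
  stopifnot(inherits(map, "lcfd_map"))
  write_ascii_grid_impl(map$values, map$cell_size, map$origin, path)
}

#' @rdname write_lcfd_raster
#' @export
read_lcfd_raster <- function(path) {
  gr <- read_ascii_grid_impl(path)
  origin <- list(xll = gr$header$xllcorner %||% 0,
                 yll = gr$header$yllcorner %||% 0)
  new_lcfd_map(gr$values, gr$header$cellsize %||% 30,
               scales = NA_integer_, origin = origin)
}
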