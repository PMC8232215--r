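#' Classify an LCFD map with a threshold set
#'
#' Half-open, lower-inclusive interval binning: class c covers
#' `[cut[c-1], cut[c])`, values below the first cut are class 1 and values
#' at or above the last cut fall in the top class, so a value exactly equal
#' to a cut belongs to the class above it. Background stays 0.
#'
#' @param map An [lcfd_map()].
#' @param thresholds A [threshold_set()] or numeric cut vector.
#' @return An object of class `classified_map`: `classes` (integer matrix,
#'   0 = background), `legend` (tibble `class`, `interval`, `label`,
#'   `color`), `cuts`, `cell_size`.
#' @examples
#' cm <- classify_lcfd(lcfd_map(make_filled(63)), c(1, 1.57))
#' unique(as.vector(cm$classes))  # 3 everywhere (LCFD = 2)
#' @export
classify_lcfd <- function(map, thresholds) {
  stopifnot(inherits(map, "lcfd_map"))
  cuts <- threshold_cuts(thresholds)
  if (!length(cuts)) {
    warn("empty threshold set: single-class map")
  }
  if (any(duplicated(cuts))) abort("cuts must be strictly increasing")
  vals <- map$values
  cls <- matrix(0L, nrow(vals), ncol(vals))
  fg <- !is.na(vals)
  cls[fg] <- findInterval(vals[fg], cuts) + 1L
  n_class <- length(cuts) + 1L
  bounds <- c(-Inf, cuts, Inf)
  legend <- tibble(
    class = seq_len(n_class),
    interval = sprintf("[%s, %s)", formatC(bounds[seq_len(n_class)], digits = 3),
                       formatC(bounds[-1][seq_len(n_class)], digits = 3)),
    label = paste0("class ", seq_len(n_class)),
    color = grDevices::hcl.colors(n_class, "Zissou 1")
  )
  structure(
    list(classes = cls, legend = legend, cuts = cuts,
         cell_size = map$cell_size, origin = map$origin),
    class = "classified_map"
  )
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- tabulate(x$classes[x$classes > 0], nbins = nrow(x$legend))
  cat(sprintf("<classified_map> %d x %d cells, %d classes (%s)\n",
              nrow(x$classes), ncol(x$classes), nrow(x$legend),
              paste(tab, collapse = "/")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classified_map <- function(x, ...) {
  tab <- tabulate(x$classes[x$classes > 0], nbins = nrow(x$legend))
  dplyr::mutate(x$legend, n = tab,
                area_ha = tab * x$cell_size^2 / 1e4,
                fraction = if (sum(tab) > 0) tab / sum(tab) else NA_real_)
}

#' Qualitative spatial-process annotation of LCFD classes
#'
#' Attaches the standard qualitative reading to each class: local dimensions
#' below 1 indicate isolated, simple patches (perforation / dissection
#' candidates, low-impact transformation); between 1 and the detected high
#' cut, connected fragmentation mosaics; at or above the high cut, the
#' aggressive expansion regime (shrinkage / attrition candidates). These are
#' annotations to aid visual interpretation, not detections.
#'
#' @param classified A [classify_lcfd()] result.
#' @param thresholds The threshold set used (for the cut values).
#' @return A tibble: `class`, `interval`, `regime`, `n`, `area_ha`,
#'   `fraction`. Per-class areas sum to the deforested area.
#' @export
interpret_classes <- function(classified, thresholds = classified$cuts) {
  stopifnot(inherits(classified, "classified_map"))
  cuts <- threshold_cuts(thresholds)
  high_cut <- if (any(cuts > 1)) min(cuts[cuts > 1]) else NA_real_
  bounds <- c(-Inf, cuts)
  regime <- vapply(seq_len(length(cuts) + 1L), function(c) {
    lo <- bounds[c]
    if (lo < 1) {
      "low-impact (perforation/dissection candidates)"
    } else if (!is.na(high_cut) && lo < high_cut) {
      "fragmentation"
    } else {
      "high-impact (shrinkage/attrition candidates)"
    }
  }, character(1))
  dplyr::mutate(tidy(classified), regime = regime, .after = "interval")
}

#' @describeIn classify_lcfd Tile plot of the classified map with its legend.
#' @param object,... Method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.classified_map <- function(object, ...) {
  idx <- which(object$classes > 0, arr.ind = TRUE)
  df <- tibble(
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
    class = factor(object$classes[idx], levels = object$legend$class,
                   labels = object$legend$label)
  )
  pal <- setNames(object$legend$color, object$legend$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "LCFD class") +
    ggplot2::theme_minimal()
}

#' @describeIn lcfd_map Continuous tile plot of the LCFD map.
#' @param object Method argument.
#' @exportS3Method ggplot2::autoplot
autoplot.lcfd_map <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$lcfd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "LCFD") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @describeIn ca_curve Log-exceedance-area curve with detected thresholds.
#' @param object,... Method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.ca_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$C, y = .data$log10_A)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "concentration C (LCFD)",
                  y = expression(log[10] ~ A(rho >= C))) +
    ggplot2::theme_minimal()
}

#' Render a classified map to a PNG and an ASCII class raster
#'
#' @param classified A [classify_lcfd()] result.
#' @param path Output PNG path; a sibling `.asc` class raster is written
#'   next to it.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return Invisibly, the paths written (`png`, `asc`).
#' @export
render_map <- function(classified, path, width = 7, height = 7, dpi = 150) {
  stopifnot(inherits(classified, "classified_map"))
  p <- autoplot(classified)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  asc <- sub("\\.png$", ".asc", path)
  if (identical(asc, path)) asc <- paste0(path, ".asc")
  write_ascii_grid_impl(classified$classes, classified$cell_size,
                        classified$origin, asc)
  invisible(list(png = path, asc = asc))
}

#' Write / read a classified map as an ASCII grid
#' @param classified A `classified_map`.
#' @param path File path.
#' @param cuts The cuts used (needed to rebuild the legend on read).
#' @return `write_classes` the path invisibly; `read_classes` the integer
#'   class matrix.
#' @export
write_classes <- function(classified, path) {
  stopifnot(inherits(classified, "classified_map"))
  write_ascii_grid_impl(classified$classes, classified$cell_size,
                        classified$origin, path)
}

#' @rdname write_classes
#' @export
read_classes <- function(path) {
  gr <- read_ascii_grid_impl(path)
  matrix(as.integer(gr$values), nrow(gr$values))
}
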