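#' Default box-counting scale schedule
#'
#' The ordered odd box side lengths used for the local connected fractal
#' dimension: 3, 7, 11, 15, 19, 23, 27, 31 pixels (90-930 m at 30 m
#' resolution). The largest box keeps the analysis local while leaving
#' enough scales for a stable log-log regression.
#'
#' @return Integer vector of box side lengths.
#' @export
default_scales <- function() c(3L, 7L, 11L, 15L, 19L, 23L, 27L, 31L)

check_scales <- function(scales) {
  scales <- as.integer(scales)
  if (length(scales) < 2) abort("at least 2 box sizes are required")
  if (any(scales < 3) || any(scales %% 2 == 0)) {
    abort("box sides must be odd and at least 3")
  }
  if (any(diff(scales) <= 0)) abort("box sides must be strictly increasing")
  scales
}

#' Locally connected set around a pixel
#'
#' The 8-connected cluster containing the center pixel, traced within the
#' window of the largest scanning box (clipped at the image border). Pixels
#' of other clusters inside the window are excluded.
#'
#' @param mask A [binary_landscape()].
#' @param center `c(row, col)` of a foreground pixel (1-based).
#' @param max_box Odd window side length (default the largest default box).
#' @return A list: `window` (logical matrix of the connected set),
#'   `row_offset`, `col_offset` (top-left of the window minus 1), `center`
#'   (local coordinates of the focal pixel).
#' @export
local_connected_set <- function(mask, center, max_box = max(default_scales())) {
  stopifnot(inherits(mask, "binary_landscape"))
  if (max_box %% 2 == 0 || max_box < 3) abort("`max_box` must be odd and >= 3")
  r0 <- as.integer(center[1]); c0 <- as.integer(center[2])
  g <- mask$grid
  if (r0 < 1 || r0 > nrow(g) || c0 < 1 || c0 > ncol(g)) {
    abort("`center` is outside the grid")
  }
  if (!g[r0, c0]) abort("`center` must be a foreground pixel")
  R <- (max_box - 1L) %/% 2L
  rows <- max(1L, r0 - R):min(nrow(g), r0 + R)
  cols <- max(1L, c0 - R):min(ncol(g), c0 + R)
  win <- g[rows, cols, drop = FALSE]
  lab <- cc_label(win, 8L)
  ctr <- c(r0 - rows[1] + 1L, c0 - cols[1] + 1L)
  list(window = lab == lab[ctr[1], ctr[2]],
       row_offset = rows[1] - 1L, col_offset = cols[1] - 1L,
       center = ctr, max_box = as.integer(max_box))
}

#' Box-counting mass profile at one pixel
#'
#' M(eps) is the number of locally connected pixels inside the eps-box
#' centered on the focal pixel, for each scheduled box side; boxes are
#' clipped at the image border. The mass is computed on the connected set
#' traced once at the largest scale.
#'
#' @param local A locally connected set from [local_connected_set()].
#' @param scales Ordered odd box sides; must not exceed the window the set
#'   was traced at.
#' @return Named numeric vector `M(eps)` indexed by box side.
#' @export
mass_profile <- function(local, scales = default_scales()) {
  scales <- check_scales(scales)
  win <- local$window
  ctr <- local$center
  if (!is.null(local$max_box) && max(scales) > local$max_box) {
    abort("schedule exceeds the window the connected set was traced at")
  }
  m <- vapply(scales, function(s) {
    rad <- (s - 1L) %/% 2L
    rows <- max(1L, ctr[1] - rad):min(nrow(win), ctr[1] + rad)
    cols <- max(1L, ctr[2] - rad):min(ncol(win), ctr[2] + rad)
    sum(win[rows, cols])
  }, numeric(1))
  setNames(m, scales)
}

#' Fit the local connected fractal dimension from a mass profile
#'
#' Ordinary least-squares slope of `log M(eps)` on `log eps` over the
#' schedule. A completely filled neighborhood (`M = eps^2`) gives exactly 2,
#' a unit-width straight line (`M = eps`) exactly 1, and an isolated pixel
#' (`M = 1` at all scales) 0.
#'
#' @param profile Mass profile from [mass_profile()] (or any positive
#'   vector, one value per scale).
#' @param scales Box sides the profile was computed at.
#' @return The fitted dimension (slope).
#' @examples
#' fit_dimension(default_scales()^2)  # 2
#' fit_dimension(default_scales())    # 1
#' @export
fit_dimension <- function(profile, scales = default_scales()) {
  scales <- check_scales(scales)
  if (length(profile) != length(scales)) {
    abort("`profile` and `scales` must have the same length")
  }
  if (any(profile < 1)) abort("masses must be at least 1 (the center pixel)")
  x <- log(scales)
  w <- (x - mean(x)) / sum((x - mean(x))^2)
  sum(w * log(profile))
}

new_lcfd_map <- function(values, cell_size, scales, r_squared = NULL,
                         origin = NULL) {
  structure(
    list(values = values, cell_size = cell_size, scales = scales,
         r_squared = r_squared, origin = origin),
    class = "lcfd_map"
  )
}

#' Local connected fractal dimension map
#'
#' Computes the LCFD at every foreground (deforested) pixel of a binary
#' mask: the 8-connected cluster containing the pixel is traced within the
#' largest scheduled box, the box-counting masses `M(eps)` are counted for
#' every scheduled box side (boxes clipped at image borders), and the
#' dimension is the OLS slope of `log M` on `log eps`. Background pixels are
#' missing. The per-pixel regression R-squared is kept as a diagnostic band
#' (`NA` where the mass profile is constant).
#'
#' Values are not clipped to `[0, 2]`; ring-like geometries can exceed 2 and
#' are reported as-is (the useful interpretation range is 1 < LCFD <= 2).
#'
#' @param mask A [binary_landscape()].
#' @param scales Ordered odd box sides (default [default_scales()]).
#' @param skip_margin If `TRUE`, pixels closer than half the largest box to
#'   a border are omitted instead of using clipped boxes.
#' @return An object of class `lcfd_map`: `values` and `r_squared` matrices
#'   in register with the mask, `cell_size`, `scales`.
#' @examples
#' m <- lcfd_map(make_filled(63))
#' m$values[32, 32]  # 2
#' @export
lcfd_map <- function(mask, scales = default_scales(), skip_margin = FALSE) {
  stopifnot(inherits(mask, "binary_landscape"))
  scales <- check_scales(scales)
  vals <- matrix(NA_real_, nrow(mask$grid), ncol(mask$grid))
  r2 <- vals
  if (!any(mask$grid)) {
    warn("empty mask: LCFD map has no foreground")
    return(new_lcfd_map(vals, mask$cell_size, scales, r2, mask$origin))
  }
  res <- lcfd_masses(mask$grid, scales)
  logm <- log(res$mass)
  x <- log(scales)
  xc <- x - mean(x)
  w <- xc / sum(xc^2)
  slope <- as.vector(logm %*% w)
  # diagnostic R^2 of the per-pixel log-log fit
  ybar <- rowMeans(logm)
  ss_tot <- rowSums((logm - ybar)^2)
  fitted <- outer(slope, xc) + ybar
  ss_res <- rowSums((logm - fitted)^2)
  r2_vec <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  idx <- cbind(res$row, res$col)
  vals[idx] <- slope
  r2[idx] <- r2_vec
  if (skip_margin) {
    R <- (max(scales) - 1L) %/% 2L
    nr <- nrow(vals); nc <- ncol(vals)
    if (nr <= 2 * R || nc <= 2 * R) {
      abort("`skip_margin` leaves no interior pixels on this grid")
    }
    keep <- matrix(FALSE, nr, nc)
    keep[(R + 1):(nr - R), (R + 1):(nc - R)] <- TRUE
    vals[!keep] <- NA_real_
    r2[!keep] <- NA_real_
  }
  new_lcfd_map(vals, mask$cell_size, scales, r2, mask$origin)
}

#' @export
print.lcfd_map <- function(x, ...) {
  n <- sum(!is.na(x$values))
  cat(sprintf("<lcfd_map> %d x %d cells, %d valued pixels",
              nrow(x$values), ncol(x$values), n))
  if (n) {
    cat(sprintf(", median %.3f, range [%.3f, %.3f]",
                median(x$values, na.rm = TRUE),
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.lcfd_map <- function(x) dim(x$values)

#' LCFD values of a map as a vector
#' @param map An [lcfd_map()].
#' @return Numeric vector of the foreground LCFD values, raster scan order.
#' @export
lcfd_values <- function(map) {
  stopifnot(inherits(map, "lcfd_map"))
  v <- t(map$values)  # raster scan: rows left-to-right, then down
  as.vector(v[!is.na(v)])
}

#' @describeIn lcfd_map One row per valued pixel: `row`, `col`, `lcfd`,
#'   `r_squared`.
#' @param x,... Method arguments.
#' @exportS3Method generics::tidy
tidy.lcfd_map <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])  # raster scan order
  idx <- idx[ord, , drop = FALSE]
  tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    lcfd = x$values[idx],
    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared[idx]
  )
}

#' @describeIn lcfd_map One-row summary: pixel count, median, quartiles,
#'   range, mean diagnostic R-squared.
#' @exportS3Method generics::glance
glance.lcfd_map <- function(x, ...) {
  v <- lcfd_values(x)
  tibble(
    n = length(v),
    median = if (length(v)) median(v) else NA_real_,
    q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
    q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_,
    mean_r_squared = mean(x$r_squared, na.rm = TRUE)
  )
}

#' LCFD frequency distribution
#'
#' Binned frequencies of the map's values over their observed range,
#' together with order statistics. The frequencies sum to the number of
#' valued (foreground) pixels.
#'
#' @param map An [lcfd_map()], or a numeric vector of LCFD values.
#' @param n_bins Number of equal-width bins (default 64).
#' @return A list of class `lcfd_distribution`: `histogram` (tibble `lower`,
#'   `upper`, `mid`, `count`), `summary` (tibble `n`, `median`, `q25`,
#'   `q75`, `min`, `max`), `values`.
#' @export
lcfd_distribution <- function(map, n_bins = 64) {
  v <- if (inherits(map, "lcfd_map")) lcfd_values(map) else as.numeric(map)
  if (!length(v)) abort("no LCFD values to summarize")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  structure(
    list(
      histogram = tibble(
        lower = breaks[-length(breaks)], upper = breaks[-1],
        mid = (breaks[-length(breaks)] + breaks[-1]) / 2, count = counts
      ),
      summary = tibble(
        n = length(v), median = median(v),
        q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)),
        min = rng[1], max = rng[2]
      ),
      values = v
    ),
    class = "lcfd_distribution"
  )
}

#' @export
print.lcfd_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<lcfd_distribution> n=%d, median %.3f, IQR [%.3f, %.3f], range [%.3f, %.3f]\n",
    s$n, s$median, s$q25, s$q75, s$min, s$max
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lcfd_distribution <- function(x, ...) x$histogram

#' @exportS3Method generics::glance
glance.lcfd_distribution <- function(x, ...) x$summary
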