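#' @title Synthetic landscape generators
#' @description Deterministic fixtures and stochastic generators producing
#'   binary deforestation masks with known geometric structure: the analytic
#'   anchors of the local connected fractal dimension (filled plane, straight
#'   line, isolated points), the maximally disaggregated checkerboard, the
#'   five canonical spatial processes of habitat transformation, and a
#'   nucleated contagion growth model yielding cumulative series.
#' @name synthetic
NULL

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

normalize_shape <- function(shape) {
  if (length(shape) == 1) shape <- c(shape, shape)
  if (length(shape) != 2 || any(shape < 1) || any(shape != round(shape))) {
    abort("`shape` must be one or two positive integers")
  }
  as.integer(shape)
}

#' Fully deforested landscape
#'
#' All cells foreground: the two-dimensional anchor of the local connected
#' fractal dimension (every mass profile is the full box, so the fitted
#' dimension at interior pixels is exactly 2).
#'
#' @param shape Grid shape, one integer (square) or `c(nrow, ncol)`. Must be
#'   at least the largest default box side (31) in each dimension; 63 or
#'   more gives interior pixels with unclipped windows.
#' @param cell_size Cell side length in metres.
#' @return A [binary_landscape()].
#' @examples
#' fg_count(make_filled(63))  # 3969
#' @export
make_filled <- function(shape = c(63, 63), cell_size = 30) {
  shape <- normalize_shape(shape)
  if (min(shape) < max(default_scales())) {
    abort("`shape` must be at least the largest box side (31) in each dimension")
  }
  binary_landscape(matrix(TRUE, shape[1], shape[2]), cell_size)
}

#' Straight-line landscape
#'
#' A single straight run of foreground of the given width through the grid
#' center: the one-dimensional anchor (unit width gives fitted dimension
#' exactly 1 at pixels away from the line ends).
#'
#' @inheritParams make_filled
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param width Line width in cells (default 1).
#' @return A [binary_landscape()].
#' @export
make_line <- function(shape = c(63, 63), orientation = c("horizontal", "vertical"),
                      width = 1, cell_size = 30) {
  shape <- normalize_shape(shape)
  orientation <- match.arg(orientation)
  if (width >= min(shape)) abort("`width` must be smaller than the grid")
  if (width < 1) abort("`width` must be at least 1")
  len <- if (orientation == "horizontal") shape[2] else shape[1]
  if (len < max(default_scales())) {
    abort("line length must be at least the largest box side (31)")
  }
  g <- matrix(FALSE, shape[1], shape[2])
  center <- (shape + 1L) %/% 2L
  band <- center[if (orientation == "horizontal") 1 else 2] +
    seq_len(width) - 1L - (width - 1L) %/% 2L
  if (orientation == "horizontal") g[band, ] <- TRUE else g[, band] <- TRUE
  binary_landscape(g, cell_size)
}

#' Isolated single-pixel patches
#'
#' `n` single foreground cells at pairwise Chebyshev distance of at least
#' `min_separation`. When the separation exceeds the largest box side, each
#' point's locally connected set is itself, so its fractal dimension is 0.
#'
#' @inheritParams make_filled
#' @param n Number of points.
#' @param min_separation Minimum pairwise Chebyshev distance in cells.
#' @param seed Integer seed; same seed gives a bit-identical grid.
#' @return A [binary_landscape()].
#' @export
make_isolated_points <- function(shape = c(256, 256), n = 5,
                                 min_separation = 40, seed = 1,
                                 cell_size = 30) {
  shape <- normalize_shape(shape)
  if (n < 1) abort("`n` must be positive")
  with_seed_(seed, {
    pts <- matrix(NA_integer_, 0, 2)
    tries <- 0L
    max_tries <- 1000L * n
    while (nrow(pts) < n && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(sample.int(shape[1], 1), sample.int(shape[2], 1))
      if (nrow(pts) == 0 ||
          all(pmax(abs(pts[, 1] - cand[1]), abs(pts[, 2] - cand[2])) >=
                min_separation)) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) < n) {
      abort(sprintf(
        "could not place %d points at Chebyshev separation %d on a %dx%d grid (placed %d after %d draws)",
        n, min_separation, shape[1], shape[2], nrow(pts), tries
      ))
    }
    g <- matrix(FALSE, shape[1], shape[2])
    g[pts] <- TRUE
    binary_landscape(g, cell_size)
  })
}

#' Checkerboard landscape
#'
#' Alternating single-cell foreground/background: foreground proportion
#' exactly 0.5 with zero like (rook) adjacencies, the maximally
#' disaggregated configuration for which the clumpiness index is exactly -1.
#'
#' @inheritParams make_filled
#' @return A [binary_landscape()].
#' @examples
#' clumpy(make_checkerboard(64))  # -1
#' @export
make_checkerboard <- function(shape = c(64, 64), cell_size = 30) {
  shape <- normalize_shape(shape)
  if (any(shape %% 2 != 0)) abort("`shape` must be even-sided")
  g <- outer(seq_len(shape[1]), seq_len(shape[2]), function(r, c) (r + c) %% 2 == 0)
  binary_landscape(g, cell_size)
}

dilate_mask <- function(grid, radius, shape = c("disc", "box")) {
  shape <- match.arg(shape)
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = shape)
  out <- EBImage::dilate(
    matrix(as.numeric(grid), nrow(grid), ncol(grid)), kern
  )
  matrix(as.vector(out) > 0.5, nrow(grid), ncol(grid))
}

#' Apply a canonical spatial process of habitat transformation
#'
#' Transforms a landscape by one of the five spatial processes of forest
#' loss. The convention is that foreground (`TRUE`) is deforested and the
#' background is remaining forest, so "perforation" punches deforested holes
#' into forest, "dissection" carves a constant-width deforested strip,
#' "fragmentation" carves a grid of strips splitting the forest into
#' disconnected remnants, "shrinkage" erodes forest patch boundaries by
#' dilating the deforested area, and "attrition" deletes whole forest
#' patches, smallest first.
#'
#' Each process is a deterministic, parameterized morphological recipe;
#' where placement is random (perforation hole centers) it is governed by
#' `seed`.
#'
#' @param base A [binary_landscape()] with at least one forest (background)
#'   cell.
#' @param process One of `"perforation"`, `"dissection"`, `"fragmentation"`,
#'   `"shrinkage"`, `"attrition"`.
#' @param n_holes,hole_radius Perforation: number and radius (cells) of the
#'   stamped discs. Holes are placed strictly inside forest, away from
#'   existing deforestation and from each other, so the forest patch count
#'   is unchanged and the deforested patch count grows by `n_holes`.
#' @param strip_width Dissection/fragmentation: strip width in cells.
#' @param orientation Dissection: `"horizontal"` or `"vertical"`.
#' @param position Dissection: row (or column) index of the strip center;
#'   default the grid center.
#' @param n_strips Fragmentation: number of strips per orientation.
#' @param erosion_radius Shrinkage: radius (cells) of the disc structuring
#'   element eroding the forest.
#' @param removal_fraction Attrition: fraction of total forest area removed,
#'   deleting smallest forest patches first until the fraction is reached.
#' @param seed Integer seed for random placement.
#' @return A [binary_landscape()] with the process applied (foreground is a
#'   superset of `base`'s).
#' @export
apply_process <- function(base,
                          process = c("perforation", "dissection",
                                      "fragmentation", "shrinkage",
                                      "attrition"),
                          n_holes = 3, hole_radius = 2,
                          strip_width = 2,
                          orientation = c("horizontal", "vertical"),
                          position = NULL, n_strips = 2,
                          erosion_radius = 2, removal_fraction = 0.5,
                          seed = 1) {
  stopifnot(inherits(base, "binary_landscape"))
  process <- tryCatch(match.arg(process),
                      error = function(e) abort(sprintf(
                        "unknown process '%s'", process[1])))
  g <- base$grid
  if (all(g)) abort("`base` has no forest (background) left to act on")
  out <- switch(
    process,
    perforation = {
      if (n_holes < 1 || hole_radius < 1) abort("perforation parameters must be positive")
      # eligible hole centers: disc plus a 1-cell buffer entirely in forest,
      # away from the image border, so holes never split or merge patches
      buffer <- hole_radius + 1L
      eligible <- !dilate_mask(g, buffer)
      nr <- nrow(g); nc <- ncol(g)
      eligible[c(seq_len(buffer), nr - seq_len(buffer) + 1L), ] <- FALSE
      eligible[, c(seq_len(buffer), nc - seq_len(buffer) + 1L)] <- FALSE
      with_seed_(seed, {
        for (k in seq_len(n_holes)) {
          cand <- which(eligible)
          if (!length(cand)) {
            abort(sprintf("no room for hole %d of %d at radius %d",
                          k, n_holes, hole_radius))
          }
          center <- cand[sample.int(length(cand), 1)]
          hole <- matrix(FALSE, nr, nc)
          hole[center] <- TRUE
          hole <- dilate_mask(hole, hole_radius)
          g <- g | hole
          blocked <- dilate_mask(hole, buffer + 1L)
          eligible <- eligible & !blocked
        }
        g
      })
    },
    dissection = {
      orientation <- match.arg(orientation)
      if (strip_width < 1) abort("`strip_width` must be positive")
      nr <- nrow(g); nc <- ncol(g)
      if (is.null(position)) {
        position <- if (orientation == "horizontal") (nr + 1L) %/% 2L else (nc + 1L) %/% 2L
      }
      band <- position + seq_len(strip_width) - 1L - (strip_width - 1L) %/% 2L
      if (orientation == "horizontal") {
        band <- band[band >= 1 & band <= nr]
        g[band, ] <- TRUE
      } else {
        band <- band[band >= 1 & band <= nc]
        g[, band] <- TRUE
      }
      g
    },
    fragmentation = {
      if (n_strips < 1 || strip_width < 1) abort("fragmentation parameters must be positive")
      nr <- nrow(g); nc <- ncol(g)
      rows <- round(seq_len(n_strips) * nr / (n_strips + 1))
      cols <- round(seq_len(n_strips) * nc / (n_strips + 1))
      for (p in rows) {
        band <- p + seq_len(strip_width) - 1L - (strip_width - 1L) %/% 2L
        g[band[band >= 1 & band <= nr], ] <- TRUE
      }
      for (p in cols) {
        band <- p + seq_len(strip_width) - 1L - (strip_width - 1L) %/% 2L
        g[, band[band >= 1 & band <= nc]] <- TRUE
      }
      g
    },
    shrinkage = {
      if (erosion_radius < 1) abort("`erosion_radius` must be positive")
      if (!any(g)) {
        warn("no deforested cells to grow from; shrinkage is a no-op")
        g
      } else {
        g | dilate_mask(g, erosion_radius)
      }
    },
    attrition = {
      if (removal_fraction < 0 || removal_fraction > 1) {
        abort("`removal_fraction` must be in [0, 1]")
      }
      forest <- label_patches(binary_landscape(!g, base$cell_size))
      sizes <- forest$sizes
      target <- removal_fraction * sum(sizes)
      ord <- order(sizes)  # smallest first
      cum <- cumsum(sizes[ord])
      drop <- ord[cum <= target + 1e-9]
      # remove at least enough patches to reach the target fraction
      if (length(drop) < length(ord) && (length(drop) == 0 ||
          cum[length(drop)] < target - 1e-9)) {
        drop <- ord[seq_len(length(drop) + 1L)]
      }
      g[forest$labels %in% drop] <- TRUE
      g
    }
  )
  binary_landscape(out, base$cell_size, base$origin)
}

#' Simulate cumulative nucleated deforestation growth
#'
#' A seeded contact (contagion) process: nuclei are planted at step 1, and at
#' each later step every forest cell that touches deforestation
#' (8-neighborhood) converts with probability `contagion_prob`, while any
#' forest cell may convert spontaneously with probability
#' `spontaneous_rate`. The series is cumulative by construction, emulating
#' the consolidation dynamics of frontier deforestation: aggregation
#' (clumpiness) rises as nuclei coalesce while the mean nearest-neighbor
#' distance first drops with infill and later rises as isolated remnants
#' dominate.
#'
#' @inheritParams make_filled
#' @param n_nuclei Number of initial clearing nuclei.
#' @param contagion_prob Per-step conversion probability of forest cells
#'   adjacent to deforestation, in (0, 1].
#' @param steps Number of time steps (landscapes) in the series.
#' @param seed Integer seed.
#' @param spontaneous_rate Per-step probability of spontaneous clearing of
#'   any forest cell (new nuclei).
#' @return A [growth_series()].
#' @examples
#' gs <- simulate_growth(shape = 64, n_nuclei = 4, steps = 3, seed = 7)
#' vapply(gs$landscapes, fg_count, numeric(1))  # non-decreasing
#' @export
simulate_growth <- function(shape = c(192, 192), n_nuclei = 25,
                            contagion_prob = 0.25, steps = 7, seed = 1,
                            spontaneous_rate = 2e-4, cell_size = 30) {
  shape <- normalize_shape(shape)
  if (n_nuclei < 1) abort("`n_nuclei` must be at least 1")
  if (contagion_prob <= 0 || contagion_prob > 1) {
    abort("`contagion_prob` must be in (0, 1]")
  }
  if (steps < 1) abort("`steps` must be at least 1")
  with_seed_(seed, {
    g <- matrix(FALSE, shape[1], shape[2])
    g[sample.int(length(g), n_nuclei)] <- TRUE
    series <- vector("list", steps)
    series[[1]] <- binary_landscape(g, cell_size)
    for (t in seq_len(steps - 1)) {
      frontier <- dilate_mask(g, 1, shape = "box") & !g  # 8-neighborhood
      convert <- frontier & matrix(stats::runif(length(g)) < contagion_prob,
                                   nrow(g), ncol(g))
      spont <- !g & !frontier &
        matrix(stats::runif(length(g)) < spontaneous_rate, nrow(g), ncol(g))
      g <- g | convert | spont
      series[[t + 1]] <- binary_landscape(g, cell_size)
    }
    growth_series(series)
  })
}
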