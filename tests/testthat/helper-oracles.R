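# Independent brute-force oracles, written against base R only, used to
# cross-check the package's C++/EBImage-backed implementations.

# 8-neighbor dilation by matrix shifts (no package code involved)
dilate8_r <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out | pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  out
}

# connected component containing (ci, cj), by repeated 8-neighbor growth
oracle_component <- function(win, ci, cj) {
  comp <- matrix(FALSE, nrow(win), ncol(win))
  comp[ci, cj] <- TRUE
  repeat {
    grown <- dilate8_r(comp) & win
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

# per-pixel box-counting masses recomputed from scratch by flood fill
oracle_masses <- function(g, r0, c0, scales) {
  R <- (max(scales) - 1L) %/% 2L
  rows <- max(1L, r0 - R):min(nrow(g), r0 + R)
  cols <- max(1L, c0 - R):min(ncol(g), c0 + R)
  win <- g[rows, cols, drop = FALSE]
  comp <- oracle_component(win, r0 - rows[1] + 1L, c0 - cols[1] + 1L)
  ci <- r0 - rows[1] + 1L; cj <- c0 - cols[1] + 1L
  vapply(scales, function(s) {
    rad <- (s - 1L) %/% 2L
    rr <- max(1L, ci - rad):min(nrow(win), ci + rad)
    cc <- max(1L, cj - rad):min(ncol(win), cj + rad)
    sum(comp[rr, cc])
  }, numeric(1))
}

# full LCFD map by per-pixel flood fill and an lm() log-log fit
oracle_lcfd_map <- function(g, scales = default_scales()) {
  out <- matrix(NA_real_, nrow(g), ncol(g))
  lx <- log(scales)
  for (r in seq_len(nrow(g))) for (c in seq_len(ncol(g))) {
    if (!g[r, c]) next
    m <- oracle_masses(g, r, c, scales)
    out[r, c] <- unname(stats::coef(stats::lm(log(m) ~ lx))[2])
  }
  out
}

# connected-component count by iterative label propagation (any grid)
oracle_label <- function(g, connectivity = 8) {
  nr <- nrow(g); nc <- ncol(g)
  lab <- matrix(0L, nr, nc)
  lab[g] <- which(g)
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  }
  repeat {
    new <- lab
    for (o in offs) {
      pad <- matrix(Inf, nr + 2, nc + 2)
      pad[2:(nr + 1), 2:(nc + 1)] <- ifelse(g, lab, Inf)
      nb <- pad[2:(nr + 1) + o[1], 2:(nc + 1) + o[2]]
      new <- ifelse(g & is.finite(nb) & nb < new, nb, new)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# canonical relabeling in raster (row-major) first-occurrence order, so two
# labelings of the same partition compare equal
canonical_labels <- function(lab) {
  v <- as.vector(t(lab))
  ids <- unique(v[v > 0])
  v2 <- v
  v2[v > 0] <- match(v[v > 0], ids)
  out <- matrix(v2, nrow(lab), byrow = TRUE)
  storage.mode(out) <- "integer"
  out
}

random_landscape <- function(nr, nc, p = 0.5, seed = 1, cell_size = 30) {
  set.seed(seed)
  binary_landscape(matrix(runif(nr * nc) < p, nr, nc), cell_size)
}

# single-break fixture for method agreement: dense uniform body below the
# break, sparser uniform tail above it (a density step at the break)
single_break_values <- function(n, seed, b = 1.5, p = 0.65, lo = 1, hi = 2) {
  set.seed(seed)
  below <- runif(n) < p
  ifelse(below, runif(n, lo, b), runif(n, b, hi))
}

# k-component Gaussian mixture with known means
gaussian_mixture <- function(n, means, sd = 0.03, seed = 1) {
  set.seed(seed)
  comp <- sample(seq_along(means), n, replace = TRUE)
  rnorm(n, means[comp], sd)
}
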