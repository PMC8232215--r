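test_that("the default scale schedule is the published box-side list", {
  expect_identical(default_scales(), c(3L, 7L, 11L, 15L, 19L, 23L, 27L, 31L))
  expect_error(lcfd_map(make_filled(63), scales = c(3, 4, 5)), "odd")
  expect_error(lcfd_map(make_filled(63), scales = c(7, 3)), "increasing")
})

test_that("the locally connected set excludes other clusters in the window", {
  filled <- make_filled(63)
  ls <- local_connected_set(filled, c(32, 32))
  expect_true(all(ls$window))
  expect_equal(dim(ls$window), c(31, 31))
  # two blobs separated inside a 7x7 window: only the center's blob counts
  g <- matrix(FALSE, 7, 7)
  g[3:4, 2:3] <- TRUE        # center blob (contains 4,3... center at (4,3))
  g[6:7, 6:7] <- TRUE        # far blob, not 8-connected to the first
  bl <- binary_landscape(g)
  ls2 <- local_connected_set(bl, c(4, 3), max_box = 7)
  expect_equal(sum(ls2$window), 4)
  expect_false(ls2$window[6, 6])
  # isolated center
  iso <- matrix(FALSE, 9, 9); iso[5, 5] <- TRUE
  ls3 <- local_connected_set(binary_landscape(iso), c(5, 5), max_box = 7)
  expect_equal(sum(ls3$window), 1)
  expect_error(local_connected_set(bl, c(1, 1)), "foreground")
})

test_that("mass profiles follow area, length and point geometry", {
  filled <- make_filled(63)
  mp <- mass_profile(local_connected_set(filled, c(32, 32)))
  expect_equal(unname(mp), default_scales()^2)
  line <- make_line(63)
  mpl <- mass_profile(local_connected_set(line, c(32, 32)))
  expect_equal(unname(mpl), as.numeric(default_scales()))
  iso <- make_isolated_points(c(256, 256), 1, 40, seed = 1)
  ctr <- which(iso$grid, arr.ind = TRUE)[1, ]
  mpi <- mass_profile(local_connected_set(iso, ctr))
  expect_equal(unname(mpi), rep(1, 8))
  small <- local_connected_set(filled, c(32, 32), max_box = 7)
  expect_error(mass_profile(small, scales = default_scales()), "exceeds")
})

test_that("the fitted dimension hits the analytic anchors exactly", {
  expect_equal(fit_dimension(default_scales()^2), 2)
  expect_equal(fit_dimension(as.numeric(default_scales())), 1)
  expect_equal(fit_dimension(rep(1, 8)), 0)
  expect_error(fit_dimension(c(1, 2)), "same length")
})

test_that("the LCFD map covers the foreground and matches fixtures", {
  filled <- make_filled(63)
  m <- lcfd_map(filled)
  expect_identical(!is.na(m$values), filled$grid)
  interior <- m$values[16:48, 16:48]
  expect_equal(max(abs(interior - 2)), 0, tolerance = 1e-12)
  iso <- make_isolated_points(c(128, 128), 4, 40, seed = 2)
  mi <- lcfd_map(iso)
  expect_equal(unique(lcfd_values(mi)), 0)
  expect_warning(lcfd_map(binary_landscape(matrix(FALSE, 40, 40))), "empty")
})

test_that("mass monotonicity and bounds hold across random masks", {
  for (seed in 1:5) {
    bl <- random_landscape(40, 40, 0.5, seed = seed)
    pts <- which(bl$grid, arr.ind = TRUE)
    set.seed(seed)
    pts <- pts[sample(nrow(pts), 25), , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
      mp <- mass_profile(local_connected_set(bl, pts[i, ]))
      expect_true(all(diff(mp) >= 0))
      expect_true(all(mp >= 1 & mp <= default_scales()^2))
    }
  }
})

test_that("the map equals the per-pixel flood-fill oracle", {
  for (seed in 1:3) {
    bl <- random_landscape(20, 20, 0.5, seed = seed)
    mine <- lcfd_map(bl)$values
    oracle <- oracle_lcfd_map(bl$grid)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("translation moves the map rigidly with the pattern", {
  g <- matrix(FALSE, 90, 90)
  g[30:40, 30:42] <- TRUE
  g[33, 35] <- FALSE  # give it some structure
  shifted <- matrix(FALSE, 90, 90)
  shifted[35:45, 34:46] <- g[30:40, 30:42]
  m1 <- lcfd_map(binary_landscape(g))$values[30:40, 30:42]
  m2 <- lcfd_map(binary_landscape(shifted))$values[35:45, 34:46]
  expect_equal(m1, m2)
})

test_that("skip_margin drops border pixels instead of clipping boxes", {
  filled <- make_filled(63)
  m <- lcfd_map(filled, skip_margin = TRUE)
  expect_true(all(is.na(m$values[1:15, ])))
  inner <- m$values[16:48, 16:48]
  expect_true(all(!is.na(inner)))
  expect_equal(max(abs(inner - 2)), 0, tolerance = 1e-12)
})

test_that("distributions conserve counts and expose order statistics", {
  m <- lcfd_map(make_filled(63), skip_margin = TRUE)  # all values exactly 2
  d <- lcfd_distribution(m)
  expect_equal(d$summary$median, 2)
  expect_equal(sum(d$histogram$count), sum(!is.na(m$values)))
  # mixed fixture: a long line and a solid block give modes near 1 and 2
  g <- matrix(FALSE, 120, 120)
  g[20, 5:115] <- TRUE
  g[60:110, 30:90] <- TRUE
  md <- lcfd_map(binary_landscape(g))
  v <- lcfd_values(md)
  expect_gt(sum(abs(v - 1) < 0.15), 50)
  expect_gt(sum(abs(v - 2) < 0.15), 500)
  expect_lt(sum(v > 1.3 & v < 1.6), sum(abs(v - 2) < 0.15))
})

test_that("LCFD text and raster outputs round-trip", {
  g <- matrix(FALSE, 40, 40)
  g[c(100, 200, 300)] <- TRUE
  m <- lcfd_map(binary_landscape(g))
  txt <- withr::local_tempfile(fileext = ".tsv")
  write_lcfd_text(m, txt)
  tb <- read_lcfd_text(txt)
  expect_equal(nrow(tb), 3)
  rebuilt <- matrix(NA_real_, 40, 40)
  rebuilt[cbind(tb$Y, tb$X)] <- tb$LCFD
  expect_equal(rebuilt, m$values)
  asc <- withr::local_tempfile(fileext = ".asc")
  write_lcfd_raster(m, asc)
  back <- read_lcfd_raster(asc)
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_equal(sum(is.na(back$values)), sum(!g))
})
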