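make_pair <- function() {
  a <- categorical_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE),
                          legend = c(`1` = "forest", `2` = "water",
                                     `3` = "agriculture"))
  b <- categorical_raster(matrix(c(1L, 3L, 2L, 3L), 2, 2, byrow = TRUE),
                          legend = c(`1` = "forest", `2` = "water",
                                     `3` = "agriculture"))
  list(a = a, b = b)
}

test_that("cross-tabulation counts every ordered class pair", {
  p <- make_pair()
  tab <- crosstab_rasters(p$a, p$b)
  expect_equal(sum(tab$n), 4)
  lookup <- function(f, t) tab$n[tab$from_class == f & tab$to_class == t]
  expect_equal(lookup(1, 1), 1)
  expect_equal(lookup(1, 3), 1)
  expect_equal(lookup(2, 2), 1)
  expect_equal(lookup(2, 3), 1)
  self <- crosstab_rasters(p$a, p$a)
  expect_true(all(self$from_class == self$to_class))
  bad <- categorical_raster(matrix(1L, 3, 3))
  expect_error(crosstab_rasters(p$a, bad), "shapes")
})

test_that("cross-tabulation marginals equal per-raster histograms", {
  set.seed(42)
  for (i in 1:5) {
    a <- categorical_raster(matrix(sample(1:4, 100, TRUE), 10, 10))
    b <- categorical_raster(matrix(sample(1:4, 100, TRUE), 10, 10))
    tab <- crosstab_rasters(a, b)
    from_marg <- tapply(tab$n, tab$from_class, sum)
    expect_equal(as.vector(from_marg),
                 as.vector(table(as.vector(a$grid))))
    to_marg <- tapply(tab$n, tab$to_class, sum)
    expect_equal(as.vector(to_marg), as.vector(table(as.vector(b$grid))))
  }
})

test_that("transition masks match cross-tabulation entries and partition", {
  p <- make_pair()
  m <- transition_mask(p$a, p$b, 1, 3)
  expect_equal(fg_count(m), 1)
  expect_true(m$grid[1, 2])
  # class in the legend but absent from the raster: an empty mask, not an error
  empty <- transition_mask(p$a, p$b, 3, 1)
  expect_equal(fg_count(empty), 0)
  expect_error(transition_mask(p$a, p$b, 9, 1), "unknown")
  # the (from, to) masks partition the grid
  total <- Reduce(`+`, lapply(1:3, function(f) {
    Reduce(`+`, lapply(1:3, function(t) {
      transition_mask(p$a, p$b, f, t)$grid * 1L
    }))
  }))
  expect_true(all(total == 1))
  # consistency on random rasters: mask count equals the crosstab entry
  set.seed(7)
  a <- categorical_raster(matrix(sample(1:3, 64, TRUE), 8, 8))
  b <- categorical_raster(matrix(sample(1:3, 64, TRUE), 8, 8))
  tab <- crosstab_rasters(a, b)
  for (r in seq_len(nrow(tab))) {
    expect_equal(fg_count(transition_mask(a, b, tab$from_class[r],
                                          tab$to_class[r])), tab$n[r])
  }
})

test_that("accumulation unions masks monotonically and is idempotent", {
  g <- matrix(FALSE, 6, 6)
  a <- binary_landscape({x <- g; x[1:2, 1:2] <- TRUE; x})
  b <- binary_landscape({x <- g; x[5:6, 5:6] <- TRUE; x})
  sub <- binary_landscape({x <- g; x[1, 1] <- TRUE; x})
  acc <- accumulate_masks(list(a, b))
  expect_equal(fg_count(acc$landscapes[[2]]), fg_count(a) + fg_count(b))
  acc2 <- accumulate_masks(list(a, sub))
  expect_identical(acc2$landscapes[[2]]$grid, a$grid)
  set.seed(13)
  masks <- lapply(1:3, function(i) random_landscape(8, 8, 0.3, seed = i))
  acc3 <- accumulate_masks(masks)
  counts <- vapply(acc3$landscapes, fg_count, numeric(1))
  expect_true(all(diff(counts) >= 0))
  union_direct <- masks[[1]]$grid | masks[[2]]$grid | masks[[3]]$grid
  expect_identical(acc3$landscapes[[3]]$grid, union_direct)
  again <- accumulate_masks(acc3)
  for (i in 1:3) {
    expect_identical(again$landscapes[[i]]$grid, acc3$landscapes[[i]]$grid)
  }
})

test_that("mask files round-trip with the historical 0/1 polarity", {
  bl <- random_landscape(9, 7, 0.4, seed = 21)
  path <- withr::local_tempfile(fileext = ".asc")
  write_mask(bl, path)  # legacy polarity: 0 = deforested
  body <- readLines(path)[-(1:6)]
  zeros <- sum(unlist(strsplit(paste(body, collapse = " "), " ")) == "0")
  expect_equal(zeros, fg_count(bl))
  back <- read_mask(path)
  expect_identical(back$grid, bl$grid)
  expect_equal(back$cell_size, bl$cell_size)
  flipped <- read_mask(path, polarity = "standard")
  expect_identical(flipped$grid, !bl$grid)
})

test_that("categorical rasters round-trip through ASCII grids", {
  cr <- categorical_raster(matrix(sample(1:5, 48, TRUE), 6, 8),
                           cell_size = 30)
  path <- withr::local_tempfile(fileext = ".asc")
  write_categorical(cr, path)
  back <- read_categorical(path)
  expect_identical(back$grid, cr$grid)
})
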