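test_that("patch labeling honors the chosen connectivity", {
  diag2 <- binary_landscape(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_equal(label_patches(diag2, connectivity = 8)$np, 1)
  expect_equal(label_patches(diag2, connectivity = 4)$np, 2)
  expect_equal(label_patches(binary_landscape(matrix(FALSE, 3, 3)))$np, 0)
  expect_equal(label_patches(binary_landscape(matrix(TRUE, 3, 3)))$np, 1)
  expect_error(label_patches(diag2, connectivity = 6), "4 or 8")
})

test_that("patch labeling agrees with label propagation on random grids", {
  for (seed in 1:25) {
    bl <- random_landscape(8, 8, p = 0.5, seed = seed)
    for (conn in c(4, 8)) {
      mine <- canonical_labels(label_patches(bl, conn)$labels)
      theirs <- canonical_labels(oracle_label(bl$grid, conn))
      expect_identical(mine, theirs)
    }
  }
})

test_that("areas, ratios and densities follow their definitions", {
  one <- binary_landscape(matrix(c(TRUE, rep(FALSE, 99)), 10, 10),
                          cell_size = 30)
  expect_equal(deforested_area(one), 0.09)
  expect_equal(round(da_ratio(103006, 18503), 2), 5.57)
  expect_equal(da_ratio(5, 5), 1)
  expect_true(is.na(da_ratio(5, 0)))
  expect_equal(patch_density(50, 1000), 5)
  expect_error(patch_density(50, 0), "positive")
})

test_that("edge density counts boundary segments per hectare", {
  g <- matrix(FALSE, 10, 10)
  g[5, 5] <- TRUE
  bl <- binary_landscape(g, cell_size = 30)
  expect_equal(edge_density(bl, landscape_area_ha = 1), 120)  # 4 x 30 m / ha
  empty <- binary_landscape(matrix(FALSE, 5, 5))
  expect_equal(edge_density(empty, landscape_area_ha = 1), 0)
  corner <- binary_landscape({m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m},
                             cell_size = 30)
  expect_equal(edge_density(corner, 1, count_border = FALSE), 60)
  expect_equal(edge_density(corner, 1, count_border = TRUE), 120)
})

test_that("nearest-neighbor distance uses cell-center Euclidean geometry", {
  g <- matrix(FALSE, 12, 20)
  g[3, 4] <- TRUE; g[3, 14] <- TRUE      # 10 columns apart
  expect_equal(enn_mn(binary_landscape(g, 30)), 300)
  g2 <- matrix(FALSE, 12, 12)
  g2[2, 2] <- TRUE; g2[6, 5] <- TRUE     # 3 right, 4 down: distance 5
  expect_equal(enn_mn(binary_landscape(g2, 30)), 150)
  single <- binary_landscape({m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m})
  expect_true(is.na(enn_mn(single)))
  # symmetric pair: both patches see the same nearest distance
  g3 <- matrix(FALSE, 8, 8)
  g3[4, 2] <- TRUE; g3[4, 7] <- TRUE
  lp <- label_patches(binary_landscape(g3, 30))
  expect_equal(enn_mn(lp), 5 * 30)
})

test_that("clumpiness spans its range with the expected anchors", {
  expect_equal(clumpy(make_checkerboard(64)), -1)
  for (seed in 1:5) {
    expect_lt(abs(clumpy(random_landscape(256, 256, 0.5, seed))), 0.05)
  }
  # solid block filling half the grid: positive, toward 1 as the grid grows
  half_block <- function(n) {
    g <- matrix(FALSE, n, n); g[, seq_len(n / 2)] <- TRUE
    binary_landscape(g)
  }
  c8 <- clumpy(half_block(8)); c64 <- clumpy(half_block(64))
  expect_gt(c8, 0)
  expect_gt(c64, c8)
  expect_lte(c64, 1)
  expect_true(is.na(clumpy(binary_landscape(matrix(TRUE, 4, 4)))))
  # bounds on random landscapes of varying occupancy
  for (seed in 1:40) {
    set.seed(seed)
    bl <- random_landscape(12, 12, p = runif(1, 0.05, 0.95), seed = seed)
    cl <- clumpy(bl)
    if (!is.na(cl)) expect_true(cl >= -1 && cl <= 1)
  }
})

test_that("adding foreground grows the deforested area, never shrinks it", {
  bl <- random_landscape(20, 20, 0.3, seed = 9)
  area_ha <- landscape_area(bl)
  grown <- bl
  set.seed(1)
  add <- sample(which(!bl$grid), 30)
  grown$grid[add] <- TRUE
  expect_gte(deforested_area(grown), deforested_area(bl))
  # an isolated new interior cell adds its full perimeter to the edge total
  iso <- bl
  candidates <- which(!dilate8_r(bl$grid), arr.ind = TRUE)
  candidates <- candidates[candidates[, 1] %in% 2:19 &
                             candidates[, 2] %in% 2:19, , drop = FALSE]
  iso$grid[candidates[1, 1], candidates[1, 2]] <- TRUE
  expect_equal(edge_density(iso, area_ha) - edge_density(bl, area_ha),
               4 * bl$cell_size / area_ha)
})

test_that("metric trends over simulated growth mirror consolidation", {
  seeds <- 1:12
  steps <- 5
  clumpy_mat <- matrix(NA_real_, length(seeds), steps)
  enn_mat <- matrix(NA_real_, length(seeds), steps)
  for (i in seq_along(seeds)) {
    gs <- simulate_growth(shape = 96, n_nuclei = 10, contagion_prob = 0.3,
                          steps = steps, seed = seeds[i])
    tb <- metrics_series(gs)
    expect_true(all(diff(tb$DA) >= 0))          # cumulative area growth
    clumpy_mat[i, ] <- tb$CLUMPY
    enn_mat[i, ] <- tb$ENN_MN
  }
  mean_clumpy <- colMeans(clumpy_mat)
  expect_gt(stats::cor(seq_len(steps), mean_clumpy, method = "spearman"), 0.8)
  # nearest-neighbor distance dips below its initial level as nuclei infill
  mean_enn <- colMeans(enn_mat, na.rm = TRUE)
  expect_lt(min(mean_enn), mean_enn[1])
})

test_that("the metrics table carries the period labels and ratio column", {
  gs <- simulate_growth(shape = 64, n_nuclei = 6, steps = 3, seed = 4)
  tb <- metrics_series(gs)
  expect_named(tb, c("CP", "DA", "Ratio", "NP", "PD", "ED", "ENN_MN",
                     "CLUMPY", "landscape_area"))
  expect_true(is.na(tb$Ratio[1]))
  expect_equal(tb$Ratio[2], tb$DA[2] / tb$DA[1])
})
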