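test_that("the exceedance curve counts areas above each level", {
  ca <- ca_curve(c(1, 2, 3), n_bins = 17)
  expect_equal(ca$A[which(ca$C == 2)], 2)
  expect_equal(ca$A[1], 3)  # at the minimum level, everything exceeds
  set.seed(5)
  for (i in 1:5) {
    ca2 <- ca_curve(rnorm(500), n_bins = 64)
    expect_true(all(diff(ca2$A) <= 0))
  }
  expect_warning(ca_curve(rep(1, 30)), "degenerate")
  expect_error(ca_curve(numeric(0)), "non-empty")
})

test_that("a planted two-regime sample yields a piecewise log-log line", {
  # wide support keeps the upper regime an uncontaminated power law; the
  # fit ignores levels with fewer than 50 exceeding values (extreme tail)
  v <- simulate_two_regime(50000, break_point = 1.4, beta1 = 1, beta2 = 6,
                           lo = 0.5, hi = 8, seed = 8)
  ca <- ca_curve(v, n_bins = 128, spacing = "log")
  keep <- which(ca$A >= 50)
  x <- log10(ca$C[keep]); y <- ca$log10_A[keep]
  m <- length(keep)
  # two-segment least-squares oracle over candidate breaks
  sse <- vapply(8:(m - 8), function(j) {
    f1 <- stats::lm(y[1:j] ~ x[1:j])
    f2 <- stats::lm(y[j:m] ~ x[j:m])
    sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
  }, numeric(1))
  j <- (8:(m - 8))[which.min(sse)]
  expect_lt(abs(ca$C[keep][j] - 1.4), 0.05)
  # and the fitted slopes recover the planted exponents
  b1 <- unname(stats::coef(stats::lm(y[1:j] ~ x[1:j]))[2])
  b2 <- unname(stats::coef(stats::lm(y[j:m] ~ x[j:m]))[2])
  expect_lt(abs(b1 - (-1)), 0.2)
  expect_lt(abs(b2 - (-6)), 1)
})

test_that("the Mexican hat transform acts as a second-derivative operator", {
  x <- seq(-3, 3, length.out = 256)
  quad <- 0.5 * x^2
  f <- cwt_mexican_hat(quad)
  for (k in c(2, 5, 8)) {
    # stay clear of the reflection pads: the kernel support is 5 scales wide
    margin <- ceiling(5 * f$scales[k]) + 1
    row <- abs(f$W[k, margin:(256 - margin)])
    expect_lt(stats::sd(row) / mean(row), 0.02)  # constant curvature response
  }
  # two vanishing moments: a constant offset changes nothing
  f2 <- cwt_mexican_hat(quad + 11.3)
  expect_equal(f$W, f2$W, tolerance = 1e-10)
  # mirror symmetry
  sig <- sin(seq(0, 6, length.out = 256)) + 0.1 * seq(0, 1, length.out = 256)
  fm <- cwt_mexican_hat(rev(sig))
  ff <- cwt_mexican_hat(sig)
  expect_equal(fm$W, ff$W[, 256:1], tolerance = 1e-8)
  expect_error(cwt_mexican_hat(rnorm(32)), "at least 64")
  expect_error(cwt_mexican_hat(rnorm(128), scales = c(100, 120)), "support")
})

test_that("maxima lines converge to planted slope breaks", {
  n <- 256
  # noiseless piecewise-linear signal with one slope break at sample 150
  sig <- c(seq(0, 1.49, length.out = 150), 1.5 - 4 * seq(1, 106) / 106)
  f <- cwt_mexican_hat(sig)
  ln <- wtmm_maxima_lines(f)
  expect_gt(nrow(ln), 0)
  expect_lt(abs(ln$u[1] - 150), 4)
  # two well-separated breaks: two persistent lines at the two positions
  sig2 <- cumsum(c(rep(0.01, 80), rep(0.05, 90), rep(0.005, 86)))
  ln2 <- wtmm_maxima_lines(cwt_mexican_hat(sig2))
  expect_gte(nrow(ln2), 2)
  expect_lt(min(abs(ln2$u - 80)), 5)
  expect_lt(min(abs(ln2$u - 170)), 5)
})

test_that("white noise fragments into many short maxima lines", {
  for (seed in 1:10) {
    set.seed(seed)
    ln <- wtmm_maxima_lines(cwt_mexican_hat(rnorm(256)), min_span = 1)
    expect_gt(nrow(ln), 20)          # many lines...
    expect_lt(median(ln$span), 8)    # ...mostly short-lived across scales
  }
})

test_that("threshold detection recovers a planted break and appends 1.0", {
  v <- simulate_two_regime(20000, break_point = 1.5, seed = 42)
  ts <- detect_thresholds_ca(v, n_bins = 256)
  expect_s3_class(ts, "threshold_set")
  expect_true(1.0 %in% ts$value)
  top <- ts$value[ts$method == "ca_wavelet" & ts$rank == 1]
  step <- diff(range(v)) / 255
  expect_lte(abs(top - 1.5), 2 * step)
  # constant input degenerates to the geometric cut alone
  w <- testthat::capture_warnings(ts0 <- detect_thresholds_ca(rep(1.3, 100)))
  expect_true(any(grepl("degenerate", w)))
  expect_identical(ts0$method, "geometric")
})

test_that("a single-regime power law yields no cut besides the geometric one", {
  # noise-free quantile sample of one power law: linear in log-log by
  # construction, so no curvature anomaly exists
  n <- 20000
  u <- (seq_len(n) - 0.5) / n
  beta <- 2
  lo <- 0.5; hi <- 2
  s_hi <- (hi / lo)^(-beta)
  t <- 1 - u * (1 - s_hi)
  v <- lo * t^(-1 / beta)
  ts <- suppressWarnings(detect_thresholds_ca(v, abscissa = "logC"))
  expect_identical(ts$value[ts$method != "geometric"], numeric(0))
  expect_true(1.0 %in% ts$value)
})

test_that("shifting the input leaves maxima positions unchanged", {
  v <- simulate_two_regime(20000, break_point = 1.45, seed = 9)
  ca <- ca_curve(v)
  f1 <- wtmm_maxima_lines(cwt_mexican_hat(ca$log10_A))
  f2 <- wtmm_maxima_lines(cwt_mexican_hat(ca$log10_A + 5))
  expect_equal(f1$u, f2$u)
})

test_that("threshold sets stay sorted, finite and deduplicated", {
  ts <- threshold_set(c(1.6, 0.4), method = "manual", add_geometric = TRUE)
  expect_equal(ts$value, c(0.4, 1, 1.6))
  expect_error(threshold_set(c(1, NA)), "finite")
  expect_warning(threshold_set(c(1, 1), add_geometric = FALSE), "duplicate")
  expect_equal(threshold_cuts(c(2, 1)), c(1, 2))
})
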