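#' Concentration-area curve
#'
#' For a set of concentration values (here, per-pixel LCFDs) the CA method
#' relates a concentration level C to the area A(C) occupied by values of at
#' least C: under a fractal model `A(C) ~ C^(-beta)`, and slope changes of
#' the log-log curve separate populations.
#'
#' @param values Numeric vector of concentrations (LCFD values).
#' @param n_bins Number of concentration levels spanning the data (at least
#'   16; default 256).
#' @param spacing `"linear"` (default) for a uniform level grid, `"log"`
#'   for log-spaced levels (requires positive values).
#' @return A tibble of class `ca_curve` with columns `C` (level), `A`
#'   (count of values >= C) and `log10_A`; attribute `degenerate` flags a
#'   constant input.
#' @examples
#' ca <- ca_curve(c(1, 2, 3), n_bins = 17)
#' ca$A[ca$C == 2]  # A(2) = 2
#' @export
ca_curve <- function(values, n_bins = 256, spacing = c("linear", "log")) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  spacing <- match.arg(spacing)
  if (!length(values)) abort("`values` must be non-empty")
  if (n_bins < 16) abort("`n_bins` must be at least 16")
  degenerate <- min(values) == max(values)
  if (degenerate) {
    warn("constant values: degenerate concentration-area curve")
    C <- rep(values[1], 2)
    A <- rep(length(values), 2)
  } else {
    C <- if (spacing == "linear") {
      seq(min(values), max(values), length.out = n_bins)
    } else {
      if (min(values) <= 0) abort("log spacing requires positive values")
      exp(seq(log(min(values)), log(max(values)), length.out = n_bins))
    }
    sv <- sort(values)
    # A(C) = #{v >= C}; findInterval counts sv < C via left-open intervals
    A <- length(sv) - findInterval(C, sv, left.open = TRUE)
  }
  out <- tibble(C = C, A = as.integer(A), log10_A = log10(A))
  attr(out, "degenerate") <- degenerate
  class(out) <- c("ca_curve", class(out))
  out
}

#' Simulate values with a two-regime concentration-area structure
#'
#' Draws values whose exceedance curve follows a power law
#' `A(C) ~ C^(-beta1)` up to a planted break and a second, steeper regime
#' `C^(-beta2)` beyond it, by inverse-transform sampling of the piecewise
#' survival function truncated to `[lo, hi]`. This is the canonical fixture
#' for validating slope-change (threshold) detection: the break position is
#' known exactly.
#'
#' @param n Number of values.
#' @param break_point Regime-change concentration, in `(lo, hi)`.
#' @param beta1,beta2 Exponents below and above the break (`beta2 > beta1`
#'   gives a concave kink in the log-exceedance curve).
#' @param lo,hi Support of the values.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_two_regime <- function(n, break_point = 1.5, beta1 = 1, beta2 = 6,
                                lo = 0.5, hi = 2, seed = 1) {
  if (break_point <= lo || break_point >= hi) {
    abort("`break_point` must lie inside (lo, hi)")
  }
  if (beta1 <= 0 || beta2 <= 0) abort("exponents must be positive")
  s_break <- (break_point / lo)^(-beta1)
  s_hi <- s_break * (hi / break_point)^(-beta2)
  with_seed_(seed, {
    t <- 1 - stats::runif(n) * (1 - s_hi)  # survival levels in (s_hi, 1]
    ifelse(t >= s_break,
           lo * t^(-1 / beta1),
           break_point * (t / s_break)^(-1 / beta2))
  })
}

mexican_hat <- function(x) (1 - x^2) * exp(-x^2 / 2)

#' Continuous wavelet transform with the Mexican hat wavelet
#'
#' Convolves a uniformly sampled signal with scaled, `1/sqrt(s)`-normalized
#' Mexican hat wavelets. The Mexican hat (negative second derivative of a
#' Gaussian) has two vanishing moments, so the transform acts as a
#' multiscale second-derivative operator: its modulus is large where the
#' signal's curvature changes. Edges are handled by reflective padding, and
#' the discretized kernel is centered to exact zero mean so that adding a
#' constant to the signal leaves the field unchanged.
#'
#' @param signal Numeric vector, at least 64 samples.
#' @param scales Positive increasing scales in sample units (default 16
#'   log-spaced scales from 2 to `length(signal)/4`).
#' @return A list of class `wavelet_field`: `W` (matrix, scales in rows,
#'   translations in columns), `scales`, `n`, `wavelet = "mexican_hat"`.
#' @export
cwt_mexican_hat <- function(signal, scales = NULL) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 64) abort("`signal` must have at least 64 samples")
  if (is.null(scales)) {
    scales <- exp(seq(log(2), log(n / 4), length.out = 16))
  }
  if (any(scales <= 0) || any(diff(scales) <= 0)) {
    abort("`scales` must be positive and increasing")
  }
  if (max(scales) > n / 2) {
    abort("signal shorter than the largest wavelet support")
  }
  half_max <- min(ceiling(5 * max(scales)), n - 1)
  padded <- c(rev(signal[seq_len(half_max) + 1]), signal,
              signal[n - seq_len(half_max)])
  W <- matrix(NA_real_, length(scales), n)
  for (k in seq_along(scales)) {
    s <- scales[k]
    half <- min(ceiling(5 * s), half_max)
    t <- (-half):half
    psi <- mexican_hat(t / s) / sqrt(s)
    psi <- psi - mean(psi)  # exact discrete zero mean
    conv <- stats::filter(padded, rev(psi), method = "convolution", sides = 2)
    W[k, ] <- conv[half_max + seq_len(n)]
  }
  structure(list(W = W, scales = scales, n = n, wavelet = "mexican_hat"),
            class = "wavelet_field")
}

#' @export
print.wavelet_field <- function(x, ...) {
  cat(sprintf("<wavelet_field> %s, %d scales [%.2f, %.2f] x %d samples\n",
              x$wavelet, length(x$scales), min(x$scales), max(x$scales), x$n))
  invisible(x)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Wavelet-transform modulus-maxima lines
#'
#' Local maxima of `|Wf(u, s)|` at each scale, chained across adjacent
#' scales (coarse to fine) by nearest-position matching within a tolerance
#' of `1 + s/2` samples. Persistent lines converge toward singular points of
#' the signal; lines spanning fewer scales than `min_span` or terminating in
#' the edge-pad region are discarded.
#'
#' @param field A [cwt_mexican_hat()] result.
#' @param min_span Minimum number of scales a line must span (default half
#'   the scales).
#' @param edge_exclude Samples at each end within which line endpoints are
#'   considered border artifacts (default the smallest scale's support).
#' @return A tibble with one row per retained line: `line` (id), `u` (finest
#'   -scale position, sample index), `span` (scales covered), `strength`
#'   (summed modulus), and a list column `path` of per-scale `(scale, u,
#'   modulus)` tibbles ordered by decreasing scale.
#' @export
wtmm_maxima_lines <- function(field, min_span = NULL, edge_exclude = NULL) {
  stopifnot(inherits(field, "wavelet_field"))
  ns <- length(field$scales)
  if (ns < 4) abort("at least 4 scales are required")
  if (is.null(min_span)) min_span <- ceiling(ns / 2)
  if (is.null(edge_exclude)) edge_exclude <- ceiling(5 * min(field$scales))
  mod <- abs(field$W)
  maxima <- lapply(seq_len(ns), function(k) local_maxima(mod[k, ]))
  # chain from the coarsest scale down
  lines <- list()
  active <- list()
  for (k in rev(seq_len(ns))) {
    pos <- maxima[[k]]
    claimed <- rep(FALSE, length(pos))
    tol <- 1 + field$scales[k] / 2
    new_active <- list()
    for (ln in active) {
      if (length(pos)) {
        d <- abs(pos - ln$u[length(ln$u)])
        j <- which.min(d)
        if (d[j] <= tol && !claimed[j]) {
          claimed[j] <- TRUE
          ln$u <- c(ln$u, pos[j])
          ln$scale <- c(ln$scale, field$scales[k])
          ln$modulus <- c(ln$modulus, mod[k, pos[j]])
          new_active[[length(new_active) + 1]] <- ln
          next
        }
      }
      lines[[length(lines) + 1]] <- ln  # line terminated above this scale
    }
    for (j in which(!claimed)) {
      new_active[[length(new_active) + 1]] <- list(
        u = pos[j], scale = field$scales[k], modulus = mod[k, pos[j]]
      )
    }
    active <- new_active
  }
  lines <- c(lines, active)
  if (!length(lines)) {
    return(tibble(line = integer(0), u = integer(0), span = integer(0),
                  strength = numeric(0), path = list()))
  }
  rows <- purrr::map(lines, function(ln) {
    tibble(
      u = ln$u[length(ln$u)],
      span = length(ln$u),
      strength = sum(ln$modulus),
      fine_modulus = ln$modulus[length(ln$modulus)],
      finest_scale = ln$scale[length(ln$scale)],
      path = list(tibble(scale = ln$scale, u = ln$u, modulus = ln$modulus))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(
    out,
    .data$span >= min_span,
    .data$u > edge_exclude, .data$u <= field$n - edge_exclude
  )
  # persistence first; among equally persistent lines, a genuine singularity
  # keeps its modulus at fine scales while smooth-background curvature decays
  out <- dplyr::arrange(out, dplyr::desc(.data$span),
                        dplyr::desc(.data$fine_modulus))
  dplyr::mutate(out, line = dplyr::row_number(), .before = 1)
}

#' Detect LCFD thresholds by the CA-wavelet method
#'
#' Builds the concentration-area curve of the LCFD values, takes `log10 A`
#' sampled on the uniform concentration grid as a 1-D signal, and locates
#' its curvature anomalies (slope-change points) with the wavelet-transform
#' modulus-maxima method under a Mexican hat wavelet. The finest-scale
#' positions of persistent maxima lines, ranked by scale-span then by summed
#' modulus, are mapped back to LCFD units. The fixed geometric threshold 1.0
#' (the dimension separating point-like from line-like sets) is always
#' appended.
#'
#' @param values LCFD values (vector, [lcfd_map()] or [lcfd_distribution()]).
#' @param n_bins Concentration grid size (default 256).
#' @param scales CWT scales (default as in [cwt_mexican_hat()]).
#' @param min_span,edge_exclude Line filtering, see [wtmm_maxima_lines()].
#' @param abscissa `"C"` (default) analyses `log10 A` against C in LCFD
#'   units; `"logC"` against `log10 C` (requires positive values).
#' @param max_thresholds Keep at most this many detected cuts (default 4).
#' @param min_modulus_frac Significance floor: lines whose peak modulus is
#'   below this fraction of the signal's total variation are treated as
#'   sampling noise and dropped (default 0.01).
#' @param min_tail_fraction A candidate cut must leave at least this
#'   fraction of the values on each side (default 0.01): a "threshold" with
#'   almost no population above or below it separates nothing and is an
#'   artifact of the exceedance curve's end plunge.
#' @return A [threshold_set()] tibble: detected cuts (method
#'   `"ca_wavelet"`, ranked) plus the geometric cut at 1.0.
#' @export
detect_thresholds_ca <- function(values, n_bins = 256, scales = NULL,
                                 min_span = NULL, edge_exclude = NULL,
                                 abscissa = c("C", "logC"),
                                 max_thresholds = 4,
                                 min_modulus_frac = 0.01,
                                 min_tail_fraction = 0.01) {
  if (inherits(values, "lcfd_map")) values <- lcfd_values(values)
  if (inherits(values, "lcfd_distribution")) values <- values$values
  abscissa <- match.arg(abscissa)
  ca <- ca_curve(values, n_bins,
                 spacing = if (abscissa == "C") "linear" else "log")
  if (isTRUE(attr(ca, "degenerate"))) {
    warn("degenerate CA curve: only the geometric threshold is returned")
    return(threshold_set(numeric(0), method = "ca_wavelet",
                         add_geometric = TRUE))
  }
  field <- cwt_mexican_hat(ca$log10_A, scales)
  lines <- wtmm_maxima_lines(field, min_span, edge_exclude)
  if (nrow(lines)) {
    peak <- vapply(lines$path, function(p) max(p$modulus), numeric(1))
    floor_mod <- min_modulus_frac * diff(range(ca$log10_A))
    n_val <- ca$A[1]
    tail_ok <- ca$A[lines$u] >= min_tail_fraction * n_val &
      ca$A[lines$u] <= (1 - min_tail_fraction) * n_val
    lines <- lines[peak >= floor_mod & tail_ok, , drop = FALSE]
    if (nrow(lines)) lines$line <- seq_len(nrow(lines))  # re-rank survivors
  }
  if (!nrow(lines)) {
    warn("no persistent maxima line: only the geometric threshold is returned")
    return(threshold_set(numeric(0), method = "ca_wavelet",
                         add_geometric = TRUE, diagnostics = list(ca = ca)))
  }
  lines <- head(lines, max_thresholds)
  cuts <- ca$C[lines$u]
  threshold_set(
    cuts, method = "ca_wavelet", rank = lines$line,
    span = lines$span, strength = lines$strength,
    add_geometric = TRUE,
    diagnostics = list(ca = ca, lines = lines)
  )
}

#' Threshold set
#'
#' Ordered LCFD cut points with their provenance. The geometric cut at 1.0
#' (separating point-like from line-like local sets) can be appended to any
#' detected set.
#'
#' @param cuts Numeric cut points in LCFD units.
#' @param method Provenance tag: `"ca_wavelet"`, `"kmeans"`, `"geometric"`
#'   or `"manual"`.
#' @param rank Detection rank per cut (1 = strongest).
#' @param span,strength Optional per-cut diagnostics.
#' @param add_geometric Append the fixed geometric cut at 1.0 (deduplicated).
#' @param diagnostics Optional list attached as an attribute.
#' @return A tibble of class `threshold_set` with columns `value`, `method`,
#'   `rank`, `span`, `strength`, sorted by `value`.
#' @export
threshold_set <- function(cuts, method = "manual", rank = seq_along(cuts),
                          span = NA_real_, strength = NA_real_,
                          add_geometric = FALSE, diagnostics = NULL) {
  cuts <- as.numeric(cuts)
  if (anyNA(cuts) || any(!is.finite(cuts))) abort("cuts must be finite")
  out <- tibble(value = cuts, method = method,
                rank = if (length(cuts)) as.integer(rank) else integer(0),
                span = as.numeric(span), strength = as.numeric(strength))
  if (add_geometric && !any(abs(out$value - 1) < 1e-9)) {
    out <- dplyr::bind_rows(out, tibble(
      value = 1, method = "geometric", rank = NA_integer_,
      span = NA_real_, strength = NA_real_
    ))
  }
  out <- dplyr::arrange(out, .data$value)
  if (any(duplicated(out$value))) {
    out <- out[!duplicated(out$value), ]
    warn("duplicate cut values collapsed")
  }
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("threshold_set", class(out))
  out
}

#' Cut points of a threshold set
#' @param x A [threshold_set()] or numeric vector.
#' @return Sorted numeric cut points.
#' @export
threshold_cuts <- function(x) {
  if (inherits(x, "threshold_set")) sort(x$value) else sort(as.numeric(x))
}
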