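#' One-dimensional k-means with deterministic quantile initialization
#'
#' Lloyd iterations on the LCFD value list. Centroids start at the
#' `(i - 0.5)/k` quantiles of the data, which makes runs fully
#' deterministic; iteration stops when the maximum centroid displacement
#' falls below `tol` (default 0.001, the minimum-distance rule of the
#' segmentation procedure) or after `max_iter` iterations (default 20).
#'
#' @param values Numeric vector (LCFD values), or an [lcfd_map()].
#' @param k Number of clusters (>= 2, at most the number of distinct
#'   values).
#' @param tol Convergence tolerance on centroid displacement.
#' @param max_iter Iteration cap.
#' @return An object of class `lcfd_kmeans`: `k`, `centroids` (sorted),
#'   `sizes`, `ranges` (tibble `class`, `min`, `max`, `n`), `assignments`
#'   (class per input value), `iterations`, `converged`, `tot_withinss`,
#'   `wss_trace` (objective after each iteration).
#' @examples
#' fit <- kmeans_1d(c(0, 0, 0, 1, 1, 1), k = 2)
#' fit$centroids  # 0 and 1
#' @export
kmeans_1d <- function(values, k, tol = 0.001, max_iter = 20) {
  if (inherits(values, "lcfd_map")) values <- lcfd_values(values)
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (k < 2) abort("`k` must be at least 2")
  if (tol <= 0) abort("`tol` must be positive")
  if (length(unique(values)) < k) {
    abort("`k` exceeds the number of distinct values")
  }
  centroids <- unname(quantile(sort(values), probs = (seq_len(k) - 0.5) / k,
                               type = 7))
  # quantile seeding can collide on heavily tied data; spread duplicates
  if (any(duplicated(centroids))) {
    centroids <- unique(sort(values))[round(seq(1, length(unique(values)),
                                                length.out = k))]
  }
  converged <- FALSE
  iterations <- 0L
  wss_trace <- numeric(0)
  assign_cls <- function(ctr) {
    d <- abs(outer(values, ctr, "-"))
    max.col(-d, ties.method = "first")
  }
  for (it in seq_len(max_iter)) {
    iterations <- it
    cls <- assign_cls(centroids)
    new_ctr <- vapply(seq_len(k), function(i) {
      v <- values[cls == i]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    # reseed an emptied class at the value farthest from its centroid
    for (i in which(is.na(new_ctr))) {
      far <- which.max(abs(values - centroids[cls]))
      new_ctr[i] <- values[far]
    }
    shift <- max(abs(new_ctr - centroids))
    centroids <- new_ctr
    wss_trace <- c(wss_trace, wss_of(values, assign_cls(centroids), centroids))
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  cls <- assign_cls(centroids)
  ord <- order(centroids)
  relabel <- match(seq_len(k), ord)
  cls <- relabel[cls]
  centroids <- centroids[ord]
  if (any(tabulate(cls, k) == 0)) {
    abort("empty class after convergence; lower `k`")
  }
  ranges <- dplyr::summarise(
    dplyr::group_by(tibble(class = cls, value = values), .data$class),
    min = min(.data$value), max = max(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  tot_withinss <- sum((values - centroids[cls])^2)
  structure(
    list(k = as.integer(k), centroids = centroids,
         sizes = tabulate(cls, k), ranges = ranges, assignments = cls,
         iterations = iterations, converged = converged,
         tot_withinss = tot_withinss, wss_trace = wss_trace),
    class = "lcfd_kmeans"
  )
}

#' @export
print.lcfd_kmeans <- function(x, ...) {
  cat(sprintf(
    "<lcfd_kmeans> k=%d, centroids %s, %s after %d iteration(s)\n",
    x$k, paste(sprintf("%.3f", x$centroids), collapse = ", "),
    if (x$converged) "converged" else "iteration cap reached", x$iterations
  ))
  invisible(x)
}

#' @describeIn kmeans_1d Per-class tibble: `class`, `centroid`, `min`,
#'   `max`, `n`.
#' @param x,... Method arguments.
#' @exportS3Method generics::tidy
tidy.lcfd_kmeans <- function(x, ...) {
  dplyr::mutate(x$ranges, centroid = x$centroids[.data$class],
                .after = "class")
}

#' @describeIn kmeans_1d One-row fit summary.
#' @exportS3Method generics::glance
glance.lcfd_kmeans <- function(x, ...) {
  tibble(k = x$k, iterations = x$iterations, converged = x$converged,
         tot_withinss = x$tot_withinss)
}

wss_of <- function(values, cls, centroids) sum((values - centroids[cls])^2)

# Internal validity indices for a 1-D clustering.
validity_indices <- function(values, fit) {
  k <- fit$k
  n <- length(values)
  cls <- fit$assignments
  centroids <- fit$centroids
  grand <- mean(values)
  wss <- fit$tot_withinss
  bss <- sum(fit$sizes * (centroids - grand)^2)
  ch <- if (wss > 0) (bss / (k - 1)) / (wss / (n - k)) else Inf
  # Davies-Bouldin
  s_i <- vapply(seq_len(k), function(i) {
    v <- values[cls == i]
    sqrt(mean((v - centroids[i])^2))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s_i[i] + s_i[j]) / abs(centroids[i] - centroids[j])
    }, numeric(1)))
  }, numeric(1)))
  sil <- mean(cluster::silhouette(cls, dist(values))[, "sil_width"])
  c(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db, wss = wss)
}

#' Select the number of clusters by internal validity indices
#'
#' Runs [kmeans_1d()] for every candidate `k` on a seeded subsample and
#' votes across four internal validity indices: mean silhouette width
#' (maximized), Calinski-Harabasz (maximized), Davies-Bouldin (minimized)
#' and the within-sum-of-squares elbow (largest drop-off curvature). The
#' majority vote wins; ties break toward the smaller `k`.
#'
#' @param values Numeric vector (or [lcfd_map()]).
#' @param k_range Candidate cluster counts within 2..10 (default `2:8`).
#' @param subsample Maximum subsample size for index computation (default
#'   2000; silhouette is quadratic in it).
#' @param seed Seed for the subsample draw.
#' @param tol,max_iter Passed to [kmeans_1d()].
#' @return The selected `k` (integer) with attribute `votes` (tibble of
#'   per-index winners) and `indices` (tibble of index values per k).
#' @export
select_k <- function(values, k_range = 2:8, subsample = 2000, seed = 1,
                     tol = 0.001, max_iter = 20) {
  if (inherits(values, "lcfd_map")) values <- lcfd_values(values)
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > 10) {
    abort("`k_range` must lie within [2, 10]")
  }
  if (length(unique(values)) < 2) abort("degenerate (constant) values")
  if (length(values) < 10 * max(k_range)) {
    abort("need at least 10 values per candidate cluster")
  }
  sub <- if (length(values) > subsample) {
    with_seed_(seed, sample(values, subsample))
  } else values
  idx <- vapply(k_range, function(k) {
    tryCatch(validity_indices(sub, kmeans_1d(sub, k, tol, max_iter)),
             error = function(e) rep(NA_real_, 4))
  }, numeric(4))
  feasible <- !is.na(idx["wss", ])
  if (!any(feasible)) abort("no feasible k in `k_range`")
  idx <- idx[, feasible, drop = FALSE]
  k_range <- k_range[feasible]
  # WSS elbow: k with the largest second difference of the WSS profile
  wss <- idx["wss", ]
  elbow_k <- if (length(wss) >= 3) {
    k_range[which.max(diff(diff(wss))) + 1L]
  } else k_range[which.max(-wss)]
  winners <- c(
    silhouette = k_range[which.max(idx["silhouette", ])],
    calinski_harabasz = k_range[which.max(idx["calinski_harabasz", ])],
    davies_bouldin = k_range[which.min(idx["davies_bouldin", ])],
    elbow = elbow_k
  )
  tallies <- table(winners)
  best <- as.integer(names(tallies)[tallies == max(tallies)])
  k <- min(best)  # ties toward smaller k
  structure(
    k,
    votes = tibble(index = names(winners), k = as.integer(winners)),
    indices = tibble(k = k_range, silhouette = idx["silhouette", ],
                     calinski_harabasz = idx["calinski_harabasz", ],
                     davies_bouldin = idx["davies_bouldin", ],
                     wss = idx["wss", ])
  )
}

#' Thresholds from a 1-D clustering
#'
#' The k-1 boundary values between adjacent classes. Each boundary is the
#' midpoint between one class's maximum and the next class's minimum; both
#' raw bounds are retained alongside, since the class minima/maxima are the
#' quantities conventionally reported as thresholds.
#'
#' @param fit An [kmeans_1d()] result.
#' @return A [threshold_set()] with columns `value` (midpoint boundary),
#'   `lower_max` (class below), `upper_min` (class above).
#' @export
class_thresholds <- function(fit) {
  stopifnot(inherits(fit, "lcfd_kmeans"))
  r <- dplyr::arrange(fit$ranges, .data$class)
  if (any(r$n == 0)) abort("empty class: cannot derive thresholds")
  lower_max <- r$max[-nrow(r)]
  upper_min <- r$min[-1]
  out <- threshold_set((lower_max + upper_min) / 2, method = "kmeans",
                       rank = seq_len(nrow(r) - 1))
  out$lower_max <- lower_max
  out$upper_min <- upper_min
  out
}
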