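#' Default pipeline configuration
#'
#' A declarative key-value list controlling [run_pipeline()]. Every entry
#' can be overridden by the `config` argument (or a YAML file with the same
#' keys); all randomness flows from the single top-level `seed`.
#'
#' @return Named list of defaults: synthetic growth-model settings (`shape`,
#'   `n_nuclei`, `contagion_prob`, `spontaneous_rate`, `steps`,
#'   `cell_size`), analysis settings (`scales`, `connectivity`,
#'   `landscape_area_ha`, `n_bins`, `k_range`, `methods`) and output
#'   switches (`render`, `write_rasters`).
#' @export
pipeline_defaults <- function() {
  list(
    mask_files = NULL,       # optional: ASCII-grid period masks to accumulate
    mask_polarity = "legacy",
    shape = c(192, 192),
    n_nuclei = 25,
    contagion_prob = 0.25,
    spontaneous_rate = 2e-4,
    steps = 7,
    cell_size = 30,
    scales = default_scales(),
    connectivity = 8,
    landscape_area_ha = NULL,
    n_bins = 256,
    k_range = 2:8,
    methods = c("ca", "kmeans"),
    render = FALSE,
    write_rasters = TRUE
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  cfg <- utils::modifyList(pipeline_defaults(), config)
  unknown <- setdiff(names(config), names(pipeline_defaults()))
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg
}

#' Run the full deforestation-characterization pipeline
#'
#' Orchestrates every stage on either synthetic or file inputs: cumulative
#' mask series (simulated nucleated growth, or accumulation of period masks
#' read from `mask_files`), the fragmentation metrics table, the LCFD map of
#' the final cumulative step, its frequency distribution, threshold
#' detection by the CA-wavelet and/or k-means routes, classification of the
#' map with each threshold set, and a JSON manifest recording inputs,
#' package version, seed and thresholds. Reruns with the same config and
#' seed produce byte-identical CSV and manifest outputs.
#'
#' @param config Named list (or YAML path) overriding [pipeline_defaults()].
#' @param seed Single integer governing all randomness.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list: `series`, `metrics`, `map`, `distribution`,
#'   `thresholds` (per method), `classified` (per method), `manifest`,
#'   `paths`.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = tempfile("ffrag_")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log <- character(0)
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  series <- stage("inputs", {
    if (!is.null(cfg$mask_files)) {
      masks <- lapply(cfg$mask_files, read_mask, polarity = cfg$mask_polarity)
      accumulate_masks(masks)
    } else {
      simulate_growth(cfg$shape, cfg$n_nuclei, cfg$contagion_prob,
                      cfg$steps, seed = seed,
                      spontaneous_rate = cfg$spontaneous_rate,
                      cell_size = cfg$cell_size)
    }
  })
  log <- c(log, sprintf("inputs: %d cumulative steps", length(series)))

  metrics <- stage("metrics", {
    metrics_series(series, landscape_area_ha = cfg$landscape_area_ha,
                   connectivity = cfg$connectivity)
  })
  paths$metrics <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics, paths$metrics)

  final <- series$landscapes[[length(series)]]
  map <- stage("lcfd", lcfd_map(final, cfg$scales))
  dist <- stage("lcfd_distribution", lcfd_distribution(map))
  paths$lcfd_text <- file.path(out_dir, "lcfd.tsv")
  write_lcfd_text(map, paths$lcfd_text)
  if (isTRUE(cfg$write_rasters)) {
    paths$lcfd_raster <- file.path(out_dir, "lcfd.asc")
    write_lcfd_raster(map, paths$lcfd_raster)
  }
  log <- c(log, sprintf("lcfd: %d valued pixels", dist$summary$n))

  thresholds <- list()
  classified <- list()
  vals <- lcfd_values(map)
  if ("ca" %in% cfg$methods) {
    thresholds$ca <- stage("segment_ca", {
      detect_thresholds_ca(vals, n_bins = cfg$n_bins)
    })
    paths$thresholds_ca <- file.path(out_dir, "thresholds_ca.csv")
    readr::write_csv(as.data.frame(thresholds$ca), paths$thresholds_ca)
  }
  if ("kmeans" %in% cfg$methods) {
    thresholds$kmeans <- stage("segment_km", {
      k <- select_k(vals, k_range = cfg$k_range, seed = seed)
      class_thresholds(kmeans_1d(vals, k))
    })
    paths$thresholds_kmeans <- file.path(out_dir, "thresholds_kmeans.csv")
    readr::write_csv(as.data.frame(thresholds$kmeans), paths$thresholds_kmeans)
  }
  for (m in names(thresholds)) {
    classified[[m]] <- stage(paste0("classify_", m), {
      classify_lcfd(map, thresholds[[m]])
    })
    if (isTRUE(cfg$write_rasters)) {
      paths[[paste0("classes_", m)]] <- file.path(out_dir,
                                                  sprintf("classes_%s.asc", m))
      write_classes(classified[[m]], paths[[paste0("classes_", m)]])
    }
    if (isTRUE(cfg$render)) {
      paths[[paste0("map_", m)]] <- file.path(out_dir, sprintf("map_%s.png", m))
      render_map(classified[[m]], paths[[paste0("map_", m)]])
    }
    interp <- interpret_classes(classified[[m]], thresholds[[m]])
    paths[[paste0("interpretation_", m)]] <-
      file.path(out_dir, sprintf("interpretation_%s.csv", m))
    readr::write_csv(interp, paths[[paste0("interpretation_", m)]])
  }
  log <- c(log, sprintf("thresholds: %s", paste(names(thresholds),
                                                collapse = ", ")))

  manifest <- list(
    package = "fractalfrag",
    version = as.character(utils::packageVersion("fractalfrag")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "mask_files")],
    inputs = if (is.null(cfg$mask_files)) "synthetic" else cfg$mask_files,
    thresholds = lapply(thresholds, function(t) t$value),
    stages = log
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(series = series, metrics = metrics, map = map,
                 distribution = dist, thresholds = thresholds,
                 classified = classified, manifest = manifest,
                 paths = paths))
}
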