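#' Pipeline run configuration
#'
#' Bundles the per-stage settings for [run_pipeline()]. Every stage reads its
#' inputs from files written by the previous stage, so any stage can be rerun
#' standalone against an existing output directory.
#'
#' @param scene a [scene_config()].
#' @param reclass_consolidation consolidation level for the crop legend.
#' @param threshold NDVI filter threshold for cover-labelled points.
#' @param split_fraction training fraction of the ground-truth points.
#' @param model_spec classifier spec ([model_random_forest()] or
#'   [model_threshold()]).
#' @param top_k rows kept per sequence table.
#' @param soc a [soc_params()].
#' @param seed integer master seed; stage seeds derive from it.
#' @return a `run_config` object.
#' @export
run_config <- function(scene = scene_config(),
                       reclass_consolidation = "seven_class",
                       threshold = 0.3, split_fraction = 0.7,
                       model_spec = model_random_forest(),
                       top_k = Inf, soc = soc_params(), seed = 1L) {
  structure(list(scene = scene,
                 reclass_consolidation = reclass_consolidation,
                 threshold = threshold, split_fraction = split_fraction,
                 model_spec = model_spec, top_k = top_k, soc = soc,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Recognised top-level keys: `seed`, `threshold`, `split_fraction`,
#' `top_k`, `reclass_consolidation`, `model` (`"random_forest"` or
#' `"threshold"`), `scene` (fields of [scene_config()], scalar-valued), and
#' `soc` (fields of [soc_params()]).
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene_args <- j$scene %||% list()
  if (!is.null(j$seed) && is.null(scene_args$seed)) {
    scene_args$seed <- j$seed
  }
  model <- switch(j$model %||% "random_forest",
                  random_forest = model_random_forest(),
                  threshold = model_threshold(),
                  stop("unknown model: ", j$model, call. = FALSE))
  run_config(
    scene = do.call(scene_config, scene_args),
    reclass_consolidation = j$reclass_consolidation %||% "seven_class",
    threshold = j$threshold %||% 0.3,
    split_fraction = j$split_fraction %||% 0.7,
    model_spec = model,
    top_k = j$top_k %||% Inf,
    soc = do.call(soc_params, as.list(j$soc %||% list())),
    seed = j$seed %||% 1L
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_simulate <- function(config, dir) {
  scene <- generate_scene(config$scene)
  paths <- write_scene(scene, file.path(dir, "scene"))
  log_stage("simulate", "seed=%d wrote %d files", config$scene$seed,
            length(paths))
  paths
}

stage_classify <- function(config, dir) {
  sdir <- file.path(dir, "scene")
  mask <- read_ascii_grid(file.path(sdir, "cultivated_mask.asc"),
                          integer_values = TRUE)
  points <- utils::read.csv(file.path(sdir, "truth_points.csv"))
  years <- sort(unique(points$year))
  paths <- character(0)
  acc <- list()
  for (y in years) {
    red <- read_ascii_grid(file.path(sdir, sprintf("red_%d.asc", y)))
    nir <- read_ascii_grid(file.path(sdir, sprintf("nir_%d.asc", y)))
    ndvi <- compute_ndvi(red, nir)
    pts <- points[points$year == y, , drop = FALSE]
    pts <- filter_training_points(pts, ndvi, config$threshold)
    pts <- split_train_validation(pts, config$split_fraction,
                                  seed = config$seed + y)
    cover <- train_and_classify(pts, list(ndvi = ndvi, red = red, nir = nir),
                                mask, config$model_spec,
                                seed = config$seed + y)
    p <- file.path(dir, sprintf("cover_%d.asc", y))
    write_ascii_grid(cover, p)
    paths <- c(paths, p)
    rep <- attr(cover, "accuracy_report")
    acc[[as.character(y)]] <- data.frame(
      year = y, overall = rep$overall,
      user_cover = rep$user_accuracy[["cover"]],
      producer_cover = rep$producer_accuracy[["cover"]],
      n_validation = rep$n_validation,
      points_dropped = attr(pts, "n_dropped") %||% NA)
    log_stage("classify", "year=%d overall accuracy=%.3f", y, rep$overall)
  }
  ap <- file.path(dir, "accuracy_report.csv")
  utils::write.csv(do.call(rbind, acc), ap, row.names = FALSE)
  c(paths, ap)
}

stage_sequences <- function(config, dir) {
  sdir <- file.path(dir, "scene")
  mask <- read_ascii_grid(file.path(sdir, "cultivated_mask.asc"),
                          integer_values = TRUE)
  map <- default_reclass_map(config$reclass_consolidation)
  crop_files <- list.files(sdir, pattern = "^crops_\\d+\\.asc$")
  years <- as.integer(gsub("\\D", "", crop_files))
  class_rasters <- cover_rasters <- list()
  for (y in sort(years)) {
    cr <- read_ascii_grid(file.path(sdir, sprintf("crops_%d.asc", y)),
                          integer_values = TRUE)
    class_rasters[[as.character(y)]] <-
      apply_cultivated_mask(reclassify(cr, map), mask)
    cf <- file.path(dir, sprintf("cover_%d.asc", y))
    if (file.exists(cf)) {
      cover_rasters[[as.character(y)]] <-
        read_ascii_grid(cf, integer_values = TRUE)
    }
  }
  rep <- rotation_report(class_rasters, cover_rasters, top_k = config$top_k)
  paths <- character(0)
  for (nm in names(rep)) {
    if (is.null(rep[[nm]])) next
    p <- file.path(dir, sprintf("sequences_%s.csv", nm))
    utils::write.csv(rep[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log_stage("sequences", "%d years, %d pattern rows (full)",
            length(cover_rasters), nrow(rep$full %||% data.frame()))
  paths
}

stage_adoption <- function(config, dir) {
  sdir <- file.path(dir, "scene")
  zones <- read_ascii_grid(file.path(sdir, "county_zones.asc"),
                           integer_values = TRUE)
  gov <- utils::read.csv(file.path(sdir, "nrcs_ledger.csv"))
  cover_files <- list.files(dir, pattern = "^cover_\\d+\\.asc$")
  years <- sort(as.integer(gsub("\\D", "", cover_files)))
  total <- do.call(rbind, lapply(years, function(y) {
    cov <- read_ascii_grid(file.path(dir, sprintf("cover_%d.asc", y)),
                           integer_values = TRUE)
    zonal_cover_acres(cov, zones, year = y)
  }))
  ledger <- compute_voluntary(total, gov)
  lp <- file.path(dir, "county_ledger.csv")
  utils::write.csv(ledger, lp, row.names = FALSE)
  trends <- adoption_trends(ledger)
  tp <- file.path(dir, "adoption_yearly.csv")
  utils::write.csv(trends$yearly, tp, row.names = FALSE)
  corr <- funding_correlation(ledger)
  sp <- file.path(dir, "adoption_summary.json")
  jsonlite::write_json(
    list(voluntary_change_acres = trends$voluntary_change_acres,
         voluntary_change_pct = trends$voluntary_change_pct,
         cumulative = as.list(trends$cumulative),
         correlation = corr),
    sp, auto_unbox = TRUE, digits = NA)
  log_stage("adoption", "voluntary change %+.1f%%, r=%.3f (n=%d)",
            trends$voluntary_change_pct, corr$r, corr$n)
  c(lp, tp, sp)
}

stage_soc <- function(config, dir) {
  yp <- file.path(dir, "adoption_yearly.csv")
  acres <- if (file.exists(yp)) utils::read.csv(yp) else published_acreage()
  tab <- soc_table(acres, config$soc)
  p <- file.path(dir, "soc_table.csv")
  utils::write.csv(tab, p, row.names = FALSE)
  log_stage("soc", "rate=%.6f tons C/acre/yr over %d year(s)",
            attr(tab, "rate"), nrow(tab))
  p
}

PIPELINE_STAGES <- c("simulate", "classify", "sequences", "adoption", "soc")

#' Run the end-to-end pipeline
#'
#' Sequences the stages simulate -> classify -> sequences -> adoption -> soc,
#' writing every artifact (plain-text rasters, CSVs, JSON summaries) under
#' `output_dir` and an md5-checksummed manifest at `manifest.json`. A stage
#' failure aborts with a stage-tagged error after writing the partial
#' manifest. Deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @param output_dir artifact directory (created if needed).
#' @param stages subset of `c("simulate", "classify", "sequences",
#'   "adoption", "soc")`, in pipeline order.
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config = run_config(), output_dir,
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  mp <- file.path(output_dir, "manifest.json")
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    fn <- switch(st, simulate = stage_simulate, classify = stage_classify,
                 sequences = stage_sequences, adoption = stage_adoption,
                 soc = stage_soc)
    paths <- tryCatch(fn(config, output_dir), error = function(e) {
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
      stop(sprintf("[stage:%s] %s", st, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[st]] <- lapply(paths, function(p) {
      list(file = basename(p),
           md5 = unname(tools::md5sum(p)))
    })
  }
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
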