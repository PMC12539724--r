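# Default crop codes: a 7-entry subset of CDL-style codes. Fallow/idle (61)
# is labelled Minor Crops so it remains part of the cropping sequence.
default_crop_codes <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 26L, 61L),
    label = c("Corn", "Cotton", "Rice", "Sorghum", "Soybean",
              "Double Crops", "Minor Crops"),
    stringsAsFactors = FALSE
  )
}

# Plausible lower-Mississippi rotation structure: soybean-dominated, with a
# strong rice/soybean alternation and persistent cotton. Rows = class this
# year, columns = class next year; rows sum to 1.
default_rotation_matrix <- function() {
  labs <- default_crop_codes()$label
  m <- rbind(
    c(0.25, 0.02, 0.02, 0.01, 0.60, 0.02, 0.08),  # Corn
    c(0.03, 0.55, 0.01, 0.01, 0.32, 0.02, 0.06),  # Cotton
    c(0.02, 0.01, 0.35, 0.01, 0.53, 0.02, 0.06),  # Rice
    c(0.05, 0.02, 0.02, 0.10, 0.70, 0.03, 0.08),  # Sorghum
    c(0.10, 0.04, 0.22, 0.02, 0.50, 0.04, 0.08),  # Soybean
    c(0.05, 0.03, 0.03, 0.02, 0.60, 0.20, 0.07),  # Double Crops
    c(0.05, 0.03, 0.08, 0.02, 0.40, 0.04, 0.38)   # Minor Crops
  )
  dimnames(m) <- list(labs, labs)
  m
}

# First-year class shares (roughly regional planted-acreage proportions).
default_initial_distribution <- function() {
  stats::setNames(c(0.10, 0.06, 0.18, 0.02, 0.45, 0.04, 0.15),
                  default_crop_codes()$label)
}

#' Configuration for the synthetic scene generator
#'
#' Describes the world the generator emulates: co-registered multi-year
#' 30-m categorical crop rasters with Markovian rotation structure, one
#' winter red/NIR composite per year in which cover-cropped pixels are green
#' (NDVI centred well above the 0.3 detection threshold) and bare pixels are
#' not, ground-truth points of which a stated fraction is mislocated off-field
#' (GPS recorded at the farmstead), a county zone map, and a county-year
#' subsidy ledger.
#'
#' @param n_rows,n_cols grid dimensions in pixels.
#' @param pixel_size_m pixel edge in meters (default 30).
#' @param years strictly increasing calendar years; each year gets a crop
#'   raster and the winter composite that follows it.
#' @param n_counties number of (contiguous, strip-shaped) county zones.
#' @param crop_codes data frame `code,label` of generated classes.
#' @param rotation_matrix row-stochastic class transition matrix
#'   (rows/columns in `crop_codes$label` order).
#' @param initial_distribution first-year class shares.
#' @param cc_adoption_rate probability a cultivated pixel carries a winter
#'   cover crop; scalar, or named vector by class label.
#' @param subsidized_fraction fraction of true cover-cropped acreage that
#'   appears in the government subsidy ledger.
#' @param contamination_rate fraction of cover-labelled ground-truth points
#'   displaced to a non-cultivated pixel (label kept, flag set).
#' @param ndvi_params list with `cover = c(mean, sd)` and `bare = c(mean, sd)`
#'   for the truncated-normal winter NDVI draws.
#' @param cultivated_fraction probability a pixel is cultivated cropland.
#' @param n_truth_points ground-truth points generated per winter.
#' @param ledger_noise_sd multiplicative noise sd on ledger acres (0 = exact).
#' @param seed integer; mandatory, drives every random draw.
#' @return a validated `scene_config` object.
#' @export
scene_config <- function(n_rows = 200, n_cols = 200, pixel_size_m = 30,
                         years = 2013:2019, n_counties = 5,
                         crop_codes = default_crop_codes(),
                         rotation_matrix = default_rotation_matrix(),
                         initial_distribution = default_initial_distribution(),
                         cc_adoption_rate = 0.3,
                         subsidized_fraction = 0.25,
                         contamination_rate = 0.1,
                         ndvi_params = list(cover = c(mean = 0.65, sd = 0.08),
                                            bare = c(mean = 0.12, sd = 0.07)),
                         cultivated_fraction = 0.9,
                         n_truth_points = 400,
                         ledger_noise_sd = 0.05,
                         seed = 1L) {
  k <- nrow(crop_codes)
  if (!is.matrix(rotation_matrix) || any(dim(rotation_matrix) != k) ||
      any(rotation_matrix < 0) ||
      any(abs(rowSums(rotation_matrix) - 1) > 1e-8)) {
    stop("`rotation_matrix` must be a row-stochastic ",
         k, "x", k, " matrix", call. = FALSE)
  }
  if (length(initial_distribution) != k || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-8) {
    stop("`initial_distribution` must be a length-", k,
         " probability vector", call. = FALSE)
  }
  if (length(years) < 1 || is.unsorted(years, strictly = TRUE)) {
    stop("`years` must be strictly increasing", call. = FALSE)
  }
  if (pixel_size_m <= 0) stop("`pixel_size_m` must be > 0", call. = FALSE)
  if (!is_proportion(cc_adoption_rate) ||
      !is_proportion(subsidized_fraction) ||
      !is_proportion(contamination_rate) ||
      !is_proportion(cultivated_fraction)) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(names(cc_adoption_rate)) &&
      !all(names(cc_adoption_rate) %in% crop_codes$label)) {
    stop("names of `cc_adoption_rate` must be class labels", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size_m = pixel_size_m, years = as.integer(years),
         n_counties = as.integer(n_counties), crop_codes = crop_codes,
         rotation_matrix = rotation_matrix,
         initial_distribution = initial_distribution,
         cc_adoption_rate = cc_adoption_rate,
         subsidized_fraction = subsidized_fraction,
         contamination_rate = contamination_rate,
         ndvi_params = ndvi_params,
         cultivated_fraction = cultivated_fraction,
         n_truth_points = as.integer(n_truth_points),
         ledger_noise_sd = ledger_noise_sd,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Per-pixel adoption probability, expanded by class code raster.
adoption_prob <- function(rate, code_values, crop_codes) {
  if (is.null(names(rate))) return(matrix(rate, nrow(code_values),
                                          ncol(code_values)))
  full <- stats::setNames(rep(0, nrow(crop_codes)), crop_codes$label)
  full[names(rate)] <- rate
  lab <- crop_codes$label[match(code_values, crop_codes$code)]
  matrix(full[lab], nrow(code_values), ncol(code_values))
}

#' Generate a synthetic multi-year scene
#'
#' Deterministic for a fixed seed. Produces, on one shared grid: per-year
#' integer crop rasters evolving by the rotation matrix; a cultivated mask;
#' per-winter cover-crop ground truth (always 0 off the cultivated mask);
#' red/NIR reflectance layers solved so that (NIR-Red)/(NIR+Red) equals the
#' drawn NDVI exactly; a county zone raster with rectangular polygons;
#' labelled ground-truth points with contamination flags; and a government
#' subsidy ledger.
#'
#' @param config a `scene_config`.
#' @return a `synthetic_scene` list: `config`, `crop_rasters` (named by
#'   year), `cultivated_mask`, `cc_truth`, `red`, `nir` (named by year),
#'   `county_zones`, `county_polygons`, `truth_points`, `nrcs_ledger`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols; n <- nr * nc
  px <- config$pixel_size_m
  codes <- config$crop_codes$code
  k <- length(codes)

  cult <- matrix(as.integer(stats::runif(n) < config$cultivated_fraction),
                 nr, nc)
  if (sum(cult) == 0) {
    stop("degenerate scene: zero cultivated pixels", call. = FALSE)
  }
  cultivated_mask <- grid_raster(cult, px)

  # county zones: contiguous vertical strips of near-equal width
  strip <- ceiling(seq_len(nc) / (nc / config$n_counties))
  strip <- pmin(strip, config$n_counties)
  zones <- matrix(rep(strip, each = nr), nr, nc)
  storage.mode(zones) <- "integer"
  county_zones <- grid_raster(zones, px)
  county_polygons <- lapply(seq_len(config$n_counties), function(i) {
    cols <- range(which(strip == i))
    list(county_id = i,
         xmin = (cols[1] - 1) * px, xmax = cols[2] * px,
         ymin = 0, ymax = nr * px)
  })

  # multi-year crop rasters via the rotation matrix
  crop_rasters <- vector("list", length(config$years))
  names(crop_rasters) <- as.character(config$years)
  cur <- matrix(sample(codes, n, replace = TRUE,
                       prob = config$initial_distribution), nr, nc)
  crop_rasters[[1]] <- grid_raster(cur, px)
  for (t in seq_along(config$years)[-1]) {
    nxt <- matrix(NA_integer_, nr, nc)
    for (j in seq_len(k)) {
      idx <- which(cur == codes[j])
      if (length(idx)) {
        nxt[idx] <- sample(codes, length(idx), replace = TRUE,
                           prob = config$rotation_matrix[j, ])
      }
    }
    cur <- nxt
    crop_rasters[[t]] <- grid_raster(cur, px)
  }

  # per-winter cover truth + reflectance composites + ground-truth points
  cc_truth <- red <- nir <- vector("list", length(config$years))
  names(cc_truth) <- names(red) <- names(nir) <- as.character(config$years)
  pts <- vector("list", length(config$years))
  cp <- config$ndvi_params$cover
  bp <- config$ndvi_params$bare
  noncult_cells <- which(cult == 0)

  for (t in seq_along(config$years)) {
    crop_v <- crop_rasters[[t]]$values
    p <- adoption_prob(config$cc_adoption_rate, crop_v, config$crop_codes)
    cc <- matrix(as.integer(stats::runif(n) < p), nr, nc)
    cc[cult == 0] <- 0L
    cc_truth[[t]] <- grid_raster(cc, px)

    ndvi <- matrix(rtruncnorm(n, bp[["mean"]], bp[["sd"]]), nr, nc)
    covered <- cc == 1L
    ndvi[covered] <- rtruncnorm(sum(covered), cp[["mean"]], cp[["sd"]])
    bright <- matrix(stats::runif(n, 0.35, 0.75), nr, nc)
    red[[t]] <- grid_raster(bright * (1 - ndvi) / 2, px)
    nir[[t]] <- grid_raster(bright * (1 + ndvi) / 2, px)

    pts[[t]] <- sample_truth_points(config, cult, cc, county_zones,
                                    config$years[t], noncult_cells)
  }
  truth_points <- do.call(rbind, pts)
  rownames(truth_points) <- NULL

  scene <- structure(
    list(config = config, crop_rasters = crop_rasters,
         cultivated_mask = cultivated_mask, cc_truth = cc_truth,
         red = red, nir = nir, county_zones = county_zones,
         county_polygons = county_polygons, truth_points = truth_points,
         nrcs_ledger = NULL),
    class = "synthetic_scene"
  )
  scene$nrcs_ledger <- generate_nrcs_ledger(
    scene, config$subsidized_fraction, seed = config$seed + 1L,
    noise_sd = config$ledger_noise_sd)
  scene
}

sample_truth_points <- function(config, cult, cc, county_zones, year,
                                noncult_cells) {
  cult_cells <- which(cult == 1)
  n_pts <- min(config$n_truth_points, length(cult_cells))
  cells <- sample(cult_cells, n_pts)
  nr <- nrow(cult)
  row <- ((cells - 1) %% nr) + 1L
  col <- ((cells - 1) %/% nr) + 1L
  xy <- xy_from_cells(county_zones, row, col)
  label <- ifelse(cc[cbind(row, col)] == 1L, "cover", "none")
  contaminated <- rep(FALSE, n_pts)

  # mislocated points: a producer records the farmstead, not the field --
  # displace some cover points onto non-cultivated pixels, keeping the label
  cov_idx <- which(label == "cover")
  n_cont <- round(config$contamination_rate * length(cov_idx))
  if (n_cont > 0 && length(noncult_cells) > 0) {
    move <- sample(cov_idx, n_cont)
    dest <- sample(noncult_cells, n_cont, replace = TRUE)
    drow <- ((dest - 1) %% nr) + 1L
    dcol <- ((dest - 1) %/% nr) + 1L
    dxy <- xy_from_cells(county_zones, drow, dcol)
    xy[move, ] <- dxy
    contaminated[move] <- TRUE
  }
  data.frame(x = xy[, "x"], y = xy[, "y"], year = year,
             label = label, contaminated = contaminated,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d @ %gm, years %s, %d counties\n",
              x$config$n_rows, x$config$n_cols, x$config$pixel_size_m,
              paste(range(x$config$years), collapse = "-"),
              x$config$n_counties))
  cat(sprintf("cultivated pixels: %d; truth points: %d\n",
              sum(x$cultivated_mask$values), nrow(x$truth_points)))
  invisible(x)
}

#' True cover-cropped acres per county-year
#'
#' Zonal ground-truth acreage: positive `cc_truth` pixels per county times
#' per-pixel acreage.
#'
#' @param scene a `synthetic_scene`.
#' @return data frame `county_id, year, acres`.
#' @export
true_cover_acres <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  out <- lapply(names(scene$cc_truth), function(yr) {
    df <- zonal_cover_acres(scene$cc_truth[[yr]], scene$county_zones,
                            year = as.integer(yr))
    df
  })
  do.call(rbind, out)
}

#' Generate a government subsidy ledger from scene truth
#'
#' Per county-year, subsidized acres are `subsidized_fraction` times the true
#' cover-cropped acres, optionally perturbed by multiplicative Gaussian noise,
#' clamped to `[0, truth]` so the ledger never exceeds the ground truth.
#'
#' @param scene a `synthetic_scene`.
#' @param subsidized_fraction proportion in \[0, 1\].
#' @param seed integer RNG seed.
#' @param noise_sd sd of the multiplicative noise (0 gives exact fractions).
#' @return data frame `county_id, year, government_acres`.
#' @export
generate_nrcs_ledger <- function(scene, subsidized_fraction, seed,
                                 noise_sd = 0.05) {
  if (!is_proportion(subsidized_fraction)) {
    stop("`subsidized_fraction` must lie in [0, 1]", call. = FALSE)
  }
  truth <- true_cover_acres(scene)
  with_seed(seed, {
    noise <- 1 + stats::rnorm(nrow(truth), 0, noise_sd)
    gov <- pmin(truth$acres, pmax(0, subsidized_fraction * truth$acres * noise))
    data.frame(county_id = truth$county_id, year = truth$year,
               government_acres = gov, stringsAsFactors = FALSE)
  })
}

#' Write every scene artifact to plain-text files
#'
#' Rasters go to ESRI ASCII grids, county polygons to GeoJSON, points and
#' ledger to CSV.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(r, name) {
    p <- file.path(dir, name)
    write_ascii_grid(r, p)
    paths <<- c(paths, p)
  }
  for (yr in names(scene$crop_rasters)) {
    w(scene$crop_rasters[[yr]], sprintf("crops_%s.asc", yr))
    w(scene$cc_truth[[yr]], sprintf("cc_truth_%s.asc", yr))
    w(scene$red[[yr]], sprintf("red_%s.asc", yr))
    w(scene$nir[[yr]], sprintf("nir_%s.asc", yr))
  }
  w(scene$cultivated_mask, "cultivated_mask.asc")
  w(scene$county_zones, "county_zones.asc")

  gj <- list(
    type = "FeatureCollection",
    features = lapply(scene$county_polygons, function(p) {
      ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin), c(p$xmax, p$ymax),
                   c(p$xmin, p$ymax), c(p$xmin, p$ymin))
      list(type = "Feature",
           properties = list(county_id = p$county_id),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
  )
  pj <- file.path(dir, "county_zones.geojson")
  jsonlite::write_json(gj, pj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pj)

  pp <- file.path(dir, "truth_points.csv")
  utils::write.csv(scene$truth_points, pp, row.names = FALSE)
  pl <- file.path(dir, "nrcs_ledger.csv")
  utils::write.csv(scene$nrcs_ledger, pl, row.names = FALSE)
  invisible(c(paths, pp, pl))
}
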