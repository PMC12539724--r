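# Class labels used throughout: the seven-class legend keeps the five major
# cash crops separate; the consolidated legend folds the low-acreage classes
# (rice, sorghum, double crops, minor crops) into "Other Crops".
SEVEN_CLASSES <- c("Corn", "Cotton", "Rice", "Sorghum", "Soybean",
                   "Double Crops", "Minor Crops")
CONSOLIDATED_CLASSES <- c("Corn", "Cotton", "Soybean", "Other Crops")

#' Code-to-class reclassification table
#'
#' Maps CDL-style integer crop codes onto analysis classes. At the
#' `seven_class` level the legend is Corn, Cotton, Rice, Sorghum, Soybean,
#' Double Crops, Minor Crops; the `consolidated` level merges rice, sorghum,
#' double crops and minor crops into "Other Crops". Fallow/idle land stays in
#' the cropping sequence and is housed (by default) under Minor Crops.
#'
#' @param codes integer vector of raster codes.
#' @param labels character vector of class labels, parallel to `codes`; each
#'   must be one of the seven-class labels.
#' @param consolidation `"seven_class"` or `"consolidated"`.
#' @param default_label class assigned to codes absent from the table.
#' @return a `reclass_map` object.
#' @export
reclass_map <- function(codes, labels,
                        consolidation = c("seven_class", "consolidated"),
                        default_label = "Minor Crops") {
  consolidation <- match.arg(consolidation)
  codes <- as.integer(codes)
  if (length(codes) == 0) stop("empty reclassification map", call. = FALSE)
  if (length(codes) != length(labels)) {
    stop("`codes` and `labels` lengths differ", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("every input code must map to exactly one label", call. = FALSE)
  }
  bad <- setdiff(unique(labels), SEVEN_CLASSES)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!default_label %in% SEVEN_CLASSES) {
    stop("`default_label` must be a seven-class label", call. = FALSE)
  }
  structure(
    list(codes = codes, labels = as.character(labels),
         consolidation = consolidation, default_label = default_label),
    class = "reclass_map"
  )
}

#' Default CDL-style reclassification map
#'
#' Corn=1, cotton=2, rice=3, sorghum=4, soybean=5; the four winter-wheat
#' double-crop codes (26, 225, 236, 238) merge into Double Crops;
#' fallow/idle (61) joins Minor Crops so it stays part of the cropping
#' sequence; any unmapped code defaults to Minor Crops.
#'
#' @inheritParams reclass_map
#' @return a `reclass_map`.
#' @export
default_reclass_map <- function(consolidation = c("seven_class",
                                                  "consolidated")) {
  consolidation <- match.arg(consolidation)
  reclass_map(
    codes = c(1L, 2L, 3L, 4L, 5L, 26L, 225L, 236L, 238L, 61L),
    labels = c("Corn", "Cotton", "Rice", "Sorghum", "Soybean",
               "Double Crops", "Double Crops", "Double Crops", "Double Crops",
               "Minor Crops"),
    consolidation = consolidation
  )
}

#' Read a reclassification map from CSV
#'
#' @param path CSV with columns `code,label`.
#' @inheritParams reclass_map
#' @return a `reclass_map`.
#' @export
read_reclass_map <- function(path,
                             consolidation = c("seven_class", "consolidated"),
                             default_label = "Minor Crops") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reclass_map(df$code, df$label, consolidation = match.arg(consolidation),
              default_label = default_label)
}

consolidate_label <- function(labels) {
  merged <- c("Rice", "Sorghum", "Double Crops", "Minor Crops")
  ifelse(labels %in% merged, "Other Crops", labels)
}

#' Reclassify a categorical raster into analysis classes
#'
#' Pixel-wise table lookup. Codes absent from the map fall back to the map's
#' default class; the number of such pixels is reported as a warning.
#' Nodata propagates unchanged.
#'
#' @param raster a `grid_raster` of integer codes.
#' @param map a `reclass_map`.
#' @return a categorical `grid_raster` whose legend is the class list at the
#'   map's consolidation level.
#' @export
reclassify <- function(raster, map) {
  stopifnot(inherits(raster, "grid_raster"), inherits(map, "reclass_map"))
  legend <- if (map$consolidation == "consolidated") CONSOLIDATED_CLASSES
            else SEVEN_CLASSES
  labels <- map$labels
  if (map$consolidation == "consolidated") labels <- consolidate_label(labels)
  default_label <- map$default_label
  if (map$consolidation == "consolidated") {
    default_label <- consolidate_label(default_label)
  }
  v <- raster$values
  idx <- match(as.vector(v), map$codes)
  unmapped <- !is.na(as.vector(v)) & is.na(idx)
  if (any(unmapped)) {
    warning(sprintf("%d pixel(s) with unmapped codes assigned to '%s'",
                    sum(unmapped), default_label), call. = FALSE)
  }
  out_labels <- labels[idx]
  out_labels[unmapped] <- default_label
  out <- matrix(match(out_labels, legend), nrow = nrow(v))
  storage.mode(out) <- "integer"
  grid_raster(out, pixel_size_m = raster$pixel_size_m,
              xll = raster$xll, yll = raster$yll, legend = legend)
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), a greenness proxy in \[-1, 1\]. Cells
#' where NIR + Red = 0 (or either band is nodata) are set to `NA`.
#'
#' @param red,nir co-registered reflectance `grid_raster`s with values >= 0.
#' @return a float `grid_raster` of NDVI.
#' @export
compute_ndvi <- function(red, nir) {
  stop_if_grid_mismatch(red, nir, what = "red/nir rasters")
  r <- red$values; n <- nir$values
  if (any(r < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE)) {
    stop("reflectance values must be >= 0", call. = FALSE)
  }
  s <- n + r
  out <- (n - r) / s
  out[!is.na(s) & s == 0] <- NA
  grid_raster(out, pixel_size_m = red$pixel_size_m,
              xll = red$xll, yll = red$yll)
}

#' Apply a cultivated-land mask
#'
#' Pixels where the mask is 0 (or nodata) are set to the nodata sentinel and
#' thereby excluded from all downstream counts and area sums; retained pixels
#' are untouched.
#'
#' @param raster any `grid_raster`.
#' @param mask a co-registered binary `grid_raster` (1 = keep).
#' @return the masked `grid_raster`.
#' @export
apply_cultivated_mask <- function(raster, mask) {
  stop_if_grid_mismatch(raster, mask, what = "raster and mask")
  v <- raster$values
  drop <- is.na(mask$values) | mask$values == 0
  v[drop] <- NA
  grid_raster(v, pixel_size_m = raster$pixel_size_m,
              xll = raster$xll, yll = raster$yll, legend = raster$legend)
}
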