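#' Filter ground-truth points by NDVI threshold
#'
#' Cover-labelled points sitting on pixels whose winter NDVI does not exceed
#' the threshold (strictly greater keeps a point) are dropped: such points are
#' typically GPS locations recorded at a farmstead rather than in the field.
#' "none"-labelled points are never filtered — the purpose of the rule is to
#' pinpoint locations *within* cover-crop fields, not to purify the negatives.
#'
#' @param points data frame with columns `x`, `y`, `label` (`"cover"`/
#'   `"none"`); extra columns pass through.
#' @param ndvi a `grid_raster` of winter NDVI.
#' @param threshold NDVI cutoff (default 0.3).
#' @return the filtered data frame, with an `ndvi` feature column added and
#'   attribute `n_dropped` recording how many cover points were removed.
#' @export
filter_training_points <- function(points, ndvi, threshold = 0.3) {
  stopifnot(is.data.frame(points), inherits(ndvi, "grid_raster"))
  v <- extract_at(ndvi, points$x, points$y)
  points$ndvi <- v
  is_cover <- points$label == "cover"
  keep <- !is_cover | (!is.na(v) & v > threshold)
  n_dropped <- sum(is_cover) - sum(keep & is_cover)
  if (sum(is_cover) > 0 && sum(keep & is_cover) == 0) {
    stop("empty training set: every cover-labelled point fell at NDVI <= ",
         threshold, call. = FALSE)
  }
  message(sprintf("NDVI filter (> %g): dropped %d of %d cover point(s)",
                  threshold, n_dropped, sum(is_cover)))
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Stratified train/validation split
#'
#' Splits points into training and validation sets, stratified by label so
#' both classes appear on both sides; deterministic for a fixed seed.
#'
#' @param set data frame with a `label` column.
#' @param fraction training fraction (default 0.7).
#' @param seed integer RNG seed.
#' @return `set` with a `split_tag` column (`"train"`/`"validation"`).
#' @export
split_train_validation <- function(set, fraction = 0.7, seed) {
  stopifnot(is.data.frame(set), is_proportion(fraction))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  tab <- table(set$label)
  if (any(tab < 2)) {
    stop("stratification error: class with fewer than 2 points: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  set$split_tag <- "validation"
  with_seed(seed, {
    for (lbl in names(tab)) {
      idx <- which(set$label == lbl)
      n_train <- round(fraction * length(idx))
      set$split_tag[sample(idx, n_train)] <- "train"
    }
  })
  if (!any(set$split_tag == "validation")) {
    warning("empty validation set (fraction = ", fraction, ")", call. = FALSE)
  }
  set
}

#' Classifier specifications
#'
#' `model_random_forest()` is the default model; `model_threshold()` is a
#' pure NDVI-rule classifier (predict cover wherever the chosen feature
#' exceeds the threshold) kept as an independent oracle route.
#'
#' @param ntree,mtry,max_depth forest hyperparameters.
#' @return a `model_spec` list.
#' @export
model_random_forest <- function(ntree = 100, mtry = NULL, max_depth = 10L) {
  structure(list(type = "random_forest", ntree = ntree, mtry = mtry,
                 max_depth = max_depth), class = "model_spec")
}

#' @rdname model_random_forest
#' @param feature feature name the rule thresholds on.
#' @param threshold decision cutoff.
#' @export
model_threshold <- function(feature = "ndvi", threshold = 0.3) {
  structure(list(type = "threshold", feature = feature,
                 threshold = threshold), class = "model_spec")
}

build_feature_matrix <- function(features, x, y) {
  m <- vapply(features, function(r) extract_at(r, x, y), numeric(length(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(features)))
  m
}

#' Train a classifier and map cover crops
#'
#' Fits the requested model on the training split, evaluates it on the
#' validation split, and predicts a binary with/without-cover raster over the
#' cultivated pixels. Masked (non-cultivated) pixels are nodata and never
#' receive a positive prediction.
#'
#' @param train output of [split_train_validation()]: points with `label`
#'   and `split_tag` columns.
#' @param features named list of co-registered feature `grid_raster`s
#'   (typically `ndvi`, `red`, `nir`).
#' @param mask binary cultivated-mask `grid_raster`.
#' @param model_spec a [model_random_forest()] or [model_threshold()] spec.
#' @param seed integer RNG seed for the stochastic model fit.
#' @return a binary `grid_raster` (1 = cover) with attributes
#'   `accuracy_report` (overall/user/producer accuracy on validation points)
#'   and `model`.
#' @export
train_and_classify <- function(train, features, mask,
                               model_spec = model_random_forest(),
                               seed = 1L) {
  stopifnot(is.data.frame(train), is.list(features),
            inherits(mask, "grid_raster"))
  do.call(stop_if_grid_mismatch, c(unname(features), list(mask)))
  if (!"split_tag" %in% names(train)) train$split_tag <- "train"
  tr <- train[train$split_tag == "train", , drop = FALSE]
  if (nrow(tr) == 0 || length(unique(tr$label)) < 2) {
    stop("degenerate model: training split must contain both labels",
         call. = FALSE)
  }

  xt <- build_feature_matrix(features, tr$x, tr$y)
  yt <- factor(tr$label, levels = c("cover", "none"))

  if (model_spec$type == "random_forest") {
    mtry <- model_spec$mtry %||% max(1L, floor(sqrt(ncol(xt))))
    model <- with_seed(seed, rf_fit(xt, yt, ntree = model_spec$ntree,
                                    mtry = mtry,
                                    max_depth = model_spec$max_depth))
    predict_fun <- function(m) predict(model, m)
  } else if (model_spec$type == "threshold") {
    f <- model_spec$feature
    thr <- model_spec$threshold
    model <- model_spec
    predict_fun <- function(m) {
      factor(ifelse(m[, f] > thr, "cover", "none"),
             levels = c("cover", "none"))
    }
  } else {
    stop("unknown model_spec type: ", model_spec$type, call. = FALSE)
  }

  # predict over cultivated pixels only
  keep <- !is.na(mask$values) & mask$values == 1
  cells <- which(keep)
  nr <- nrow(mask$values)
  fx <- vapply(features,
               function(r) r$values[cells], numeric(length(cells)))
  if (is.null(dim(fx))) {
    fx <- matrix(fx, nrow = length(cells), dimnames = list(NULL, names(features)))
  }
  pred <- predict_fun(fx)
  out <- matrix(NA_integer_, nr, ncol(mask$values))
  out[cells] <- as.integer(pred == "cover")

  report <- NULL
  va <- train[train$split_tag == "validation", , drop = FALSE]
  if (nrow(va) > 0) {
    xv <- build_feature_matrix(features, va$x, va$y)
    pv <- predict_fun(xv)
    report <- accuracy_report(factor(va$label, levels = c("cover", "none")),
                              pv)
  }

  cr <- grid_raster(out, pixel_size_m = mask$pixel_size_m,
                    xll = mask$xll, yll = mask$yll)
  attr(cr, "accuracy_report") <- report
  attr(cr, "model") <- model
  cr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Confusion-matrix summary: overall, user's (precision) and producer's
# (recall) accuracy per class, on validation points.
accuracy_report <- function(truth, pred) {
  cm <- table(truth = truth, pred = pred)
  overall <- sum(diag(cm)) / sum(cm)
  user <- diag(cm) / pmax(colSums(cm), 1)      # by prediction
  producer <- diag(cm) / pmax(rowSums(cm), 1)  # by truth
  list(confusion = cm, overall = overall,
       user_accuracy = user, producer_accuracy = producer,
       n_validation = sum(cm))
}

#' Winter wheat harvested-for-grain share
#'
#' The classifier treats winter wheat as a cover crop; this proxy bounds the
#' error of that assumption by expressing wheat harvested for grain as a
#' percentage of total cropland, per year.
#'
#' @param wheat_harvested_acres numeric vector of yearly acres.
#' @param total_cropland_acres numeric vector of yearly acres (> 0).
#' @return numeric vector: `100 * wheat / total` per year.
#' @export
winter_wheat_grain_share <- function(wheat_harvested_acres,
                                     total_cropland_acres) {
  if (any(wheat_harvested_acres < 0) || any(total_cropland_acres < 0)) {
    stop("acreages must be non-negative", call. = FALSE)
  }
  if (any(total_cropland_acres <= 0)) {
    stop("`total_cropland_acres` must be > 0", call. = FALSE)
  }
  100 * wheat_harvested_acres / total_cropland_acres
}
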