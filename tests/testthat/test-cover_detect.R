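make_ndvi_raster <- function(vals) grid_raster(matrix(vals, 1))

test_that("NDVI filter keeps strictly-greater cover points and all negatives", {
  ndvi <- make_ndvi_raster(c(0.31, 0.30, 0.10))
  pts <- data.frame(x = c(0.5, 1.5, 2.5) * 30, y = rep(15, 3),
                    label = c("cover", "cover", "none"))
  suppressMessages(out <- filter_training_points(pts, ndvi))
  expect_equal(out$label, c("cover", "none"))   # 0.31 kept, 0.30 dropped
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$ndvi, c(0.31, 0.10))

  all_bad <- data.frame(x = 1.5 * 30, y = 15, label = "cover")
  expect_error(suppressMessages(filter_training_points(all_bad, ndvi)),
               "empty training")
})

test_that("filtering is monotone in the threshold", {
  set.seed(8)
  ndvi <- grid_raster(matrix(runif(400, -0.2, 0.9), 20, 20))
  pts <- data.frame(x = runif(120, 0, 20 * 30), y = runif(120, 0, 20 * 30),
                    label = sample(c("cover", "none"), 120, replace = TRUE))
  kept <- vapply(c(0.1, 0.3, 0.5, 0.7), function(th) {
    out <- suppressMessages(filter_training_points(pts, ndvi, th))
    sum(out$label == "cover")
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("noiseless contamination is removed exactly by the filter", {
  cfg <- small_scene_config(contamination_rate = 0.2,
                            ndvi_params = noiseless_ndvi())
  sc <- generate_scene(cfg)
  yr <- "2013"
  pts <- sc$truth_points[sc$truth_points$year == 2013, ]
  ndvi <- compute_ndvi(sc$red[[yr]], sc$nir[[yr]])
  suppressMessages(out <- filter_training_points(pts, ndvi))
  expect_equal(attr(out, "n_dropped"),
               sum(pts$contaminated & pts$label == "cover"))
  expect_false(any(out$contaminated))
})

test_that("train/validation split is stratified, sized, and deterministic", {
  pts <- data.frame(x = 1:100, y = 1:100,
                    label = rep(c("cover", "none"), each = 50))
  s1 <- split_train_validation(pts, 0.7, seed = 4)
  expect_equal(sum(s1$split_tag == "train"), 70)
  expect_equal(sum(s1$split_tag == "validation"), 30)
  expect_equal(sum(s1$split_tag == "train" & s1$label == "cover"), 35)
  s2 <- split_train_validation(pts, 0.7, seed = 4)
  expect_identical(s1, s2)

  expect_warning(split_train_validation(pts, 1.0, seed = 1), "empty validation")
  one <- data.frame(x = 1:3, y = 1:3, label = c("cover", "none", "none"))
  expect_error(split_train_validation(one, 0.7, seed = 1), "stratification")
  expect_error(split_train_validation(pts, 0.7), "mandatory")
})

test_that("threshold classifier reproduces truth on a separable scene", {
  cfg <- small_scene_config(ndvi_params = noiseless_ndvi(),
                            contamination_rate = 0)
  sc <- generate_scene(cfg)
  yr <- "2013"
  ndvi <- compute_ndvi(sc$red[[yr]], sc$nir[[yr]])
  pts <- sc$truth_points[sc$truth_points$year == 2013, ]
  pts <- suppressMessages(filter_training_points(pts, ndvi))
  pts <- split_train_validation(pts, 0.7, seed = 2)
  cover <- train_and_classify(pts, list(ndvi = ndvi), sc$cultivated_mask,
                              model_threshold(), seed = 2)
  cult <- sc$cultivated_mask$values == 1
  expect_identical(cover$values[cult], sc$cc_truth[[yr]]$values[cult])
  # masked pixels carry no positive predictions
  expect_true(all(is.na(cover$values[!cult])))
  rep <- attr(cover, "accuracy_report")
  expect_equal(rep$overall, 1)
})

test_that("all-bare scenes yield an all-zero cover raster", {
  cfg <- small_scene_config(cc_adoption_rate = 0,
                            ndvi_params = noiseless_ndvi())
  sc <- generate_scene(cfg)
  yr <- "2013"
  ndvi <- compute_ndvi(sc$red[[yr]], sc$nir[[yr]])
  pts <- sc$truth_points[sc$truth_points$year == 2013, ]
  # inject two synthetic cover points so the model is trainable
  fake <- pts[1:2, ]
  fake$label <- "cover"
  cult <- sc$cultivated_mask$values == 1
  pred_in <- rbind(pts, fake)
  pred_in$split_tag <- "train"
  cover <- train_and_classify(pred_in, list(ndvi = ndvi),
                              sc$cultivated_mask, model_threshold(), seed = 1)
  expect_true(all(cover$values[cult] == 0L))
})

test_that("single-label training is a degenerate model", {
  pts <- data.frame(x = 1:10, y = 1:10, label = "none", split_tag = "train")
  mask <- grid_raster(matrix(1L, 5, 5))
  ndvi <- grid_raster(matrix(0.5, 5, 5))
  expect_error(train_and_classify(pts, list(ndvi = ndvi), mask),
               "degenerate")
})

test_that("random forest separates cover from bare at default noise", {
  cfg <- scene_config(n_rows = 60, n_cols = 60, years = 2013L,
                      n_truth_points = 300, seed = 21)
  sc <- generate_scene(cfg)
  ndvi <- compute_ndvi(sc$red[["2013"]], sc$nir[["2013"]])
  pts <- suppressMessages(filter_training_points(sc$truth_points, ndvi))
  pts <- split_train_validation(pts, 0.7, seed = 3)
  cover <- train_and_classify(
    pts, list(ndvi = ndvi, red = sc$red[["2013"]], nir = sc$nir[["2013"]]),
    sc$cultivated_mask, model_random_forest(ntree = 50), seed = 3)
  rep <- attr(cover, "accuracy_report")
  expect_gte(rep$overall, 0.95)
  # acreage recovers generative truth within 10%
  est <- sum(cover$values == 1L, na.rm = TRUE)
  truth <- sum(sc$cc_truth[["2013"]]$values == 1L)
  expect_lt(abs(est - truth) / truth, 0.10)
})

test_that("winter wheat grain share is a simple yearly percentage", {
  expect_equal(winter_wheat_grain_share(10, 1000), 1)
  expect_equal(winter_wheat_grain_share(0, 1000), 0)
  expect_error(winter_wheat_grain_share(-1, 100), "non-negative")
  expect_error(winter_wheat_grain_share(1, 0), "> 0")
  # engineered series spanning the plausible band
  wheat <- c(8, 25, 97, 50)
  total <- rep(1000, 4)
  share <- winter_wheat_grain_share(wheat, total)
  expect_true(all(share >= 0.8 & share <= 9.7))
})
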