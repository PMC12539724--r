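test_that("pattern counts multiply through the arity", {
  expect_equal(enumerate_patterns(7, 2), 14L)
  expect_equal(enumerate_patterns(7, 2, 7), 98L)
  expect_equal(enumerate_patterns(133, 2, 133), 35378L)
})

test_that("constant rasters combine to a single full-cover pattern", {
  a <- grid_raster(matrix(1L, 6, 6), legend = c("Soybean"))
  b <- grid_raster(matrix(2L, 6, 6), legend = c("None", "CC"))
  out <- combine_rasters(list(a, b))
  expect_equal(nrow(out$table), 1)
  expect_equal(out$table$label, "Soybean – CC")
  expect_equal(out$table$pixels, 36L)
  expect_equal(out$table$pct, 100)
})

test_that("7 classes x 2 states with all combos present gives 14 rows", {
  legend7 <- c("Corn", "Cotton", "Rice", "Sorghum", "Soybean",
               "Double Crops", "Minor Crops")
  v <- matrix(rep(1:7, each = 2), 2, 7)
  crop <- grid_raster(v, legend = legend7)
  cover <- grid_raster(matrix(rep(1:2, 7), 2, 7), legend = c("None", "CC"))
  out <- combine_rasters(list(crop, cover))
  expect_equal(nrow(out$table), 14)
  expect_equal(sum(out$table$pixels), 14L)
})

test_that("combine equals the nested-loop cross-tab oracle", {
  set.seed(31)
  legend7 <- c("Corn", "Cotton", "Rice", "Sorghum", "Soybean",
               "Double Crops", "Minor Crops")
  for (rep_i in 1:20) {
    arity <- sample(2:3, 1)
    rasters <- c(list(random_class_raster(12, 12, legend7, na_frac = 0.1)),
                 list(random_class_raster(12, 12, c("None", "CC"),
                                          na_frac = 0.05)))
    if (arity == 3) {
      rasters <- c(rasters, list(random_class_raster(12, 12, legend7)))
    }
    got <- combine_rasters(rasters)$table
    want <- oracle_crosstab(rasters)
    expect_equal(got, want)
  }
})

test_that("areas conserve and percentages sum to 100", {
  set.seed(5)
  legend <- c("Corn", "Soybean", "Rice")
  a <- random_class_raster(20, 20, legend, na_frac = 0.15)
  b <- random_class_raster(20, 20, c("None", "CC"))
  out <- combine_rasters(list(a, b))
  accountable <- sum(!is.na(a$values) & !is.na(b$values))
  expect_equal(sum(out$table$pixels), accountable)
  expect_equal(sum(out$table$acres), accountable * pixel_acres(a))
  expect_equal(sum(out$table$pct), 100)
  # pattern raster agrees with the table
  expect_equal(as.integer(table(out$raster$values)[as.character(
    seq_len(nrow(out$table)))]), out$table$pixels)
})

test_that("combine is permutation-consistent and marginalizes exactly", {
  set.seed(17)
  legend <- c("Corn", "Soybean")
  a <- random_class_raster(15, 15, legend, na_frac = 0.1)
  b <- random_class_raster(15, 15, c("None", "CC"))
  c3 <- random_class_raster(15, 15, legend)

  ab <- combine_rasters(list(a, b))$table
  ba <- combine_rasters(list(b, a))$table
  flip <- function(lbl) {
    parts <- strsplit(lbl, " – ", fixed = TRUE)
    vapply(parts, function(p) paste(rev(p), collapse = " – "), character(1))
  }
  ba$label <- flip(ba$label)
  ba <- ba[order(-ba$acres, ba$label), ]
  rownames(ba) <- NULL
  expect_equal(ab, ba)

  full <- combine_rasters(list(a, b, c3))$table
  # marginalize over the third element
  first2 <- sub(" – [^–]+$", "", full$label)
  marg <- tapply(full$pixels, first2, sum)
  two <- combine_rasters(list(a, b))$table
  # rasters differ in NA patterns: restrict to pixels valid in all three
  mask3 <- grid_raster(
    matrix(ifelse(is.na(c3$values), NA_integer_, 1L), 15, 15))
  a2 <- apply_cultivated_mask(a, mask3)
  two3 <- combine_rasters(list(a2, b))$table
  expect_equal(sort(names(marg)), sort(two3$label))
  expect_equal(as.integer(marg[two3$label]), two3$pixels)
})

test_that("arity and legend contracts are enforced", {
  a <- grid_raster(matrix(1L, 3, 3), legend = "Corn")
  expect_error(combine_rasters(list(a)), "2 or 3")
  expect_error(combine_rasters(list(a, a, a, a)), "2 or 3")
  expect_error(combine_rasters(list(a, grid_raster(matrix(1L, 4, 4),
                                                   legend = "Corn"))),
               "co-registered")
  expect_error(combine_rasters(list(a, grid_raster(matrix(1L, 3, 3)))),
               "legend")
})

test_that("rotation report finds a constructed dominant sequence", {
  # soybean always follows soybean with a cover crop in between
  legend <- c("Corn", "Soybean")
  soy <- grid_raster(matrix(2L, 8, 8), legend = legend)
  corn <- grid_raster(matrix(1L, 8, 8), legend = legend)
  cc <- grid_raster(matrix(1L, 8, 8))           # all cover
  none <- grid_raster(matrix(0L, 8, 8))
  class_rasters <- list("2013" = soy, "2014" = soy, "2015" = corn)
  cover_rasters <- list("2013" = cc, "2014" = none)
  rep <- rotation_report(class_rasters, cover_rasters)
  top13 <- rep$full[rep$full$year == 2013, ][1, ]
  expect_equal(top13$label, "Soybean – CC – Soybean")
  expect_equal(top13$pct, 100)

  # top-k = all equals the full table
  set.seed(2)
  a <- random_class_raster(10, 10, legend)
  b <- random_class_raster(10, 10, c("None", "CC"))
  tab <- combine_rasters(list(a, b))$table
  expect_equal(top_patterns(tab, Inf), tab)
  expect_equal(nrow(top_patterns(tab, 2)), 2)
})

test_that("missing next-year raster truncates the report with a warning", {
  legend <- c("Corn", "Soybean")
  class_rasters <- list("2013" = grid_raster(matrix(2L, 5, 5),
                                             legend = legend))
  cover_rasters <- list("2013" = grid_raster(matrix(1L, 5, 5)))
  expect_warning(rep <- rotation_report(class_rasters, cover_rasters),
                 "truncated")
  expect_null(rep$full)
  expect_false(is.null(rep$before))
})

test_that("a 10x10 fixture reproduces hand-computed shares", {
  legend <- c("Corn", "Soybean")
  # 60 soybean pixels, 40 corn pixels; cover on 25 soybean + 10 corn pixels
  crop_v <- matrix(c(rep(2L, 60), rep(1L, 40)), 10, 10)
  cover_v <- matrix(0L, 10, 10)
  cover_v[1:25] <- 1L         # all within the soybean block
  cover_v[61:70] <- 1L        # 10 corn pixels
  crop <- grid_raster(crop_v, legend = legend)
  cover <- cover_as_class(grid_raster(cover_v))
  tab <- combine_rasters(list(crop, cover))$table
  get <- function(lbl) tab$pct[tab$label == lbl]
  expect_equal(get("Soybean – CC"), 25)
  expect_equal(get("Soybean – None"), 35)
  expect_equal(get("Corn – CC"), 10)
  expect_equal(get("Corn – None"), 30)
})
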