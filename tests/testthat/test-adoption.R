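test_that("zonal accounting partitions the scene", {
  # single county covering the grid: county acres = scene total
  cover <- grid_raster(matrix(c(1L, 0L), 6, 6))
  one <- grid_raster(matrix(1L, 6, 6))
  z1 <- zonal_cover_acres(cover, one, year = 2013)
  expect_equal(z1$acres, sum(cover$values) * pixel_acres(cover))

  # empty cover raster: explicit zero rows
  empty <- grid_raster(matrix(0L, 6, 6))
  z0 <- zonal_cover_acres(empty, one)
  expect_equal(z0$acres, 0)

  # two-county split of a known truth raster matches a manual tally
  zones <- grid_raster(matrix(rep(c(1L, 2L), each = 18), 6, 6))
  z2 <- zonal_cover_acres(cover, zones)
  left <- sum(cover$values[, 1:3] == 1L)
  right <- sum(cover$values[, 4:6] == 1L)
  expect_equal(z2$acres, c(left, right) * pixel_acres(cover))
  expect_equal(sum(z2$acres), z1$acres)

  # zone id missing from the polygon set raises a consistency warning
  polys <- list(list(county_id = 1))
  expect_warning(zonal_cover_acres(cover, zones, polygons = polys),
                 "absent from polygon set")
})

test_that("zonal truth recovers the generative oracle per county", {
  sc <- generate_scene(small_scene_config(seed = 13))
  got <- true_cover_acres(sc)
  # independent tally: loop over counties and compare raw pixel counts
  for (yr in names(sc$cc_truth)) {
    cc <- sc$cc_truth[[yr]]$values
    zv <- sc$county_zones$values
    for (cid in 1:sc$config$n_counties) {
      manual <- sum(cc[zv == cid] == 1L) * pixel_acres(sc$county_zones)
      expect_equal(
        got$acres[got$year == as.integer(yr) & got$county_id == cid],
        manual)
    }
  }
})

test_that("voluntary = total - government, exactly and row-wise", {
  total <- data.frame(county_id = 1, year = 2013, acres = 677272)
  gov <- data.frame(county_id = 1, year = 2013, government_acres = 9617)
  led <- compute_voluntary(total, gov)
  expect_equal(led$voluntary_acres, 667655)

  # government = 0 acts as identity
  gov0 <- data.frame(county_id = 1, year = 2013, government_acres = 0)
  expect_equal(compute_voluntary(total, gov0)$voluntary_acres, 677272)

  # government > total: negative voluntary retained and flagged
  govbig <- data.frame(county_id = 1, year = 2013, government_acres = 7e5)
  ledb <- compute_voluntary(total, govbig)
  expect_equal(ledb$voluntary_acres, 677272 - 7e5)
  expect_true(ledb$negative_voluntary)

  # missing keys warn and fill 0; duplicates error
  t2 <- data.frame(county_id = c(1, 2), year = 2013, acres = c(10, 20))
  expect_warning(led2 <- compute_voluntary(t2, gov0), "missing")
  expect_equal(led2$voluntary_acres[led2$county_id == 2], 20)
  dup <- rbind(gov0, gov0)
  expect_error(compute_voluntary(total, dup), "duplicate")
})

test_that("ledger identity holds on generated scenes", {
  sc <- generate_scene(small_scene_config(seed = 23))
  total <- true_cover_acres(sc)
  led <- compute_voluntary(total, sc$nrcs_ledger)
  expect_equal(led$total_acres, led$government_acres + led$voluntary_acres)
  expect_false(any(led$negative_voluntary))  # ledger never exceeds truth
})

test_that("trend summary reproduces the published fixture numbers", {
  pub <- published_acreage()
  tr <- adoption_trends(pub)
  expect_equal(tr$voluntary_change_acres, 703263 - 667655)
  expect_equal(tr$voluntary_change_acres, 35608)
  expect_equal(round(tr$voluntary_change_pct, 1), 5.3)
  expect_equal(tr$cumulative[["government"]], 402840)

  const <- data.frame(county_id = 1, year = 2013:2015, total_acres = 10,
                      government_acres = 4, voluntary_acres = 6)
  expect_equal(adoption_trends(const)$voluntary_change_pct, 0)

  zero <- const
  zero$voluntary_acres[zero$year == 2013] <- 0
  expect_error(adoption_trends(zero), "undefined percent")
  expect_error(adoption_trends(const[const$year == 2013, ]), "2 years")
})

test_that("funding correlation matches the closed-form oracle", {
  mk <- function(g, v) {
    data.frame(county_id = seq_along(g), year = 2013, total_acres = g + v,
               government_acres = g, voluntary_acres = v)
  }
  expect_equal(funding_correlation(mk(1:5, 2 * (1:5)))$r, 1)
  expect_equal(funding_correlation(mk(1:5, -(1:5)))$r, -1)

  g <- c(3, 7, 2, 9, 5)
  v <- c(10, 14, 8, 13, 12)
  got <- funding_correlation(mk(g, v))
  # hand-computed covariance formula
  r_manual <- sum((g - mean(g)) * (v - mean(v))) /
    sqrt(sum((g - mean(g))^2) * sum((v - mean(v))^2))
  expect_equal(got$r, r_manual)
  ct <- cor.test(g, v)
  expect_equal(got$p, ct$p.value)
  expect_equal(got$n, 5)

  expect_error(funding_correlation(mk(c(1, 2), c(2, 1))), "at least 3")
  expect_error(funding_correlation(mk(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")
})
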