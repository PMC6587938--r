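square <- tibble::tibble(easting = c(0, 1, 1, 0), northing = c(0, 0, 1, 1))

test_that("polygon area and point-in-polygon basics", {
  expect_equal(polygon_area(square), 1)
  expect_true(point_in_polygon(0.5, 0.5, square))
  expect_false(point_in_polygon(1.5, 0.5, square))
  # concave polygon: notch excluded
  notch <- tibble::tibble(easting = c(0, 4, 4, 2, 2, 0),
                          northing = c(0, 0, 3, 3, 1, 1))
  expect_true(point_in_polygon(1, 0.5, notch))
  expect_false(point_in_polygon(1, 2, notch))
  expect_equal(polygon_area(notch), 4 * 3 - 2 * 2)
})

test_that("prediction grid tiles the polygon", {
  g <- build_prediction_grid(square, pixel_area = 0.25)
  expect_equal(nrow(g), 4L)
  expect_true(all(point_in_polygon(g$easting, g$northing, square)))
  # kept cells never exceed the bounding-box capacity
  poly <- tibble::tibble(easting = c(0, 10, 5), northing = c(0, 0, 8))
  g2 <- build_prediction_grid(poly, pixel_area = 1)
  expect_lte(nrow(g2) * 1, 10 * 8)
  expect_equal(attr(g2, "n_cells_estimate"), round(polygon_area(poly) / 1))
  degenerate <- tibble::tibble(easting = c(0, 1, 2), northing = c(0, 1, 2))
  expect_error(build_prediction_grid(degenerate, 1), "degenerate")
})

test_that("kriging is exact at data points when the nugget is zero", {
  s <- withr::with_seed(1, tibble::tibble(easting = runif(8, 0, 100),
                                          northing = runif(8, 0, 100),
                                          z = rnorm(8)))
  m <- variogram_model("spherical", nugget = 0, psill = 2, range = 50)
  kr <- ordinary_kriging(s, "z", m, s[, c("easting", "northing")])
  expect_equal(kr$prediction, s$z, tolerance = 1e-8)
  expect_true(all(kr$variance < 1e-8))
})

test_that("kriging weights always sum to one", {
  s <- withr::with_seed(2, tibble::tibble(easting = runif(10, 0, 100),
                                          northing = runif(10, 0, 100),
                                          z = rnorm(10)))
  targets <- withr::with_seed(3, tibble::tibble(easting = runif(200, -20, 120),
                                                northing = runif(200, -20, 120)))
  for (fam in c("spherical", "exponential", "periodic")) {
    m <- variogram_model(fam, nugget = 0.4, psill = 1.1, range = 35)
    kr <- ordinary_kriging(s, "z", m, targets, keep_weights = TRUE)
    expect_true(all(abs(rowSums(attr(kr, "weights")) - 1) < 1e-8))
    expect_true(all(kr$variance >= 0))
  }
})

test_that("pure-nugget kriging is the sample mean with equal weights", {
  s <- withr::with_seed(4, tibble::tibble(easting = runif(7, 0, 50),
                                          northing = runif(7, 0, 50),
                                          z = rnorm(7)))
  m <- variogram_model("nugget", nugget = 1.3, psill = 0, range = 1)
  kr <- ordinary_kriging(s, "z", m, tibble::tibble(easting = 25, northing = 25),
                         keep_weights = TRUE)
  expect_equal(unname(attr(kr, "weights")[1, ]), rep(1 / 7, 7), tolerance = 1e-10)
  expect_equal(kr$prediction, mean(s$z), tolerance = 1e-10)
  expect_true(kr$prediction >= min(s$z) && kr$prediction <= max(s$z))
})

test_that("kriging agrees with an independent naive solver", {
  m <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 30)
  s <- transect_1d(c(0, 20, 55), z = c(1.0, 2.5, 0.3))
  target <- c(30, 0)
  kr <- ordinary_kriging(s, "z", m,
                         tibble::tibble(easting = 30, northing = 0),
                         keep_weights = TRUE)
  ref <- naive_ok(as.matrix(s[, c("easting", "northing")]), s$z, m, target)
  expect_equal(kr$prediction, ref$pred, tolerance = 1e-10)
  expect_equal(kr$variance, ref$var, tolerance = 1e-10)
  expect_equal(unname(attr(kr, "weights")[1, ]), ref$w, tolerance = 1e-10)
})

test_that("duplicate locations: identical values deduplicated, conflicts fatal", {
  m <- variogram_model("spherical", nugget = 0, psill = 1, range = 10)
  s <- tibble::tibble(easting = c(0, 0, 5), northing = 0, z = c(1, 1, 2))
  expect_warning(
    kr <- ordinary_kriging(s, "z", m, tibble::tibble(easting = 2, northing = 0)),
    "duplicate")
  expect_true(is.finite(kr$prediction))
  s2 <- tibble::tibble(easting = c(0, 0, 5), northing = 0, z = c(1, 9, 2))
  expect_error(suppressWarnings(
    ordinary_kriging(s2, "z", m, tibble::tibble(easting = 2, northing = 0))),
    "singular")
})

test_that("nearest sample dominates the weights on a transect", {
  s <- transect_1d(seq(0, 120, by = 15), z = rnorm(9))
  m <- variogram_model("exponential", nugget = 0.05, psill = 1, range = 40)
  kr <- ordinary_kriging(s, "z", m, tibble::tibble(easting = 16, northing = 0),
                         keep_weights = TRUE)
  w <- abs(attr(kr, "weights")[1, ])
  expect_equal(unname(which.max(w)), 2L) # the sample at 15 m
})

test_that("LOO cross-validation error metrics follow their formulas", {
  # toy vectors: Z = (1,2,3) vs Z' = (2,2,2) -> RMSE = sqrt(2/3)
  z <- c(1, 2, 3); zp <- c(2, 2, 2)
  expect_equal(sqrt(mean((z - zp)^2)), sqrt(2 / 3))
  s <- withr::with_seed(5, tibble::tibble(easting = runif(9, 0, 90),
                                          northing = runif(9, 0, 90),
                                          z = rnorm(9)))
  m <- variogram_model("nugget", nugget = 1, psill = 0, range = 1)
  cv <- loo_cross_validation(s, "z", m)
  # pure nugget: each LOO estimate is the mean of the other observations
  loo_means <- vapply(1:9, function(j) mean(s$z[-j]), numeric(1))
  expect_equal(cv$estimated, loo_means, tolerance = 1e-10)
  g <- glance(cv)
  expect_equal(g$RMSE, sqrt(mean((s$z - loo_means)^2)), tolerance = 1e-12)
  expect_equal(g$ASE, sqrt(mean((loo_means - mean(loo_means))^2)),
               tolerance = 1e-12)
  expect_equal(g$RMSE_r, g$RMSE / sd(s$z), tolerance = 1e-12)
  expect_equal(g$n, 9L)
})

test_that("LOO reproduces a smooth field almost perfectly", {
  s <- transect_1d(seq(0, 100, by = 5))
  s$z <- 2 + 0.05 * s$easting # linear field
  m <- variogram_model("gaussian", nugget = 0, psill = 1, range = 80)
  cv <- loo_cross_validation(s, "z", m)
  expect_lt(attr(cv, "RMSE"), 1e-4 * sd(s$z))
  expect_lt(attr(cv, "RMSE_r"), 1e-4)
})

test_that("accuracy flags apply the similarity and 40% rules", {
  fake_cv <- function(ase, rmse, rr) {
    structure(tibble::tibble(), class = c("cv_report", "tbl_df", "tbl", "data.frame"),
              ASE = ase, RMSE = rmse, RMSE_r = rr, S_z = 1, N = 13)
  }
  f <- prediction_accuracy_flag(fake_cv(1, 1, 0.38))
  expect_true(f$ase_rmse_similar)
  expect_true(f$rmse_r_accurate)
  # the water-content case: RMSE_r = 1.108 is not an accurate prediction
  expect_false(prediction_accuracy_flag(fake_cv(1, 1, 1.108))$rmse_r_accurate)
  expect_false(prediction_accuracy_flag(fake_cv(1, 2, 0.3))$ase_rmse_similar)
})
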