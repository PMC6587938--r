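test_that("pairwise distances are planar Euclidean and well-formed", {
  s <- tibble::tibble(sample_id = c("a", "b"), easting = c(0, 3), northing = c(0, 4))
  d <- pairwise_distances(s)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_warning(
    d2 <- pairwise_distances(tibble::tibble(easting = c(1, 1, 2), northing = c(1, 1, 0))),
    "duplicate")
  expect_true(attr(d2, "has_duplicates"))
  # symmetry and triangle inequality on random points
  pts <- withr::with_seed(1, tibble::tibble(easting = runif(13, 0, 200),
                                            northing = runif(13, 0, 50)))
  D <- pairwise_distances(pts)
  expect_equal(D, t(D))
  for (i in 1:13) for (j in 1:13) for (k in 1:13) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("empirical semivariogram reproduces direct evaluation", {
  # 1-D points 0,1,2 with z = 0,1,0: gamma(1) = 0.5 (two pairs), gamma(2) = 0
  s <- transect_1d(c(0, 1, 2), z = c(0, 1, 0))
  emp <- empirical_variogram(s, "z", n_bins = 2, max_lag = 2)
  expect_equal(emp$gamma, c(0.5, 0))
  expect_equal(emp$np, c(2L, 1L))
  # constant field -> all-zero semivariances
  s2 <- transect_1d(seq(0, 100, 10), z = rep(3.3, 11))
  expect_true(all(empirical_variogram(s2, "z")$gamma == 0))
  expect_error(empirical_variogram(s2[1, ], "z"), "at least 2")
})

test_that("binned semivariances are means of cloud values per bin", {
  s <- withr::with_seed(5, tibble::tibble(easting = runif(25, 0, 100),
                                          northing = runif(25, 0, 100),
                                          z = rnorm(25)))
  emp <- empirical_variogram(s, "z", n_bins = 6)
  cloud <- variogram_cloud(emp)
  breaks <- seq(0, attr(emp, "max_lag"), length.out = 7)
  bin <- cut(cloud$h, breaks, include.lowest = TRUE, labels = FALSE)
  for (k in sort(unique(bin))) {
    expect_equal(emp$gamma[emp$h == (breaks[k] + breaks[k + 1]) / 2],
                 mean(cloud$gamma[bin == k]))
  }
  expect_equal(sum(emp$np), nrow(cloud))
})

test_that("semivariogram is shift invariant and scales quadratically", {
  s <- withr::with_seed(6, tibble::tibble(easting = runif(15, 0, 80),
                                          northing = 0, z = rnorm(15)))
  base <- empirical_variogram(s, "z")
  s$z2 <- s$z + 100
  s$z3 <- 3 * s$z
  expect_equal(empirical_variogram(s, "z2")$gamma, base$gamma)
  expect_equal(empirical_variogram(s, "z3")$gamma, 9 * base$gamma)
})

test_that("model curves hit their closed-form landmarks", {
  sph <- variogram_model("spherical", nugget = 0.2, psill = 1, range = 30)
  expect_equal(model_curve(sph, 30), 1.2)
  expect_equal(model_curve(sph, 100), 1.2) # beyond range: sill
  per <- variogram_model("periodic", nugget = 0.2, psill = 1, range = 30)
  expect_equal(model_curve(per, 30), 0.2) # one full period: back to nugget
  expect_equal(model_curve(per, 15), 2.2) # half period: hole-effect peak
  ex <- variogram_model("exponential", nugget = 0.2, psill = 1, range = 30)
  expect_equal(model_curve(ex, 30), 0.2 + (1 - exp(-3)))
  ga <- variogram_model("gaussian", nugget = 0.1, psill = 2, range = 30)
  expect_equal(model_curve(ga, 30), 0.1 + 2 * (1 - exp(-3)))
  # all families: exactly 0 at h = 0, non-negative on a lag grid
  h <- c(0, seq(0.5, 120, by = 0.5))
  for (fam in c("nugget", "spherical", "exponential", "gaussian", "periodic")) {
    m <- variogram_model(fam, nugget = 0.3, psill = 0.9, range = 40)
    g <- model_curve(m, h)
    expect_equal(g[1], 0)
    expect_true(all(g >= 0))
  }
})

test_that("fit recovers parameters exactly from noise-free bins", {
  pts <- withr::with_seed(1, tibble::tibble(easting = runif(40, 0, 200),
                                            northing = runif(40, 0, 200)))
  pts$z <- pts$easting # placeholder; gamma overwritten below
  for (fam in c("spherical", "exponential", "gaussian", "periodic")) {
    true <- variogram_model(fam, nugget = 0.3, psill = 1.2, range = 60)
    emp <- empirical_variogram(pts, "z", n_bins = 10, max_lag = 140)
    emp$gamma <- model_curve(true, emp$h)
    fit <- fit_variogram(emp, families = fam)
    expect_lt(abs(fit$nugget - 0.3) / 0.3, 0.01)
    expect_lt(abs(fit$psill - 1.2) / 1.2, 0.01)
    expect_lt(abs(fit$range - 60) / 60, 0.01)
  }
  # nugget family: flat bins recovered as the weighted mean level
  emp <- empirical_variogram(pts, "z", n_bins = 10, max_lag = 140)
  emp$gamma <- rep(0.7, nrow(emp))
  fit <- fit_variogram(emp, families = "nugget")
  expect_equal(fit$nugget, 0.7, tolerance = 1e-9)
})

test_that("flat semivariograms classify as low spatial dependence", {
  pts <- withr::with_seed(2, tibble::tibble(easting = runif(30, 0, 100),
                                            northing = runif(30, 0, 100),
                                            z = rnorm(30)))
  emp <- empirical_variogram(pts, "z", n_bins = 8)
  emp$gamma <- rep(1, nrow(emp)) # pure nugget shape
  fit <- fit_variogram(emp)
  expect_lt(fit$psill, 0.05 * fit$nugget)
  expect_equal(spatial_dependence_class(fit), "low")
})

test_that("nugget/sill classes follow the 0.25/0.75 cuts", {
  mk <- function(r) variogram_model("spherical", nugget = r, psill = 1 - r, range = 10)
  expect_equal(spatial_dependence_class(mk(0.10)), "high")
  expect_equal(spatial_dependence_class(mk(0.50)), "medium")
  expect_equal(spatial_dependence_class(mk(0.80)), "low")
  expect_equal(spatial_dependence_class(mk(0.25)), "medium")
  expect_equal(spatial_dependence_class(mk(0.75)), "medium")
  degenerate <- variogram_model("spherical", nugget = 0, psill = 1, range = 10)
  degenerate$psill <- 0
  expect_error(spatial_dependence_class(degenerate), "no spatial variance")
})

test_that("Mantel correlogram sees a monotone gradient's sign pattern", {
  s <- transect_1d(seq(0, 120, by = 10))
  mc <- mantel_correlogram(s$easting, s, n_classes = 4, n_perm = 199, seed = 1)
  expect_gt(mc$statistic[1], 0)
  expect_lt(mc$statistic[nrow(mc)], 0)
  expect_true(all(abs(mc$statistic) <= 1))
  expect_true(all(mc$p_value >= 1 / 200 & mc$p_value <= 1))
  # deterministic given seed
  mc2 <- mantel_correlogram(s$easting, s, n_classes = 4, n_perm = 199, seed = 1)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("Mantel statistics match vegan::mantel.correlog on shared breaks", {
  s <- withr::with_seed(7, tibble::tibble(easting = runif(14, 0, 100),
                                          northing = runif(14, 0, 100),
                                          z = rnorm(14)))
  mc <- mantel_correlogram(s$z, s, n_classes = 4, n_perm = 99, seed = 1)
  brk <- c(mc$lower[1], mc$upper)
  vm <- vegan::mantel.correlog(dist(s$z),
                               XY = as.matrix(s[, c("easting", "northing")]),
                               break.pts = brk, nperm = 9, mult = "none",
                               cutoff = FALSE)
  expect_equal(mc$statistic, unname(vm$mantel.res[, "Mantel.cor"]),
               tolerance = 1e-10)
})

test_that("Monte-Carlo permutation p matches the exhaustive p on 5 samples", {
  s <- transect_1d(c(0, 10, 25, 60, 100), z = c(0.2, 0.7, 1.8, 4.1, 9.0))
  mc <- mantel_correlogram(s$z, s, n_classes = 2, n_perm = 999, seed = 3)
  # exhaustive: all 120 relabelings of the 5 samples
  D <- abs(outer(s$z, s$z, "-"))
  geo <- pairwise_distances(s)
  low <- which(lower.tri(geo), arr.ind = TRUE)
  brk <- c(mc$lower[1], mc$upper)
  cls <- cut(geo[low], brk, include.lowest = TRUE, labels = FALSE)
  stat <- function(dv, k) {
    ind <- as.numeric(cls == k)
    -cor(dv, ind)
  }
  for (k in seq_len(nrow(mc))) {
    obs <- stat(D[low], k)
    perm_stats <- vapply(all_perms(5), function(p) {
      stat(D[cbind(p[low[, 1]], p[low[, 2]])], k)
    }, numeric(1))
    p_exact <- mean(abs(perm_stats) >= abs(obs) - 1e-12)
    expect_lt(abs(mc$p_value[k] - p_exact), 0.05)
  }
})
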