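test_that("mortality model maps dNPV to percent with floor and cap", {
  m <- mortality_model()
  expect_equal(mortality_from_dnpv(0.16, m), 13.1952)
  expect_equal(mortality_from_dnpv(0.02, m), 0)
  expect_equal(mortality_from_dnpv(0.5, m), 48.29)
  expect_equal(mortality_from_dnpv(2, m), 100)  # capped
  # nondecreasing, zero below the floor, elementwise on rasters
  x <- seq(-0.2, 1, by = 0.001)
  y <- mortality_from_dnpv(x, m)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y[x < m$zero_floor] == 0))
  r <- bd_raster(matrix(c(0.02, 0.16, 0.5, 1), 2, 2))
  expect_equal(mortality_from_dnpv(r, m)$values,
               matrix(c(0, 13.1952, 48.29, 99.9), 2, 2))
  expect_error(mortality_from_dnpv(Inf, m), "finite")
})

test_that("model zero root solves slope*x + intercept = 0", {
  expect_equal(round(model_zero_root(mortality_model()), 3), 0.032)
  expect_equal(model_zero_root(mortality_model(100, -5, 0.05)), 0.05)
  expect_equal(model_zero_root(mortality_model(1, 0, 0)), 0)
  expect_error(mortality_model(0, -3), "slope")
})

test_that("grid refinement replicates values and preserves the mean", {
  r <- bd_raster(matrix(0.4, 1, 1))
  f <- refine_grid(r, 10)
  expect_equal(dim(f$values), c(10, 10))
  expect_true(all(f$values == 0.4))
  r2 <- bd_raster(matrix(runif(36), 6, 6))
  expect_equal(mean(refine_grid(r2, 3)$values), mean(r2$values))
  expect_identical(refine_grid(r2, 1), r2)
  expect_error(refine_grid(r2, 2.5), "integer")
})

test_that("area-weighted sub-plot dNPV handles containment and straddling", {
  r <- bd_raster(matrix(c(0.2, 0.4), 1, 2))  # two 30 m pixels side by side
  inside <- list(xmin = 2, xmax = 27, ymin = 10, ymax = 20)
  expect_equal(subplot_weighted_dnpv(bd_raster(matrix(0.3, 1, 1)),
                                     inside), 0.3)
  straddle <- list(xmin = 15, xmax = 45, ymin = 9, ymax = 21)
  expect_equal(subplot_weighted_dnpv(r, straddle), 0.3)
  expect_error(subplot_weighted_dnpv(r, list(xmin = 100, xmax = 101,
                                             ymin = 0, ymax = 1)))
})

test_that("grid-snapped polygons match the exact geometric oracle", {
  set.seed(9)
  r <- bd_raster(matrix(runif(64), 8, 8))
  for (i in 1:20) {
    # corners snapped to the 3 m refined grid
    x <- sort(sample(seq(0, 240, by = 3), 2))
    y <- sort(sample(seq(0, 240, by = 3), 2))
    if (diff(x) == 0 || diff(y) == 0) next
    sp <- list(xmin = x[1], xmax = x[2], ymin = y[1], ymax = y[2])
    expect_equal(subplot_weighted_dnpv(r, sp),
                 rect_weighted_oracle(r, x[1], x[2], y[1], y[2]),
                 tolerance = 1e-12)
  }
  # arbitrary rectangles agree within the 3 m discretisation bound
  for (i in 1:10) {
    x <- sort(runif(2, 0, 240)); y <- sort(runif(2, 0, 240))
    if (diff(x) < 10 || diff(y) < 10) next
    sp <- list(xmin = x[1], xmax = x[2], ymin = y[1], ymax = y[2])
    got <- subplot_weighted_dnpv(r, sp)
    want <- rect_weighted_oracle(r, x[1], x[2], y[1], y[2])
    expect_lt(abs(got - want), 0.15)
    expect_gte(got, min(r$values)); expect_lte(got, max(r$values))
  }
})

test_that("sub-plot mortality composes weighting with the model", {
  u <- function(v) bd_raster(matrix(v, 3, 3))
  sp <- list(xmin = 30, xmax = 60, ymin = 30, ymax = 60)
  expect_equal(subplot_mortality(u(0.16), sp), 13.1952)
  expect_equal(subplot_mortality(u(0), sp), 0)
  expect_equal(subplot_mortality(u(0.696), sp), 68.52112, tolerance = 1e-6)
})

test_that("neighboring mortality averages the 8 adjacent pixels, centre excluded", {
  v <- matrix(0.2, 3, 3); v[2, 2] <- 0.9
  r <- bd_raster(v)
  centre <- list(xmin = 35, xmax = 55, ymin = 35, ymax = 55)
  expect_equal(neighboring_mortality(r, centre), 17.324)
  u <- bd_raster(matrix(0.3, 5, 5))
  expect_equal(neighboring_mortality(u, centre),
               mortality_from_dnpv(0.3))
  # corner pixel: only the 3 existing neighbours enter the mean
  w <- bd_raster(matrix(c(0.9, 0.1, 0.2, 0.3), 2, 2))  # corner at [1,1]
  corner <- list(xmin = 1, xmax = 29, ymin = 31, ymax = 59)
  got <- neighboring_mortality(w, corner)
  expect_equal(got, mortality_from_dnpv(mean(c(0.2, 0.1, 0.3))))
  expect_error(neighboring_mortality(u, list(xmin = 900, xmax = 910,
                                             ymin = 0, ymax = 10)))
})

test_that("gap labelling finds connected super-threshold components", {
  v <- matrix(0, 5, 5)
  v[2, 2] <- 0.3; v[2, 3] <- 0.2; v[3, 2] <- 0.25  # three contiguous
  gm <- label_gaps(bd_raster(v), threshold = 0.16)
  expect_equal(nrow(gm$gaps), 1)
  expect_equal(gm$gaps$area_m2, 2700)
  expect_equal(label_gaps(bd_raster(matrix(0, 4, 4)))$gaps,
               tibble::tibble(gap_id = integer(), n_pixels = integer(),
                              area_m2 = numeric(), area_ha = numeric()))
  # diagonal-only adjacency: one gap at 8-connectivity, two at 4
  d <- matrix(0, 4, 4); d[2, 2] <- 0.5; d[3, 3] <- 0.5
  expect_equal(label_gaps(bd_raster(d), connectivity = 8)$gaps$area_m2,
               1800)
  expect_equal(label_gaps(bd_raster(d), connectivity = 4)$gaps$area_m2,
               c(900, 900))
})

test_that("gap areas partition the super-threshold pixel count", {
  set.seed(5)
  r <- bd_raster(matrix(runif(400, 0, 0.4), 20, 20))
  gm <- label_gaps(r, threshold = 0.16)
  expect_true(all(gm$gaps$area_m2 %% 900 == 0))
  expect_equal(sum(gm$gaps$n_pixels), sum(r$values >= 0.16))
  expect_true(all(r$values[gm$labels$values > 0] >= 0.16))
})

test_that("gap size for a sub-plot reads the centroid's component", {
  v <- matrix(0, 5, 5)
  v[2, 2] <- 0.3; v[2, 3] <- 0.2; v[3, 2] <- 0.25
  gm <- label_gaps(bd_raster(v))
  # centroid inside pixel (row 2, col 2): x in [30,60), y in [90,120)
  inside <- list(xmin = 35, xmax = 55, ymin = 95, ymax = 115)
  expect_equal(gap_size_for_subplot(gm, inside), 0.27)
  background <- list(xmin = 125, xmax = 145, ymin = 5, ymax = 25)
  expect_equal(gap_size_for_subplot(gm, background), 0)
  empty <- label_gaps(bd_raster(matrix(0, 5, 5)))
  expect_equal(gap_size_for_subplot(empty, inside), 0)
})

test_that("low/high classification assigns the boundary to low", {
  expect_equal(classify_disturbance(c(0.15, 0.17, 0.16)),
               c("low", "high", "low"))
})

test_that("disturbance_summary assembles all per-plot metrics", {
  w <- tiny_world(seed = 7, n = 30, count = 10)
  ds <- disturbance_summary(w$subplots, w$dnpv)
  expect_named(ds, c(names(w$subplots), "dnpv_w", "sp_mortality_pct",
                     "ng_mortality_pct", "gap_ha", "disturbance_class"))
  expect_true(all(ds$sp_mortality_pct >= 0 & ds$sp_mortality_pct <= 100))
  expect_true(all(ds$gap_ha >= 0))
  expect_equal(ds$disturbance_class, classify_disturbance(ds$dnpv_w))
})
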