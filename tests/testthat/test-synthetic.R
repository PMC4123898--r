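test_that("parameter constructors validate their invariants", {
  expect_error(landscape_params(nrows = 2), ">= 3")
  expect_error(landscape_params(noise_sd = -1))
  expect_error(landscape_params(severity_by_class = c(plateau = 1.2,
                                                      slope = 0.3,
                                                      valley = 0)),
               "\\[0, 1\\]")
  expect_error(community_params(baseline_density = -5))
  expect_error(community_params(species_pool = default_species_pool()[0, ]),
               "empty")
})

test_that("a flat clay field above 80 m classifies entirely as plateau", {
  lp <- landscape_params(nrows = 10, ncols = 10, patch_count = 0,
                         flat_altitude = 100)
  topo <- generate_topography(lp)
  expect_true(all(topo$class$values == 1L))
  expect_true(all(topo$slope_deg$values == 0))
})

test_that("synthetic altitude stays in the 40-180 m range and is seeded", {
  lp <- landscape_params(seed = 21)
  t1 <- generate_topography(lp)
  expect_gte(min(t1$altitude$values), 40)
  expect_lte(max(t1$altitude$values), 180)
  t2 <- generate_topography(lp)
  expect_identical(t1$altitude$values, t2$altitude$values)
  expect_identical(t1$class$values, t2$class$values)
  t3 <- generate_topography(landscape_params(seed = 22))
  expect_false(identical(t1$altitude$values, t3$altitude$values))
})

test_that("true mortality respects the 0-70% range and class ordering", {
  lp <- landscape_params(nrows = 100, ncols = 100,
                         severity_by_class = c(plateau = 0.4, slope = 0.3,
                                               valley = 0.05),
                         patch_count = 12, seed = 5)
  topo <- generate_topography(lp)
  m <- generate_true_mortality(topo, lp)
  expect_gte(min(m$values), 0)
  expect_lte(max(m$values), 0.70)
  means <- tapply(as.vector(m$values),
                  topo_levels[as.vector(topo$class$values)], mean)
  expect_gt(means["plateau"], means["slope"])
  expect_gt(means["slope"], means["valley"])
  zero <- generate_true_mortality(
    topo, landscape_params(severity_by_class = c(plateau = 0, slope = 0,
                                                 valley = 0), seed = 5))
  expect_true(all(zero$values == 0))
})

test_that("scene synthesis inverts the mortality model exactly", {
  model <- mortality_model()
  # zero mortality everywhere: recovered dNPV sits at the model root
  z <- bd_raster(matrix(0, 4, 4))
  sc <- synthesize_scene_pair(z, noise_sd = 0)
  d <- delta_npv(shade_normalize(unmix_scene(sc$pre)),
                 shade_normalize(unmix_scene(sc$post)))
  expect_equal(max(abs(d$values - 3.32 / 103.22)), 0, tolerance = 1e-6)
  # the recovered dNPV sits within numerical noise of the exact root, so
  # predicted mortality is (essentially) zero everywhere
  expect_lt(max(mortality_from_dnpv(d, model)$values), 1e-3)
  # the ~13% mortality pixel maps to dNPV 0.16
  v <- matrix(0, 2, 2); v[1, 1] <- 0.131952
  sc2 <- synthesize_scene_pair(bd_raster(v), noise_sd = 0)
  d2 <- delta_npv(shade_normalize(unmix_scene(sc2$pre)),
                  shade_normalize(unmix_scene(sc2$post)))
  expect_equal(d2$values[1, 1], 0.16, tolerance = 1e-6)
  # determinism and error paths
  n1 <- synthesize_scene_pair(z, noise_sd = 0.02, seed = 4)
  n2 <- synthesize_scene_pair(z, noise_sd = 0.02, seed = 4)
  expect_identical(n1$pre$bands, n2$pre$bands)
  expect_identical(n1$post$bands, n2$post$bands)
  expect_error(synthesize_scene_pair(z, noise_sd = -0.1), "nonnegative")
  expect_error(synthesize_scene_pair(bd_raster(matrix(0.9, 2, 2)),
                                     base_npv_n = 0.5), "NPV")
})

test_that("sub-plot layout reproduces the sampling frame arithmetic", {
  lp <- landscape_params(nrows = 60, ncols = 60, seed = 2)
  topo <- generate_topography(lp)
  sp <- generate_subplots(topo, count = 144, width = 25, height = 10)
  expect_equal(sum(sp$area_m2), 36000)      # 3.6 ha
  expect_equal(anyDuplicated(sp$subplot_id), 0)
  expect_true(all(sp$topo_class %in% topo_levels))
  one <- generate_subplots(topo, count = 1)
  expect_equal(one$area_m2, 250)
  expect_equal(nrow(generate_subplots(topo, count = 0)), 0)
  expect_error(generate_subplots(topo, count = 1e6), "holds only")
})

test_that("stem tables hit the expected density, DBH floor and determinism", {
  lp <- landscape_params(nrows = 40, ncols = 40, patch_count = 0,
                         flat_altitude = 100, seed = 8)
  topo <- generate_topography(lp)
  sp <- generate_subplots(topo, count = 200)
  sp$true_mortality <- 0
  cp <- community_params(baseline_density = 600)
  cen <- generate_stem_table(sp, cp, seed = 31)
  live_n <- table(factor(cen$stems$subplot_id[cen$stems$status == "live"],
                         levels = sp$subplot_id))
  # Poisson mean 600 * 0.025 = 15 live stems per plot at zero mortality
  expect_equal(mean(live_n), 15, tolerance = 0.05)
  expect_true(all(cen$stems$dbh_cm >= 10))
  expect_true(all(cen$stems$status %in% c("live", "dead")))
  expect_true(all((cen$stems$mode_of_death == "none") ==
                    (cen$stems$status == "live")))
  cen2 <- generate_stem_table(sp, cp, seed = 31)
  expect_identical(cen$stems, cen2$stems)
  expect_error(generate_stem_table(dplyr::mutate(sp, true_mortality = 2),
                                   cp), "\\[0, 1\\]")
})

test_that("pioneer wood density sits strictly below the pool median", {
  pool <- default_species_pool()
  expect_true(all(pool$wood_density[pool$pioneer] <
                    stats::median(pool$wood_density)))
  expect_true(all(pool$wood_density > 0))
  expect_setequal(unique(pool$genus[pool$pioneer]),
                  default_pioneer_genera())
  expect_equal(nrow(pool), 60)
  expect_equal(length(unique(pool$genus)), 25)
})

test_that("zero pioneer gain yields a flat pioneer-fraction response", {
  lp <- landscape_params(nrows = 50, ncols = 50, seed = 12)
  topo <- generate_topography(lp)
  sp <- generate_subplots(topo, count = 250)
  set.seed(77)
  sp$true_mortality <- runif(nrow(sp), 0, 0.7)
  cen <- generate_stem_table(sp, community_params(pioneer_gain = 0),
                             seed = 55)
  pf <- cen$stems |>
    dplyr::filter(.data$status == "live") |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(frac = mean(.data$genus %in%
                                   default_pioneer_genera())) |>
    dplyr::left_join(sp[, c("subplot_id", "true_mortality")],
                     by = "subplot_id")
  fit <- simple_ols(pf$frac, pf$true_mortality)
  expect_gt(fit$p_value, 0.01)   # no detectable trend under the null
})

test_that("the simulation bundle is reproducible end to end", {
  lp <- landscape_params(nrows = 30, ncols = 30, seed = 19,
                         noise_sd = 0.005)
  b1 <- simulate_blowdown(lp, subplot_count = 12)
  b2 <- simulate_blowdown(lp, subplot_count = 12)
  expect_identical(b1$stems, b2$stems)
  expect_identical(b1$scenes$post$bands, b2$scenes$post$bands)
  expect_identical(b1$subplots, b2$subplots)
})
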