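test_that("community matrices tabulate live stems per sub-plot and taxon", {
  stems <- make_stems(
    c("Eschweilera sp01", "Eschweilera sp01", "Eschweilera sp01",
      "Eschweilera sp02", "Cecropia sp01"),
    c(15, 20, 25, 30, 12),
    subplot = c("a", "a", "a", "a", "b"))
  cm <- build_matrix(stems)
  expect_equal(cm$counts["a", "Eschweilera sp01"], 3)
  expect_equal(rowSums(cm$counts), c(a = 4, b = 1))
  cg <- build_matrix(stems, level = "genus")
  expect_equal(cg$counts["a", "Eschweilera"], 4)
  expect_equal(sum(cm$basal), sum(basal_area_m2(stems$dbh_cm)))
  dead <- dplyr::mutate(stems, status = "dead")
  expect_error(build_matrix(dead), "live")
})

test_that("IVI components sum to 300 and respect symmetry", {
  single <- make_stems(rep("Goupia sp01", 5), rep(20, 5))
  expect_equal(ivi(build_matrix(single, "genus"))$ivi, 300)
  two <- make_stems(c("Goupia sp01", "Micrandra sp01"), c(20, 20),
                    subplot = c("a", "b"))
  expect_equal(ivi(build_matrix(two, "genus"))$ivi, c(150, 150))
  # random communities: total IVI is always 300
  set.seed(3)
  for (i in 1:5) {
    n <- 40
    stems <- make_stems(sample(default_species_pool()$species, n, TRUE),
                        runif(n, 10, 60),
                        subplot = sample(letters[1:6], n, TRUE))
    expect_equal(sum(ivi(build_matrix(stems, "genus"))$ivi), 300,
                 tolerance = 1e-9)
  }
})

test_that("Shannon diversity and richness follow the entropy formula", {
  expect_equal(shannon(c(5)), 0)
  expect_equal(shannon(rep(2, 4)), log(4))
  expect_equal(shannon(c(8, 1, 1)), 0.6390, tolerance = 1e-4)
  expect_equal(richness(c(2, 0, 1, 0)), 2)
  expect_error(shannon(c(0, 0)), "zero")
  # H <= log(S), equality only for uniform abundances
  set.seed(8)
  for (i in 1:20) {
    x <- rpois(10, 4) + 1
    expect_lte(shannon(x), log(richness(x)) + 1e-12)
  }
})

test_that("analytic rarefaction matches brute-force enumeration", {
  expect_equal(rarefy_expected(c(5, 3, 2), 2), 1.688889,
               tolerance = 1e-6)
  for (counts in list(c(5, 3, 2), c(4, 4, 2, 1), c(6, 3, 1, 1))) {
    N <- sum(counts)
    expect_equal(rarefy_expected(counts, 1), 1)
    expect_equal(rarefy_expected(counts, N), length(counts))
    for (n in c(2, 4, 7)) {
      expect_equal(rarefy_expected(counts, n), rarefy_brute(counts, n),
                   tolerance = 1e-12)
    }
  }
  expect_error(rarefy_expected(c(3, 2), 9), "\\[1, ")
})

test_that("rarefaction is nondecreasing, concave and bounded by richness", {
  counts <- c(12, 7, 5, 3, 2, 1, 1)
  n <- seq_len(sum(counts))
  e <- rarefy_expected(counts, n)
  expect_true(all(diff(e) > -1e-12))
  expect_true(all(diff(diff(e)) < 1e-12))
  expect_true(all(e <= length(counts) + 1e-12))
  # agreement with the vegan implementation
  expect_equal(e[c(5, 10, 20)],
               as.numeric(vegan::rarefy(counts, c(5, 10, 20))),
               tolerance = 1e-9)
})

test_that("mortality-ranked grouping keeps complete groups of five", {
  # the sampling frame: 44 plateau + 73 slope + 27 valley sub-plots
  frame <- tibble::tibble(
    subplot_id = sprintf("sp%03d", 1:144),
    topo_class = rep(c("plateau", "slope", "valley"), c(44, 73, 27)),
    sp_mortality_pct = c(seq(0, 60, length.out = 117), rep(1, 27))
  )
  g <- group_by_mortality_rank(frame)
  expect_equal(length(unique(g$group_id)), 23)
  expect_equal(nrow(g), 115)                      # 2 of 117 dropped
  expect_true(all(table(g$group_id) == 5))
  expect_true(all(g$topo_class %in% c("plateau", "slope")))
  # groups are ordered along the gradient
  mm <- tapply(g$group_mean_mortality, g$group_id, unique)
  expect_true(all(diff(mm) > 0))
  small <- group_by_mortality_rank(frame[1:10, ])
  expect_equal(length(unique(small$group_id)), 2)
  # ties broken by sub-plot id: grouping is deterministic
  tied <- dplyr::mutate(frame, sp_mortality_pct = 1)
  expect_identical(group_by_mortality_rank(tied),
                   group_by_mortality_rank(tied[sample(1:144), ]))
  expect_error(group_by_mortality_rank(frame[1:3, ]), "fewer")
})

test_that("Bray-Curtis dissimilarity matches its formula", {
  m <- rbind(a = c(2, 1, 0), b = c(0, 1, 2), c = c(2, 1, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 2 / 3, tolerance = 1e-9)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  disjoint <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  withempty <- rbind(c(1, 2), c(0, 0), c(0, 0))
  expect_warning(de <- as.matrix(bray_curtis(withempty)), "empty")
  expect_equal(de[1, 2], 1)
  expect_equal(de[2, 3], 0)
  expect_error(bray_curtis(m[1, , drop = FALSE]), "2 sub-plots")
})

test_that("NMDS re-embeds planar configurations with near-zero stress", {
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  fit <- suppressWarnings(nmds_ordination(d, n_starts = 10, seed = 6))
  expect_lt(fit$stress, 0.01)
  fit2 <- suppressWarnings(nmds_ordination(d, n_starts = 10, seed = 6))
  expect_identical(fit$scores, fit2$scores)
  expect_equal(colMeans(as.matrix(fit$scores[, -1])), c(NMDS1 = 0,
                                                        NMDS2 = 0),
               tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$n_points, 4)
  expect_equal(names(tidy(fit)), c("subplot_id", "NMDS1", "NMDS2"))
  bad <- matrix(runif(9), 3, 3)
  expect_error(nmds_ordination(bad), "symmetric")
})

test_that("the Mantel test recovers identity and matches vegan", {
  set.seed(4)
  d1 <- dist(matrix(rnorm(24), 12, 2))
  out <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p_value, 1 / 100)
  d2 <- dist(matrix(rnorm(24), 12, 2))
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 1)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.06)
  expect_error(mantel_test(d1, dist(matrix(rnorm(10), 5, 2))), "size")
  expect_error(mantel_test(d1, dist(rep(1, 12)) * 0), "variance")
})

test_that("simple OLS reports the regression statistics", {
  x <- 1:10
  fit <- suppressWarnings(simple_ols(2 * x, x))  # exact fit trips summary.lm
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  flat <- simple_ols(rep(5, 10), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  # parameter recovery at known noise
  set.seed(10)
  xs <- runif(200); ys <- 1.5 + 3 * xs + rnorm(200, 0, 0.2)
  rec <- simple_ols(ys, xs)
  expect_equal(rec$slope, 3, tolerance = 0.1)
  expect_equal(rec$intercept, 1.5, tolerance = 0.1)
  expect_equal(rec$pearson_r, cor(xs, ys))
  expect_error(simple_ols(c(1, 2), c(1, 2)), "at least 3")
  expect_error(simple_ols(1:5, rep(2, 5)), "variance")
})

test_that("genus response splines label disturbance guilds", {
  mort <- seq(0, 70, length.out = 23)
  flat <- genus_response_spline(rep(4, 23) + c(0.001, rep(0, 22)), mort,
                                "Flat")
  expect_equal(flat$guild, "resistant")
  inc <- genus_response_spline(seq(1, 30, length.out = 23), mort, "Inc")
  expect_equal(inc$guild, "high-specialist")
  expect_equal(inc$optimum_pct, 70)
  # unimodal response peaking at 35% mortality
  set.seed(14)
  y <- 10 * exp(-((mort - 35) / 12)^2) + rnorm(23, 0, 0.3)
  uni <- genus_response_spline(y, mort, "Uni")
  expect_lt(abs(uni$optimum_pct - 35), 10)
  expect_equal(uni$guild, "intermediate")
  expect_error(genus_response_spline(1:3, c(1, 2, 3), df = 3), "df")
})

test_that("diversity along the gradient uses pooled group abundances", {
  w <- tiny_world(seed = 7, n = 40, count = 60)
  ds <- disturbance_summary(w$subplots, w$dnpv)
  cen <- generate_stem_table(w$subplots, seed = 2)
  g <- group_by_mortality_rank(ds)
  div <- diversity_by_group(cen$stems, g)
  expect_equal(nrow(div), length(unique(g$group_id)))
  expect_true(all(div$richness >= 1))
  expect_true(all(div$shannon <= log(div$richness) + 1e-9))
  expect_true(all(div$rarefied_richness <= div$richness + 1e-9))
})
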