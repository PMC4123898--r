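#' Build a sub-plot by taxon community matrix
#'
#' Live-stem counts and, in parallel, summed basal areas per sub-plot and
#' taxon (species or genus level); these are the inputs for importance
#' values, diversity and ordination.
#'
#' @param stems Stem tibble; only live stems are tabulated.
#' @param level `"species"` or `"genus"`.
#' @param subplots Optional sub-plot tibble fixing row order (and keeping
#'   empty sub-plots as all-zero rows).
#' @return A `bd_community` list: integer matrix `counts` and numeric
#'   matrix `basal` (rows = sub-plots, columns = taxa), plus `level`.
#' @export
build_matrix <- function(stems, level = c("species", "genus"),
                         subplots = NULL) {
  level <- match.arg(level)
  live <- stems[stems$status == "live", ]
  if (nrow(live) == 0) stop("no live stems to tabulate")
  taxon <- live[[level]]
  ids <- if (is.null(subplots)) sort(unique(live$subplot_id)) else
    subplots$subplot_id
  taxa <- sort(unique(taxon))
  fi <- factor(live$subplot_id, levels = ids)
  fj <- factor(taxon, levels = taxa)
  counts <- as.matrix(table(fi, fj))
  ba <- tapply(basal_area_m2(live$dbh_cm), list(fi, fj), sum,
               default = 0)
  structure(list(counts = counts, basal = ba, level = level),
            class = "bd_community")
}

#' @export
print.bd_community <- function(x, ...) {
  cat(sprintf("<bd_community> %d sub-plots x %d %s-level taxa, %d stems\n",
              nrow(x$counts), ncol(x$counts), x$level, sum(x$counts)))
  invisible(x)
}

#' Importance Value Index
#'
#' Per taxon, the sum of relative density (stems), relative frequency
#' (number of sub-plots of occurrence) and relative dominance (basal
#' area), each expressed in percent; the index totals 300 over taxa.
#'
#' @param comm A `bd_community` from [build_matrix()].
#' @return Tibble ordered by decreasing IVI: `taxon`, `rel_density`,
#'   `rel_frequency`, `rel_dominance`, `ivi`.
#' @export
ivi <- function(comm) {
  stopifnot(inherits(comm, "bd_community"))
  n <- colSums(comm$counts)
  if (sum(n) == 0) stop("empty community")
  f <- colSums(comm$counts > 0)
  ba <- colSums(comm$basal)
  tibble::tibble(
    taxon = colnames(comm$counts),
    rel_density = unname(100 * n / sum(n)),
    rel_frequency = unname(100 * f / sum(f)),
    rel_dominance = unname(100 * ba / sum(ba)),
    ivi = .data$rel_density + .data$rel_frequency + .data$rel_dominance
  ) |>
    dplyr::arrange(dplyr::desc(.data$ivi))
}

#' Species richness and Shannon diversity
#'
#' `richness()` counts taxa with positive abundance; `shannon()` is
#' `-sum(p * log(p))` in natural-log units.
#'
#' @param counts Nonnegative abundance vector with at least one positive
#'   entry.
#' @return Scalar.
#' @export
richness <- function(counts) {
  if (all(counts == 0)) stop("all-zero abundance vector")
  sum(counts > 0)
}

#' @rdname richness
#' @export
shannon <- function(counts) {
  if (all(counts == 0)) stop("all-zero abundance vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Analytic (hypergeometric) rarefaction
#'
#' Expected number of species in a random subsample of `n` individuals
#' drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(N - n_i, n) / choose(N, n))`.
#' Computed on the log scale for numerical stability.
#'
#' @param counts Nonnegative integer abundances.
#' @param n Subsample size(s), each between 1 and `sum(counts)`.
#' @return Expected species count, vectorised over `n`.
#' @export
rarefy_expected <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(n < 1 | n > N)) stop("n must lie in [1, total count]")
  vapply(n, function(k) {
    lp <- lchoose(N - counts, k) - lchoose(N, k)
    lp[N - counts < k] <- -Inf
    sum(1 - exp(lp))
  }, numeric(1))
}

#' Group sub-plots by ranked mortality
#'
#' Restricts to the requested topographic classes (plateaus and slopes by
#' default: valleys are weakly disturbed and floristically distinct),
#' sorts sub-plots by sub-plot mortality (ties broken by id), and forms
#' consecutive complete groups of `group_size`; the remainder beyond the
#' last complete group is dropped. Pooling five plots at a time removes
#' the low-tree-count artefact of heavily disturbed single plots.
#'
#' @param summary Tibble with `subplot_id`, `topo_class` and the mortality
#'   column (a [disturbance_summary()] output).
#' @param group_size Plots per group (default 5).
#' @param classes Topographic classes retained.
#' @param mortality_col Column holding sub-plot mortality.
#' @return Tibble of retained sub-plots: `subplot_id`, mortality, `group_id`
#'   and the group's `group_mean_mortality`.
#' @export
group_by_mortality_rank <- function(summary, group_size = 5,
                                    classes = c("plateau", "slope"),
                                    mortality_col = "sp_mortality_pct") {
  keep <- summary[summary$topo_class %in% classes, ]
  if (nrow(keep) < group_size) {
    stop("fewer sub-plots (", nrow(keep), ") than one group of ",
         group_size)
  }
  ord <- order(keep[[mortality_col]], keep$subplot_id)
  keep <- keep[ord, ]
  n_groups <- nrow(keep) %/% group_size
  keep <- keep[seq_len(n_groups * group_size), ]
  keep$group_id <- rep(seq_len(n_groups), each = group_size)
  keep |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(group_mean_mortality =
                    mean(.data[[mortality_col]])) |>
    dplyr::ungroup() |>
    dplyr::select("subplot_id", "topo_class",
                  dplyr::all_of(mortality_col), "group_id",
                  "group_mean_mortality")
}

#' Diversity along the mortality gradient
#'
#' Pools live stems within each mortality-ranked group and computes
#' species richness, Shannon diversity and rarefied richness at a common
#' subsample size (the smallest group total by default).
#'
#' @param stems Stem tibble.
#' @param groups Output of [group_by_mortality_rank()].
#' @param rarefy_n Common rarefaction size; default is the smallest group
#'   stem total.
#' @return Tibble per group: `group_id`, `mean_mortality_pct`, `n_stems`,
#'   `richness`, `shannon`, `rarefied_richness`.
#' @export
diversity_by_group <- function(stems, groups, rarefy_n = NULL) {
  live <- stems[stems$status == "live", ]
  pooled <- live |>
    dplyr::inner_join(groups[, c("subplot_id", "group_id",
                                 "group_mean_mortality")],
                      by = "subplot_id") |>
    dplyr::count(.data$group_id, .data$group_mean_mortality,
                 .data$species)
  per_group <- split(pooled, pooled$group_id)
  if (is.null(rarefy_n)) {
    rarefy_n <- min(vapply(per_group, function(g) sum(g$n), numeric(1)))
  }
  purrr::map_dfr(per_group, function(g) {
    tibble::tibble(
      group_id = g$group_id[1],
      mean_mortality_pct = g$group_mean_mortality[1],
      n_stems = sum(g$n),
      richness = richness(g$n),
      shannon = shannon(g$n),
      rarefied_richness = rarefy_expected(g$n, min(rarefy_n, sum(g$n)))
    )
  })
}

#' Bray-Curtis dissimilarity between sub-plots
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` on raw counts
#' (computed with [vegan::vegdist()]). Empty rows have no defined
#' dissimilarity; they are set to 1 against non-empty rows (0 between two
#' empty rows) with a warning.
#'
#' @param comm A `bd_community` or a plain abundance matrix.
#' @return A `dist` object with values in `[0, 1]`.
#' @export
bray_curtis <- function(comm) {
  m <- if (inherits(comm, "bd_community")) comm$counts else as.matrix(comm)
  if (nrow(m) < 2) stop("need at least 2 sub-plots")
  empty <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (any(empty)) {
    warning(sum(empty), " empty sub-plot(s); their dissimilarities set ",
            "to 1 (0 between empty pairs)")
    dm <- as.matrix(d)
    dm[empty, ] <- 1; dm[, empty] <- 1
    dm[empty, empty] <- 0
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  d
}

#' Nonmetric multidimensional scaling of a community
#'
#' Kruskal NMDS (two axes by default) minimising stress-1 with monotone
#' regression on dissimilarity ranks, taking the best of `n_starts` random
#' starts ([vegan::metaMDS()] engine); seeded, so results are reproducible.
#'
#' @param d A `dist` of community dissimilarities (e.g. [bray_curtis()]).
#' @param k Number of axes (default 2).
#' @param n_starts Random starts (default 20).
#' @param seed Integer RNG seed.
#' @return A `bd_nmds`: `scores` tibble (`subplot_id`, `NMDS1`, ...),
#'   `stress` in `[0, 1]`, `seed`, `n_starts`, and the underlying
#'   `engine` fit.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = 1L) {
  dm <- as.matrix(d)
  if (!isTRUE(all.equal(dm, t(dm)))) stop("distance matrix not symmetric")
  fit <- with_local_seed(seed, {
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = n_starts,
                   trace = 0)
  })
  pts <- fit$points
  scores <- tibble::as_tibble(pts, .name_repair = "minimal")
  names(scores) <- paste0("NMDS", seq_len(ncol(pts)))
  scores <- dplyr::bind_cols(
    tibble::tibble(subplot_id = rownames(pts) %||%
                     as.character(seq_len(nrow(pts)))),
    scores
  )
  structure(list(scores = scores, stress = fit$stress, seed = seed,
                 n_starts = n_starts, engine = fit),
            class = "bd_nmds")
}

#' @export
print.bd_nmds <- function(x, ...) {
  cat(sprintf("<bd_nmds> %d points, %d axes, stress %.3f\n",
              nrow(x$scores), ncol(x$scores) - 1, x$stress))
  invisible(x)
}

#' @export
tidy.bd_nmds <- function(x, ...) x$scores

#' @export
glance.bd_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_points = nrow(x$scores),
                 n_axes = ncol(x$scores) - 1, n_starts = x$n_starts,
                 seed = x$seed)
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two distance matrices;
#' significance from random row/column permutations of the second matrix,
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects or square matrices of equal size.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed.
#' @return One-row tibble: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (sd(v1) == 0 || sd(m2[lt]) == 0) {
    stop("a distance matrix has zero variance")
  }
  r_obs <- cor(v1, m2[lt])
  r_perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(v1, m2[p, p][lt])
    }, numeric(1))
  })
  tibble::tibble(
    r = r_obs,
    p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    n_perm = n_perm
  )
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with the statistics the study
#' tables report (slope, intercept, r-squared, F, p, Pearson's r).
#'
#' @param y,x Numeric vectors, `n >= 3`; pairs with missing values are
#'   dropped.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `f_statistic`, `p_value`, `pearson_r`, `n`.
#' @export
simple_ols <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("x has zero variance")
  if (sd(y) == 0) {
    # a constant response carries no signal; report the null fit directly
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 0,
                          f_statistic = 0, p_value = 1, pearson_r = 0,
                          n = length(x)))
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  f <- s$fstatistic
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    f_statistic = unname(f[1]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    pearson_r = cor(x, y),
    n = length(x)
  )
}

#' Genus response curve along the mortality gradient
#'
#' Fits a cubic smoothing spline (3 effective degrees of freedom) of a
#' genus's pooled abundance on group mean mortality, evaluates it on a
#' half-percent grid over the observed mortality range (within 0-70%),
#' and labels the genus's disturbance guild from the curve optimum:
#' flat curves (range below 5% of the mean level) are `resistant`;
#' otherwise an optimum at <= 10% mortality is `low-specialist`,
#' 10-40% `intermediate`, 40-55% `high-favored`, above 55%
#' `high-specialist`.
#'
#' @param abundance Abundance per mortality-ranked group.
#' @param mortality Group mean sub-plot mortality, percent.
#' @param genus Genus label carried through.
#' @param df Effective degrees of freedom of the spline (default 3).
#' @return A `bd_guild_curve`: `genus`, `curve` tibble
#'   (`mortality_pct`, `fitted`), `optimum_pct`, `guild`.
#' @export
genus_response_spline <- function(abundance, mortality, genus = "genus",
                                  df = 3) {
  ok <- is.finite(abundance) & is.finite(mortality)
  x <- mortality[ok]; y <- abundance[ok]
  if (length(unique(x)) <= df) {
    stop("need more distinct mortality values than spline df")
  }
  fit <- smooth.spline(x, y, df = df)
  grid <- seq(max(0, min(x)), min(70, max(x)), by = 0.5)
  fitted <- predict(fit, grid)$y
  opt <- grid[which.max(fitted)]
  rng <- diff(range(fitted))
  lvl <- mean(abs(fitted))
  guild <- if (lvl > 0 && rng < 0.05 * lvl) "resistant"
  else if (opt <= 10) "low-specialist"
  else if (opt <= 40) "intermediate"
  else if (opt <= 55) "high-favored"
  else "high-specialist"
  structure(
    list(genus = genus,
         curve = tibble::tibble(mortality_pct = grid, fitted = fitted),
         optimum_pct = opt, guild = guild, df = df),
    class = "bd_guild_curve"
  )
}

#' @export
print.bd_guild_curve <- function(x, ...) {
  cat(sprintf("<bd_guild_curve> %s: optimum %.1f%% mortality (%s)\n",
              x$genus, x$optimum_pct, x$guild))
  invisible(x)
}

#' @export
tidy.bd_guild_curve <- function(x, ...) {
  dplyr::mutate(x$curve, genus = x$genus, .before = 1)
}

#' @export
glance.bd_guild_curve <- function(x, ...) {
  tibble::tibble(genus = x$genus, optimum_pct = x$optimum_pct,
                 guild = x$guild, df = x$df)
}

#' Guild curves for the most important genera
#'
#' Ranks genera by IVI, keeps the top `n_top` (25 by default), pools their
#' abundances within mortality-ranked groups and fits
#' [genus_response_spline()] to each.
#'
#' @param stems Stem tibble.
#' @param groups Output of [group_by_mortality_rank()].
#' @param n_top Number of top-IVI genera (default 25).
#' @param df Spline degrees of freedom.
#' @return List: `curves` (named list of `bd_guild_curve`) and `summary`
#'   tibble (`genus`, `ivi`, `optimum_pct`, `guild`).
#' @export
genus_guilds <- function(stems, groups, n_top = 25, df = 3) {
  live <- stems[stems$status == "live", ] |>
    dplyr::inner_join(groups[, c("subplot_id", "group_id",
                                 "group_mean_mortality")],
                      by = "subplot_id")
  comm <- build_matrix(live, level = "genus")
  ranks <- ivi(comm)
  top <- head(ranks$taxon, n_top)
  ab <- live |>
    dplyr::filter(.data$genus %in% top) |>
    dplyr::count(.data$genus, .data$group_id, .data$group_mean_mortality)
  grid <- tidyr::expand_grid(
    genus = top,
    dplyr::distinct(groups[, c("group_id", "group_mean_mortality")])
  ) |>
    dplyr::left_join(ab, by = c("genus", "group_id",
                                "group_mean_mortality")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  curves <- lapply(split(grid, grid$genus), function(g) {
    genus_response_spline(g$n, g$group_mean_mortality, g$genus[1], df)
  })
  summary <- purrr::map_dfr(curves, glance) |>
    dplyr::left_join(ranks[, c("taxon", "ivi")],
                     by = c(genus = "taxon")) |>
    dplyr::arrange(dplyr::desc(.data$ivi)) |>
    dplyr::select("genus", "ivi", "optimum_pct", "guild")
  list(curves = curves, summary = summary)
}
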