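#' Classify landscape position into plateau / slope / valley
#'
#' Field rules of the toposequence: plateaus are higher areas
#' (altitude above `plateau_altitude_min`) with gentle slopes (at most
#' `slope_angle_min` degrees) and clay soils; valleys are low, sandy and in
#' contact with perennial or intermittent streams; everything else is a
#' slope. The three rules are not mutually exclusive, so precedence is
#' valley, then plateau, then slope.
#'
#' @param altitude Altitude, m a.s.l. (vectorised).
#' @param slope_deg Terrain slope, degrees.
#' @param soil `"clay"`, `"mixed"` or `"sand"`.
#' @param stream_adjacent Logical, direct contact with a stream.
#' @param plateau_altitude_min Plateau altitude threshold, m (default 80).
#' @param slope_angle_min Plateau maximum slope, degrees (default 10).
#' @return Character vector of `"plateau"`, `"slope"`, `"valley"`.
#' @export
classify_topography <- function(altitude, slope_deg, soil, stream_adjacent,
                                plateau_altitude_min = 80,
                                slope_angle_min = 10) {
  stopifnot(all(is.finite(altitude)), all(is.finite(slope_deg)))
  out <- rep("slope", length(altitude))
  out[altitude > plateau_altitude_min & slope_deg <= slope_angle_min &
        soil == "clay"] <- "plateau"
  out[altitude <= plateau_altitude_min & soil == "sand" &
        stream_adjacent] <- "valley"
  out
}

#' Basal area of a stem
#'
#' @param dbh_cm DBH in cm.
#' @return Cross-sectional area at breast height, m2:
#'   `pi * (dbh / 200)^2`.
#' @export
basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Per-sub-plot forest structure metrics
#'
#' Tree density (trees per ha), basal area (m2 per ha), mean DBH and mean
#' wood density for the selected stems of each sub-plot. Sub-plots without
#' stems keep density and basal area 0 and missing means.
#'
#' @param stems Stem tibble (see [generate_stem_table()]).
#' @param subplots Sub-plot tibble with `subplot_id` and `area_m2`.
#' @param status Which stems to use: `"live"`, `"dead"` or `"all"`.
#' @return Tibble: `subplot_id`, `n_stems`, `density_ha`,
#'   `basal_area_m2ha`, `mean_dbh_cm`, `mean_wood_density`.
#' @export
structure_metrics <- function(stems, subplots,
                              status = c("live", "dead", "all")) {
  status <- match.arg(status)
  if (any(subplots$area_m2 <= 0)) stop("sub-plot areas must be positive")
  sel <- if (status == "all") stems else stems[stems$status == status, ]
  agg <- sel |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(
      n_stems = dplyr::n(),
      sum_ba = sum(basal_area_m2(.data$dbh_cm)),
      mean_dbh_cm = mean(.data$dbh_cm),
      mean_wood_density = if (all(is.na(.data$wood_density))) NA_real_
        else mean(.data$wood_density, na.rm = TRUE),
      .groups = "drop"
    )
  subplots[, c("subplot_id", "area_m2")] |>
    dplyr::left_join(agg, by = "subplot_id") |>
    dplyr::mutate(
      n_stems = dplyr::coalesce(.data$n_stems, 0L),
      sum_ba = dplyr::coalesce(.data$sum_ba, 0),
      density_ha = .data$n_stems / .data$area_m2 * 1e4,
      basal_area_m2ha = .data$sum_ba / .data$area_m2 * 1e4
    ) |>
    dplyr::select("subplot_id", "n_stems", "density_ha",
                  "basal_area_m2ha", "mean_dbh_cm", "mean_wood_density")
}

#' Assign wood density with taxonomic fallback
#'
#' Looks each stem up in a wood-density table at species level; species
#' not listed get the arithmetic mean of listed congeners, then of listed
#' confamilials, and finally the table-wide mean (so that plot means keep
#' all stems). The level used is recorded in `wd_level` and global
#' fallbacks raise a warning.
#'
#' @param stems Stem tibble with `species`, `genus`, `family`.
#' @param table Tibble with `species`, `genus`, `family`, `wood_density`
#'   (g cm-3), e.g. [default_species_pool()].
#' @return `stems` with columns `wood_density` (replaced) and `wd_level`
#'   (`"species"`, `"genus"`, `"family"` or `"global"`).
#' @export
assign_wood_density <- function(stems, table) {
  if (nrow(table) == 0) stop("wood-density table is empty")
  stopifnot(all(table$wood_density > 0))
  sp <- setNames(table$wood_density, table$species)
  gmean <- tapply(table$wood_density, table$genus, mean)
  fmean <- tapply(table$wood_density, table$family, mean)
  glob <- mean(table$wood_density)

  wd <- unname(sp[stems$species])
  lvl <- ifelse(is.na(wd), NA_character_, "species")
  need <- is.na(wd)
  wd[need] <- unname(gmean[stems$genus[need]])
  lvl[need & !is.na(wd)] <- "genus"
  need <- is.na(wd)
  wd[need] <- unname(fmean[stems$family[need]])
  lvl[need & !is.na(wd)] <- "family"
  need <- is.na(wd)
  if (any(need)) {
    warning(sum(need), " stem(s) fell back to the table-wide mean ",
            "wood density")
    wd[need] <- glob
    lvl[need] <- "global"
  }
  stems$wood_density <- wd
  stems$wd_level <- lvl
  stems
}

#' Pioneer stem and basal-area fractions
#'
#' A live stem counts as a pioneer only if its genus is in the pioneer
#' list and its DBH is at most `dbh_max` (25 cm by default, excluding
#' likely pre-disturbance establishment).
#'
#' @param stems Stem tibble; only `status == "live"` rows are used.
#' @param pioneer_genera Character vector of pioneer genera.
#' @param dbh_max Maximum pioneer DBH, cm.
#' @return One-row tibble: `n_live`, `stem_fraction`, `ba_fraction`
#'   (missing when there are no live stems).
#' @export
pioneer_metrics <- function(stems, pioneer_genera = default_pioneer_genera(),
                            dbh_max = 25) {
  live <- stems[stems$status == "live", ]
  if (nrow(live) == 0) {
    return(tibble::tibble(n_live = 0L, stem_fraction = NA_real_,
                          ba_fraction = NA_real_))
  }
  is_pio <- live$genus %in% pioneer_genera & live$dbh_cm <= dbh_max
  ba <- basal_area_m2(live$dbh_cm)
  tibble::tibble(
    n_live = nrow(live),
    stem_fraction = mean(is_pio),
    ba_fraction = sum(ba[is_pio]) / sum(ba)
  )
}

#' Fraction of live stems with resprouting
#'
#' Resprouting is shoot regrowth stimulated by mechanical injury
#' (uprooting, partial or total crown rupture).
#'
#' @param stems Stem tibble; only live stems enter the denominator.
#' @return Scalar fraction, `NA` if there are no live stems.
#' @export
resprouter_fraction <- function(stems) {
  live <- stems[stems$status == "live", ]
  if (nrow(live) == 0) return(NA_real_)
  mean(live$resprouter)
}

#' Dead-tree density and modes of death
#'
#' @param stems Stem tibble.
#' @param subplots Sub-plot tibble with `subplot_id` and `area_m2`.
#' @return Tibble per sub-plot: `n_dead`, `dead_density_ha`,
#'   `n_snapped`, `n_uprooted`, `n_standing`, `mean_dead_dbh_cm`.
#' @export
dead_tree_metrics <- function(stems, subplots) {
  if (any(subplots$area_m2 <= 0)) stop("sub-plot areas must be positive")
  dead <- stems[stems$status == "dead", ]
  agg <- dead |>
    dplyr::group_by(.data$subplot_id) |>
    dplyr::summarise(
      n_dead = dplyr::n(),
      n_snapped = sum(.data$mode_of_death == "snapped"),
      n_uprooted = sum(.data$mode_of_death == "uprooted"),
      n_standing = sum(.data$mode_of_death == "standing"),
      mean_dead_dbh_cm = mean(.data$dbh_cm),
      .groups = "drop"
    )
  subplots[, c("subplot_id", "area_m2")] |>
    dplyr::left_join(agg, by = "subplot_id") |>
    dplyr::mutate(
      dplyr::across(c("n_dead", "n_snapped", "n_uprooted", "n_standing"),
                    ~ dplyr::coalesce(.x, 0L)),
      dead_density_ha = .data$n_dead / .data$area_m2 * 1e4
    ) |>
    dplyr::select("subplot_id", "n_dead", "dead_density_ha", "n_snapped",
                  "n_uprooted", "n_standing", "mean_dead_dbh_cm")
}

#' Mean with a Student-t confidence half-width
#'
#' Summary convention used throughout the structural tables:
#' mean plus/minus the 99% confidence half-width
#' `t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector (`NA`s dropped).
#' @param level Confidence level (default 0.99).
#' @return One-row tibble: `mean`, `ci_half`, `n` (`ci_half` is `NA` when
#'   `n < 2`).
#' @export
summarize_ci <- function(values, level = 0.99) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0) return(tibble::tibble(mean = NA_real_, ci_half = NA_real_,
                                    n = 0L))
  hw <- if (n < 2) NA_real_ else
    qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n)
  tibble::tibble(mean = mean(x), ci_half = hw, n = n)
}

#' Bin DBH values into diameter classes
#'
#' @param dbh_cm DBH values, cm.
#' @param bin_width Class width, cm (default 10).
#' @param min_dbh Lower edge of the first class (default 10, the census
#'   threshold).
#' @param max_dbh Optional upper edge of the last class; defaults to the
#'   smallest multiple of `bin_width` above the data.
#' @return Tibble: `bin_lo`, `bin_hi` (classes `[lo, hi)`), `count`.
#' @export
dbh_histogram <- function(dbh_cm, bin_width = 10, min_dbh = 10,
                          max_dbh = NULL) {
  stopifnot(bin_width > 0, all(dbh_cm >= min_dbh))
  if (is.null(max_dbh)) {
    max_dbh <- min_dbh +
      bin_width * max(1, ceiling((max(dbh_cm) - min_dbh) / bin_width + 1e-9))
    if (max(dbh_cm) >= max_dbh) max_dbh <- max_dbh + bin_width
  }
  breaks <- seq(min_dbh, max_dbh, by = bin_width)
  cnt <- table(cut(dbh_cm, breaks, right = FALSE))
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = as.integer(cnt))
}

#' Chi-squared comparison of two diameter distributions
#'
#' Two-sample chi-squared on the 2 x k contingency table of counts from
#' two histograms with identical binning; classes empty in both are
#' dropped first.
#'
#' @param h1,h2 Histograms from [dbh_histogram()] (or plain count
#'   vectors) over the same classes.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chisq_compare <- function(h1, h2) {
  c1 <- if (is.data.frame(h1)) h1$count else h1
  c2 <- if (is.data.frame(h2)) h2$count else h2
  if (length(c1) != length(c2)) stop("histograms use different binning")
  keep <- c1 + c2 > 0
  if (sum(keep) < 2) stop("fewer than 2 usable diameter classes")
  ct <- rbind(c1[keep], c2[keep])
  ht <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}
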