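#' Default run configuration
#'
#' All tunable parameters of the synthetic end-to-end run with their
#' defaults: the calibrated mortality model (slope 103.22, intercept
#' -3.32, zero floor 0.032, cap 100), the 0.16 dNPV gap/class threshold,
#' 8-connectivity, the 30 m to 3 m refinement factor, groups of five
#' plots, and the synthetic landscape dimensions.
#'
#' @return A `bd_config` list.
#' @export
default_config <- function() {
  structure(
    list(
      slope = 103.22, intercept = -3.32, zero_floor = 0.032, cap = 100,
      gap_threshold = 0.16, connectivity = 8, refine_factor = 10,
      group_size = 5, seed = 42L, nmds_starts = 20,
      pioneer_genera = default_pioneer_genera(),
      nrows = 100, ncols = 100, noise_sd = 0.01,
      patch_count = 6, patch_radius = 8, subplot_count = 144
    ),
    class = "bd_config"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], rejects unknown
#' keys by name and validates values (an empty file yields all defaults).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `bd_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- c("slope", "intercept", "zero_floor", "cap", "gap_threshold",
           "connectivity", "refine_factor", "group_size", "seed",
           "nmds_starts", "nrows", "ncols", "noise_sd", "patch_count",
           "patch_radius", "subplot_count")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 ||
        !is.finite(cfg[[k]])) {
      stop("configuration key '", k, "' must be a single finite number")
    }
  }
  mortality_model(cfg$slope, cfg$intercept, cfg$zero_floor, cfg$cap)
  if (!cfg$connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (cfg$group_size < 1) stop("group_size must be at least 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(cfg, class = "bd_config")
}

config_model <- function(cfg) {
  mortality_model(cfg$slope, cfg$intercept, cfg$zero_floor, cfg$cap)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, unmix, disturbance, inventory and community in
#' order, writes every output table as CSV into `out_dir` along with a
#' JSON manifest (package version, seed, configuration hash, completed
#' stages), and returns the in-memory bundle. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config A `bd_config` (see [default_config()], [load_config()]).
#' @param out_dir Output directory, created if needed.
#' @return (Invisibly) a list with the simulation bundle, the dNPV
#'   raster, disturbance summary, inventory and community tables, and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  model <- config_model(config)
  lib <- default_endmembers()

  sim <- simulate_blowdown(
    landscape_params(nrows = config$nrows, ncols = config$ncols,
                     patch_count = config$patch_count,
                     patch_radius = config$patch_radius,
                     noise_sd = config$noise_sd, seed = config$seed),
    community_params(), model, lib,
    subplot_count = config$subplot_count
  )
  stages <- c(stages, "simulate")

  fr_pre <- shade_normalize(unmix_scene(sim$scenes$pre, lib))
  fr_post <- shade_normalize(unmix_scene(sim$scenes$post, lib))
  dnpv <- delta_npv(fr_pre, fr_post)
  stages <- c(stages, "unmix")

  dist <- disturbance_summary(sim$subplots, dnpv, model,
                              gap_threshold = config$gap_threshold,
                              connectivity = config$connectivity,
                              refine_factor = config$refine_factor)
  gaps <- label_gaps(dnpv, config$gap_threshold, config$connectivity)
  dist_out <- dist[, c("subplot_id", "dnpv_w", "sp_mortality_pct",
                       "ng_mortality_pct", "gap_ha", "disturbance_class")]
  write.csv(dist_out, file.path(out_dir, "disturbance_summary.csv"),
            row.names = FALSE)
  write_raster_csv(gaps$labels, file.path(out_dir, "gap_labels.csv"))
  stages <- c(stages, "disturbance")

  live <- structure_metrics(sim$stems, sim$subplots, "live")
  dead <- dead_tree_metrics(sim$stems, sim$subplots)
  by_subplot <- dist |>
    dplyr::left_join(live, by = "subplot_id") |>
    dplyr::left_join(dead, by = "subplot_id")
  stems_out <- dplyr::mutate(
    sim$stems,
    resprouter = as.integer(.data$resprouter),
    mode_of_death = ifelse(.data$mode_of_death == "none", NA,
                           .data$mode_of_death)
  )
  write.csv(stems_out, file.path(out_dir, "stems.csv"), row.names = FALSE)
  write.csv(sim$subplots, file.path(out_dir, "subplots.csv"),
            row.names = FALSE)
  write.csv(by_subplot, file.path(out_dir, "structure_by_subplot.csv"),
            row.names = FALSE)
  t1 <- table1_summary(by_subplot)
  write.csv(t1, file.path(out_dir, "structure_by_class.csv"),
            row.names = FALSE)
  stages <- c(stages, "inventory")

  groups <- group_by_mortality_rank(dist, group_size = config$group_size)
  div <- diversity_by_group(sim$stems, groups)
  write.csv(div, file.path(out_dir, "diversity_by_group.csv"),
            row.names = FALSE)
  comm_low <- sim$stems |>
    dplyr::semi_join(dist[dist$disturbance_class == "low", "subplot_id"],
                     by = "subplot_id")
  comm_high <- sim$stems |>
    dplyr::semi_join(dist[dist$disturbance_class == "high", "subplot_id"],
                     by = "subplot_id")
  ivi_tbl <- dplyr::bind_rows(
    low = if (any(comm_low$status == "live"))
      ivi(build_matrix(comm_low, "genus")),
    high = if (any(comm_high$status == "live"))
      ivi(build_matrix(comm_high, "genus")),
    .id = "disturbance_class"
  )
  write.csv(ivi_tbl, file.path(out_dir, "ivi_by_class.csv"),
            row.names = FALSE)
  keep_ids <- groups$subplot_id
  comm <- build_matrix(
    sim$stems[sim$stems$subplot_id %in% keep_ids, ], "species",
    subplots = dist[dist$subplot_id %in% keep_ids, ]
  )
  ord <- nmds_ordination(bray_curtis(comm), k = 2,
                         n_starts = config$nmds_starts,
                         seed = config$seed)
  write.csv(tidy(ord), file.path(out_dir, "nmds_scores.csv"),
            row.names = FALSE)
  guilds <- genus_guilds(sim$stems, groups)
  curves <- purrr::map_dfr(guilds$curves, tidy)
  write.csv(curves, file.path(out_dir, "guild_curves.csv"),
            row.names = FALSE)
  write.csv(guilds$summary, file.path(out_dir, "guild_summary.csv"),
            row.names = FALSE)
  stages <- c(stages, "community")

  manifest <- list(
    package = "blowdownr",
    version = as.character(utils::packageVersion("blowdownr")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages,
    files = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, sim = sim, dnpv = dnpv, gaps = gaps,
                 disturbance = dist, structure = by_subplot,
                 table1 = t1, groups = groups, diversity = div,
                 ivi = ivi_tbl, nmds = ord, guilds = guilds,
                 manifest = manifest, out_dir = out_dir))
}

#' Structural summary by topographic class and disturbance level
#'
#' Mean and 99% confidence half-width of tree density (TD), basal area
#' (BA), weighted dNPV, sub-plot mortality (SP), neighboring mortality
#' (NG) and gap size (GS), for every combination of disturbance level and
#' topographic class plus an `All` row per level. Empty strata keep their
#' row with missing values.
#'
#' @param by_subplot Joined per-sub-plot table (disturbance + structure),
#'   as produced inside [run_pipeline()].
#' @param level Confidence level (default 0.99).
#' @return A tibble, one row per stratum.
#' @export
table1_summary <- function(by_subplot, level = 0.99) {
  vars <- c(TD = "density_ha", BA = "basal_area_m2ha", dNPV = "dnpv_w",
            SP = "sp_mortality_pct", NG = "ng_mortality_pct",
            GS = "gap_ha")
  vars <- vars[vars %in% names(by_subplot)]
  strata <- tidyr::expand_grid(
    disturbance_class = c("low", "high"),
    topo_class = c("All", topo_levels)
  )
  purrr::pmap_dfr(strata, function(disturbance_class, topo_class) {
    rows <- by_subplot[by_subplot$disturbance_class == disturbance_class, ]
    if (topo_class != "All") {
      rows <- rows[rows$topo_class == topo_class, ]
    }
    out <- tibble::tibble(disturbance_class = disturbance_class,
                          topo_class = topo_class, n_subplots = nrow(rows))
    for (nm in names(vars)) {
      ci <- summarize_ci(rows[[vars[[nm]]]], level)
      out[[paste0(nm, "_mean")]] <- ci$mean
      out[[paste0(nm, "_ci")]] <- ci$ci_half
    }
    out
  })
}

#' Structure-versus-mortality regressions by topographic class
#'
#' OLS of tree density, basal area, mean live DBH and mean wood density
#' on sub-plot mortality, per topographic class and overall.
#'
#' @param by_subplot Joined per-sub-plot table (see [table1_summary()]).
#' @return Tibble of [simple_ols()] rows with `topo_class` and `response`.
#' @export
table2_regressions <- function(by_subplot) {
  resp <- c(TD = "density_ha", BA = "basal_area_m2ha",
            mean_DBH = "mean_dbh_cm", WD = "mean_wood_density")
  resp <- resp[resp %in% names(by_subplot)]
  classes <- c("All", intersect(topo_levels,
                                unique(by_subplot$topo_class)))
  purrr::map_dfr(classes, function(cl) {
    rows <- if (cl == "All") by_subplot else
      by_subplot[by_subplot$topo_class == cl, ]
    purrr::map_dfr(names(resp), function(nm) {
      y <- rows[[resp[[nm]]]]
      ok <- sum(is.finite(y) & is.finite(rows$sp_mortality_pct)) >= 3 &&
        sd(rows$sp_mortality_pct[is.finite(rows$sp_mortality_pct) &
                                   is.finite(y)]) > 0
      if (!ok) {
        return(tibble::tibble(topo_class = cl, response = nm))
      }
      dplyr::bind_cols(
        tibble::tibble(topo_class = cl, response = nm),
        simple_ols(y, rows$sp_mortality_pct)
      )
    })
  })
}

#' Write a plain-text run report
#'
#' Renders the structural summary ([table1_summary()]) and the regression
#' table ([table2_regressions()]) of a pipeline bundle as aligned text.
#'
#' @param bundle Result of [run_pipeline()].
#' @param path Optional file to write; omitted = return text only.
#' @return (Invisibly) the report lines.
#' @export
write_report <- function(bundle, path = NULL) {
  if (is.null(bundle$structure)) stop("incomplete bundle: no structure table")
  t1 <- bundle$table1 %||% table1_summary(bundle$structure)
  t2 <- table2_regressions(bundle$structure)
  fmt <- function(m, c) {
    ifelse(is.na(m), "-", sprintf("%.1f+-%s", m,
                                  ifelse(is.na(c), "NA", sprintf("%.1f", c))))
  }
  lines <- c(
    "Structural summary by disturbance level and topographic class",
    "(mean +- 99% CI)",
    sprintf("%-6s %-8s %4s %14s %14s %12s %12s %12s %10s",
            "level", "class", "n", "TD", "BA", "dNPV", "SP", "NG", "GS"))
  for (i in seq_len(nrow(t1))) {
    r <- t1[i, ]
    dn <- ifelse(is.na(r$dNPV_mean), "-",
                 sprintf("%.3f+-%.3f", r$dNPV_mean, r$dNPV_ci))
    lines <- c(lines, sprintf(
      "%-6s %-8s %4d %14s %14s %12s %12s %12s %10s",
      r$disturbance_class, r$topo_class, r$n_subplots,
      fmt(r$TD_mean, r$TD_ci), fmt(r$BA_mean, r$BA_ci), dn,
      fmt(r$SP_mean, r$SP_ci), fmt(r$NG_mean, r$NG_ci),
      fmt(r$GS_mean, r$GS_ci)))
  }
  lines <- c(lines, "", "Regressions on sub-plot mortality (y = a + b x)",
             sprintf("%-8s %-9s %9s %9s %6s %8s %7s", "class",
                     "response", "slope", "intercept", "r2", "p", "r"))
  for (i in seq_len(nrow(t2))) {
    r <- t2[i, ]
    lines <- c(lines, if (is.na(r$slope %||% NA)) {
      sprintf("%-8s %-9s %9s", r$topo_class, r$response, "-")
    } else {
      sprintf("%-8s %-9s %9.3f %9.2f %6.2f %8.1e %7.2f", r$topo_class,
              r$response, r$slope, r$intercept, r$r_squared, r$p_value,
              r$pearson_r)
    })
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
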