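#' Parameters for the synthetic landscape generator
#'
#' Describes an undulating terra-firme landscape (plateau/slope/valley
#' toposequence) hit by a convective-storm blowdown. Defaults follow the
#' study conditions: altitudes 40-180 m a.s.l., plateaus above 80 m with
#' gentle (<= 10 degree) slopes, mortality 0-70% concentrated on plateaus
#' and slopes, weak disturbance in valleys.
#'
#' @param nrows,ncols Grid size in native 30 m pixels (>= 3).
#' @param plateau_altitude_min Plateau altitude threshold, m (default 80).
#' @param slope_angle_min Slope-class angle threshold, degrees (default 10).
#' @param severity_by_class Named vector of per-class disturbance severity
#'   (peak mortality fraction reached where a storm patch is centred on
#'   that class), each in `[0, 1]`, ordered plateau >= slope > valley.
#' @param patch_count Number of storm damage patches (Gaussian blobs).
#' @param patch_radius Patch e-folding radius in pixels.
#' @param noise_sd Reflectance noise standard deviation (>= 0).
#' @param flat_altitude If set, a constant-altitude landscape at this
#'   elevation (m) instead of the undulating field; useful for tests.
#' @param seed Integer RNG seed.
#' @return A `bd_landscape_params` list.
#' @export
landscape_params <- function(nrows = 100, ncols = 100,
                             plateau_altitude_min = 80,
                             slope_angle_min = 10,
                             severity_by_class = c(plateau = 0.40,
                                                   slope = 0.30,
                                                   valley = 0.05),
                             patch_count = 6, patch_radius = 8,
                             noise_sd = 0.01, flat_altitude = NULL,
                             seed = 42L) {
  stopifnot(nrows >= 3, ncols >= 3, noise_sd >= 0, patch_count >= 0,
            patch_radius > 0)
  if (!all(c("plateau", "slope", "valley") %in% names(severity_by_class))) {
    stop("severity_by_class needs entries plateau, slope, valley")
  }
  if (any(severity_by_class < 0 | severity_by_class > 1)) {
    stop("severity values must lie in [0, 1]")
  }
  structure(
    list(nrows = as.integer(nrows), ncols = as.integer(ncols),
         plateau_altitude_min = plateau_altitude_min,
         slope_angle_min = slope_angle_min,
         severity_by_class = severity_by_class,
         patch_count = as.integer(patch_count),
         patch_radius = patch_radius, noise_sd = noise_sd,
         flat_altitude = flat_altitude, seed = as.integer(seed)),
    class = "bd_landscape_params"
  )
}

#' Topographic class labels
#'
#' Integer class rasters use 1 = plateau, 2 = slope, 3 = valley.
#' @export
topo_levels <- c("plateau", "slope", "valley")

# evaluate code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic topography
#'
#' Builds a smooth altitude field (a seeded sum of low-frequency cosine
#' modes rescaled to 40-180 m), derives slope angle by finite differences
#' at the 30 m pixel scale, assigns soil texture and stream adjacency from
#' elevation (clay above the plateau threshold, mixed on mid-elevations,
#' sand with stream contact on the valley bottoms), and classifies each
#' pixel with [classify_topography()].
#'
#' @param params A [landscape_params()].
#' @return A `bd_topography` list of [bd_raster()]s: `altitude`,
#'   `slope_deg`, `class` (integer, see [topo_levels]) plus character
#'   matrices `soil` and logical `stream`.
#' @export
generate_topography <- function(params = landscape_params()) {
  stopifnot(inherits(params, "bd_landscape_params"))
  nr <- params$nrows; nc <- params$ncols
  if (!is.null(params$flat_altitude)) {
    alt <- matrix(params$flat_altitude, nr, nc)
  } else {
    alt <- with_local_seed(params$seed, {
      xs <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
      ys <- matrix(rep(seq_len(nr), times = nc), nr, nc) / nr
      z <- matrix(0, nr, nc)
      for (k in 1:5) {
        fx <- sample(1:3, 1); fy <- sample(1:3, 1)
        ph <- runif(2, 0, 2 * pi)
        z <- z + (1 / k) * cos(2 * pi * (fx * xs + ph[1])) *
          cos(2 * pi * (fy * ys + ph[2]))
      }
      z
    })
    rng <- range(alt)
    alt <- if (diff(rng) > 0) 40 + 140 * (alt - rng[1]) / diff(rng) else
      matrix(110, nr, nc)
  }
  res <- 30
  # central-difference slope magnitude, one-sided at the borders
  gx <- alt; gy <- alt
  gx[, 2:(nc - 1)] <- (alt[, 3:nc] - alt[, 1:(nc - 2)]) / (2 * res)
  gx[, 1] <- (alt[, 2] - alt[, 1]) / res
  gx[, nc] <- (alt[, nc] - alt[, nc - 1]) / res
  gy[2:(nr - 1), ] <- (alt[3:nr, ] - alt[1:(nr - 2), ]) / (2 * res)
  gy[1, ] <- (alt[2, ] - alt[1, ]) / res
  gy[nr, ] <- (alt[nr, ] - alt[nr - 1, ]) / res
  slope_deg <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

  lo <- params$plateau_altitude_min
  soil <- matrix("mixed", nr, nc)
  soil[alt > lo] <- "clay"
  soil[alt < 0.75 * lo] <- "sand"
  stream <- alt < 0.7 * lo  # seasonal stream network on the valley floors

  cls <- classify_topography(as.vector(alt), as.vector(slope_deg),
                             as.vector(soil), as.vector(stream),
                             plateau_altitude_min = lo,
                             slope_angle_min = params$slope_angle_min)
  cls_i <- matrix(match(cls, topo_levels), nr, nc)

  structure(
    list(altitude = bd_raster(alt), slope_deg = bd_raster(slope_deg),
         class = bd_raster(cls_i), soil = soil, stream = stream),
    class = "bd_topography"
  )
}

#' @export
print.bd_topography <- function(x, ...) {
  tab <- table(factor(topo_levels[x$class$values], levels = topo_levels))
  cat(sprintf("<bd_topography> %d x %d pixels: %s\n",
              nrow(x$altitude$values), ncol(x$altitude$values),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Generate the true mortality field
#'
#' Storm-damage patches are Gaussian blobs centred on randomly chosen
#' plateau or slope pixels; the blob field is normalised to peak 1 and
#' modulated by the per-class severity, then capped at 0.70 (the maximum
#' mortality the disturbance gradient spans). Valleys receive only blob
#' tails times their (low) severity, so class-mean mortality is ordered
#' plateau >= slope > valley.
#'
#' @param topo A `bd_topography` from [generate_topography()].
#' @param params The same [landscape_params()].
#' @return A [bd_raster()] of mortality fractions in `[0, 0.70]`.
#' @export
generate_true_mortality <- function(topo, params) {
  stopifnot(inherits(topo, "bd_topography"))
  nr <- params$nrows; nc <- params$ncols
  sev <- params$severity_by_class
  s_px <- matrix(sev[topo_levels[topo$class$values]], nr, nc)
  B <- matrix(0, nr, nc)
  if (params$patch_count > 0) {
    B <- with_local_seed(params$seed + 1L, {
      eligible <- which(topo$class$values %in% c(1L, 2L))
      if (!length(eligible)) eligible <- seq_len(nr * nc)
      centers <- sample(eligible, params$patch_count,
                        replace = length(eligible) < params$patch_count)
      ci <- (centers - 1L) %% nr + 1L
      cj <- (centers - 1L) %/% nr + 1L
      ii <- matrix(rep(seq_len(nr), times = nc), nr, nc)
      jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      acc <- matrix(0, nr, nc)
      for (k in seq_along(centers)) {
        d2 <- (ii - ci[k])^2 + (jj - cj[k])^2
        acc <- acc + exp(-d2 / (2 * params$patch_radius^2))
      }
      acc
    })
  }
  m <- if (max(B) > 0) pmin((B / max(B)) * s_px, 0.70) else B
  bd_raster(m)
}

#' Synthesise a pre/post reflectance scene pair
#'
#' Inverts the analysis chain: per-pixel true mortality is mapped through
#' the inverse mortality model to a true dNPV, added to a constant
#' pre-storm shade-normalised NPV baseline, and both states are rendered
#' as exact convex combinations of the endmember spectra (fixed shade
#' fraction) plus optional Gaussian reflectance noise. With zero noise the
#' unmixing + disturbance chain recovers `100 * true_mortality` exactly
#' (up to numerical tolerance) above the zero floor.
#'
#' @param true_mortality A [bd_raster()] of mortality fractions.
#' @param lib An [endmember_library()].
#' @param model A [mortality_model()].
#' @param noise_sd Reflectance noise SD (>= 0).
#' @param base_npv_n Pre-storm shade-normalised NPV (default 0.2).
#' @param shade_frac Constant shade fraction in both scenes (default 0.25).
#' @param seed Integer seed for the noise draws.
#' @return List with elements `pre` and `post`, both [bd_scene()]s.
#' @export
synthesize_scene_pair <- function(true_mortality, lib = default_endmembers(),
                                  model = mortality_model(), noise_sd = 0,
                                  base_npv_n = 0.2, shade_frac = 0.25,
                                  seed = 1L) {
  stopifnot(inherits(true_mortality, "bd_raster"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  m <- true_mortality$values
  if (any(m < 0 | m > 1)) stop("mortality fractions must lie in [0, 1]")
  dnpv <- (100 * m - model$intercept) / model$slope
  if (any(abs(dnpv) > 1)) stop("mortality implies dNPV outside [-1, 1]")
  npv_pre <- matrix(base_npv_n, nrow(m), ncol(m))
  npv_post <- npv_pre + dnpv
  if (any(npv_post < 0 | npv_post > 1)) {
    stop("implied post-storm NPV fraction outside [0, 1]; lower base_npv_n")
  }
  E <- endmember_matrix(lib)
  render <- function(npv_n, tag, noise) {
    gvf <- (1 - npv_n) * (1 - shade_frac)
    npvf <- npv_n * (1 - shade_frac)
    bands <- lapply(seq_len(nrow(E)), function(b) {
      gvf * E[b, 1] + npvf * E[b, 2] + shade_frac * E[b, 3] + noise[[b]]
    })
    names(bands) <- paste0("b", seq_len(nrow(E)))
    bd_scene(bands, res = true_mortality$res, xmin = true_mortality$xmin,
             ymin = true_mortality$ymin, date_tag = tag)
  }
  noise <- with_local_seed(seed, {
    lapply(seq_len(2 * nrow(E)), function(i) {
      if (noise_sd > 0) {
        matrix(rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
      } else {
        0
      }
    })
  })
  list(pre = render(npv_pre, "pre", noise[seq_len(nrow(E))]),
       post = render(npv_post, "post", noise[nrow(E) + seq_len(nrow(E))]))
}

#' Lay out field sub-plots on the landscape
#'
#' Places `count` rectangular sub-plots (default 10 x 25 m, the census
#' plot size; 144 of them total 3.6 ha) in transect-like rows inside the
#' raster extent and attaches the topographic attributes of each plot's
#' centroid pixel. Placement is deterministic.
#'
#' @param topo A `bd_topography`.
#' @param count Number of sub-plots.
#' @param width,height Plot dimensions in m (default 25 x 10).
#' @param margin Margin kept from the raster edge, m (default 90).
#' @param row_spacing Spacing between transect rows, m (default 120).
#' @return Tibble: `subplot_id`, rectangle corners `xmin`, `xmax`, `ymin`,
#'   `ymax`, `area_m2`, `topo_class`, `altitude_m`, `slope_deg`, `soil`,
#'   `stream_adjacent`.
#' @export
generate_subplots <- function(topo, count = 144, width = 25, height = 10,
                              margin = 90, row_spacing = 120) {
  stopifnot(inherits(topo, "bd_topography"), count >= 0)
  r <- topo$altitude
  if (count == 0) {
    return(tibble::tibble(subplot_id = character(), xmin = numeric(),
                          xmax = numeric(), ymin = numeric(),
                          ymax = numeric(), area_m2 = numeric(),
                          topo_class = character(), altitude_m = numeric(),
                          slope_deg = numeric(), soil = character(),
                          stream_adjacent = logical()))
  }
  x0 <- r$xmin + margin; x1 <- raster_xmax(r) - margin - width
  y0 <- r$ymin + margin; y1 <- raster_ymax(r) - margin - height
  if (x1 < x0 || y1 < y0) stop("raster too small for the requested margin")
  xs <- seq(x0, x1, by = width)
  ys <- seq(y0, y1, by = row_spacing)
  pos <- expand.grid(x = xs, y = ys)
  if (nrow(pos) < count) {
    stop("extent holds only ", nrow(pos), " sub-plots; requested ", count)
  }
  # spread the plots over the whole transect grid, not just the first rows
  pos <- pos[unique(round(seq(1, nrow(pos), length.out = count))), ]
  if (nrow(pos) < count) pos <- expand.grid(x = xs, y = ys)[seq_len(count), ]
  cx <- pos$x + width / 2; cy <- pos$y + height / 2
  rc <- t(mapply(function(x, y) cell_at(r, x, y), cx, cy))
  idx <- cbind(rc[, 1], rc[, 2])
  tibble::tibble(
    subplot_id = sprintf("sp%03d", seq_len(count)),
    xmin = pos$x, xmax = pos$x + width,
    ymin = pos$y, ymax = pos$y + height,
    area_m2 = width * height,
    topo_class = topo_levels[topo$class$values[idx]],
    altitude_m = topo$altitude$values[idx],
    slope_deg = topo$slope_deg$values[idx],
    soil = topo$soil[idx],
    stream_adjacent = topo$stream[idx]
  )
}

#' True area-weighted mortality of each sub-plot
#'
#' Ground-truth counterpart of [subplot_weighted_dnpv()]: the area-weighted
#' mean of the true mortality raster under each plot rectangle.
#'
#' @param subplots Sub-plot tibble from [generate_subplots()].
#' @param true_mortality A [bd_raster()] of mortality fractions.
#' @param refine_factor Subdivision factor (default 10).
#' @return The tibble with a `true_mortality` column (fraction) appended.
#' @export
subplot_true_mortality <- function(subplots, true_mortality,
                                   refine_factor = 10) {
  fine <- refine_grid(true_mortality, refine_factor)
  subplots$true_mortality <- vapply(
    seq_len(nrow(subplots)),
    function(i) weighted_dnpv_fine(fine, subplots[i, ]),
    numeric(1)
  )
  subplots
}
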