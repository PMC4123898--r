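#' Calibrated dNPV-to-mortality model
#'
#' Linear model mapping a pixel's (or plot's) dNPV to percent tree
#' mortality, `Y = slope * dNPV + intercept`, with a zero floor: below
#' `zero_floor` the linear form goes negative (an artefact of calibrating
#' on disturbed areas only), so mortality is set to 0 there. Predictions
#' are clamped to `[0, cap]`.
#'
#' @param slope Percent mortality per unit dNPV (default 103.22).
#' @param intercept Percent (default -3.32).
#' @param zero_floor dNPV below which mortality is taken as zero
#'   (default 0.032, the rounded root of the default line).
#' @param cap Maximum percent (default 100).
#' @return A `bd_mortality_model` object.
#' @export
mortality_model <- function(slope = 103.22, intercept = -3.32,
                            zero_floor = 0.032, cap = 100) {
  stopifnot(is.finite(slope), is.finite(intercept), is.finite(zero_floor))
  if (slope <= 0) stop("slope must be positive")
  if (cap <= 0 || cap > 100) stop("cap must be in (0, 100]")
  root <- -intercept / slope
  if (abs(zero_floor - root) > 1e-3 && zero_floor < root) {
    stop("zero_floor must sit at (or above) the model's zero-mortality root")
  }
  structure(list(slope = slope, intercept = intercept,
                 zero_floor = zero_floor, cap = cap),
            class = "bd_mortality_model")
}

#' @export
print.bd_mortality_model <- function(x, ...) {
  cat(sprintf(
    "<mortality model> Y = %.4g * dNPV %+.4g %%, floor dNPV < %.3g -> 0, cap %g%%\n",
    x$slope, x$intercept, x$zero_floor, x$cap))
  invisible(x)
}

#' @export
glance.bd_mortality_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 zero_floor = x$zero_floor, cap = x$cap,
                 zero_root = model_zero_root(x))
}

#' Predict percent mortality from dNPV
#'
#' Elementwise on vectors, matrices or [bd_raster()]s: 0 below the floor,
#' otherwise the linear prediction clamped to `[0, cap]`.
#'
#' @param dnpv Numeric scalar/vector/matrix or a [bd_raster()].
#' @param model A [mortality_model()].
#' @return Percent mortality, same shape as the input.
#' @export
mortality_from_dnpv <- function(dnpv, model = mortality_model()) {
  if (inherits(dnpv, "bd_raster")) {
    out <- dnpv
    out$values <- mortality_from_dnpv(dnpv$values, model)
    return(out)
  }
  if (any(!is.finite(dnpv) & !is.na(dnpv))) stop("dNPV must be finite")
  y <- pmin(pmax(model$slope * dnpv + model$intercept, 0), model$cap)
  y[dnpv < model$zero_floor] <- 0
  y
}

#' dNPV at which the model predicts zero mortality
#'
#' @param model A [mortality_model()].
#' @return `-intercept / slope`.
#' @export
model_zero_root <- function(model = mortality_model()) {
  if (model$slope == 0) stop("slope is zero")
  -model$intercept / model$slope
}

#' Refine a raster to a finer grid
#'
#' Value-preserving nearest-neighbour refinement: each native pixel becomes
#' `factor^2` subcells carrying the identical value, so the grid mean is
#' unchanged. Used to resample 30 m dNPV to a 3 m grid before area-weighted
#' plot extraction.
#'
#' @param r A [bd_raster()].
#' @param factor Positive integer subdivision factor (default 10).
#' @return A [bd_raster()] at `res / factor`.
#' @export
refine_grid <- function(r, factor = 10) {
  stopifnot(inherits(r, "bd_raster"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  v <- kronecker(r$values, matrix(1, factor, factor))
  bd_raster(v, xmin = r$xmin, ymin = r$ymin, res = r$res / factor)
}

# index range of refined subcells whose centres fall inside [lo, hi)
subcell_range <- function(lo, hi, origin, res, n) {
  first <- ceiling((lo - origin) / res + 0.5 - 1e-9)
  last <- floor((hi - origin) / res + 0.5 - 1e-9)
  c(max(1L, first), min(n, last))
}

#' Area-weighted mean dNPV of a sub-plot
#'
#' Refines the dNPV raster (native 30 m to 3 m by default) and averages the
#' subcells whose centres fall inside the sub-plot rectangle, so pixels
#' partially covered by the plot contribute in proportion to covered area.
#'
#' @param dnpv A [bd_raster()] of dNPV at native resolution.
#' @param subplot One-row data frame (or list) with `xmin`, `xmax`,
#'   `ymin`, `ymax` in the raster's projected metres.
#' @param refine_factor Subdivision factor (default 10: 30 m -> 3 m).
#' @return Scalar weighted mean dNPV.
#' @export
subplot_weighted_dnpv <- function(dnpv, subplot, refine_factor = 10) {
  fine <- refine_grid(dnpv, refine_factor)
  weighted_dnpv_fine(fine, subplot)
}

weighted_dnpv_fine <- function(fine, subplot) {
  nr <- nrow(fine$values); nc <- ncol(fine$values)
  jr <- subcell_range(subplot$xmin, subplot$xmax, fine$xmin, fine$res, nc)
  ytop <- fine$ymin + nr * fine$res
  # rows count from the top; invert the y interval
  ir <- subcell_range(ytop - subplot$ymax, ytop - subplot$ymin, 0, fine$res, nr)
  if (jr[1] > jr[2] || ir[1] > ir[2]) {
    stop("sub-plot covers no refined subcell centres")
  }
  mean(fine$values[ir[1]:ir[2], jr[1]:jr[2]], na.rm = TRUE)
}

#' Sub-plot mortality (SP)
#'
#' Applies the mortality model to the sub-plot's area-weighted mean dNPV;
#' the zero floor and cap apply after averaging.
#'
#' @inheritParams subplot_weighted_dnpv
#' @param model A [mortality_model()].
#' @return Percent mortality.
#' @export
subplot_mortality <- function(dnpv, subplot, model = mortality_model(),
                              refine_factor = 10) {
  mortality_from_dnpv(subplot_weighted_dnpv(dnpv, subplot, refine_factor),
                      model)
}

#' Neighboring mortality (NG)
#'
#' Locates the native pixel containing the sub-plot's centre point,
#' averages dNPV over the eight adjacent pixels (centre excluded; edge
#' pixels average over the neighbours that exist) and applies the model to
#' that mean.
#'
#' @inheritParams subplot_mortality
#' @return Percent mortality.
#' @export
neighboring_mortality <- function(dnpv, subplot, model = mortality_model()) {
  cx <- (subplot$xmin + subplot$xmax) / 2
  cy <- (subplot$ymin + subplot$ymax) / 2
  rc <- cell_at(dnpv, cx, cy)
  nr <- nrow(dnpv$values); nc <- ncol(dnpv$values)
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  i <- rc[1] + off$di; j <- rc[2] + off$dj
  ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
  vals <- dnpv$values[cbind(i[ok], j[ok])]
  mortality_from_dnpv(mean(vals, na.rm = TRUE), model)
}

#' Delineate blowdown gaps
#'
#' Gaps are the connected components of pixels with `dNPV >= threshold`
#' ("virtual polygons" of contiguous disturbed canopy). Contiguity is
#' 8-connected by default (diagonal adjacency counts), configurable to 4.
#'
#' @param dnpv A [bd_raster()] at native resolution.
#' @param threshold dNPV gap threshold (default 0.16, ~13% mortality).
#' @param connectivity 4 or 8.
#' @return A `bd_gapmap`: `labels` (a [bd_raster()]; 0 = background) and a
#'   tibble `gaps` (`gap_id`, `n_pixels`, `area_m2`, `area_ha`).
#' @export
label_gaps <- function(dnpv, threshold = 0.16, connectivity = 8) {
  stopifnot(inherits(dnpv, "bd_raster"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- dnpv$values
  nr <- nrow(v); nc <- ncol(v)
  fg <- which(!is.na(v) & v >= threshold)
  lab <- matrix(0L, nr, nc)
  gaps <- tibble::tibble(gap_id = integer(), n_pixels = integer(),
                         area_m2 = numeric(), area_ha = numeric())
  if (length(fg)) {
    idx <- match(seq_len(nr * nc), fg)  # linear index -> vertex id
    off <- if (connectivity == 4) {
      cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
    } else {
      as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5, ]
    }
    ii <- (fg - 1L) %% nr + 1L
    jj <- (fg - 1L) %/% nr + 1L
    edges <- NULL
    for (k in seq_len(nrow(off))) {
      i2 <- ii + off[k, 1]; j2 <- jj + off[k, 2]
      ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
      nb <- idx[(j2[ok] - 1L) * nr + i2[ok]]
      src <- which(ok)[!is.na(nb)]
      edges <- rbind(edges, cbind(src, nb[!is.na(nb)]))
    }
    g <- igraph::graph_from_edgelist(
      if (is.null(edges)) matrix(integer(), 0, 2) else edges,
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lab[fg] <- as.integer(comp)
    px_area <- dnpv$res^2
    counts <- tabulate(comp)
    gaps <- tibble::tibble(
      gap_id = seq_along(counts),
      n_pixels = counts,
      area_m2 = counts * px_area,
      area_ha = counts * px_area / 1e4
    )
  }
  structure(
    list(labels = bd_raster(lab, dnpv$xmin, dnpv$ymin, dnpv$res),
         gaps = gaps, threshold = threshold, connectivity = connectivity),
    class = "bd_gapmap"
  )
}

#' @export
print.bd_gapmap <- function(x, ...) {
  cat(sprintf("<bd_gapmap> %d gaps at dNPV >= %g (%d-connected)\n",
              nrow(x$gaps), x$threshold, x$connectivity))
  invisible(x)
}

#' Gap size (GS) for a sub-plot
#'
#' Area in hectares of the gap whose pixels include the sub-plot's centre
#' point; 0 if that pixel is background.
#'
#' @param gapmap A `bd_gapmap` from [label_gaps()].
#' @param subplot One-row data frame/list with the rectangle corners.
#' @return Gap area in ha.
#' @export
gap_size_for_subplot <- function(gapmap, subplot) {
  cx <- (subplot$xmin + subplot$xmax) / 2
  cy <- (subplot$ymin + subplot$ymax) / 2
  rc <- cell_at(gapmap$labels, cx, cy)
  id <- gapmap$labels$values[rc[1], rc[2]]
  if (id == 0L) return(0)
  gapmap$gaps$area_ha[gapmap$gaps$gap_id == id]
}

#' Low/high disturbance classification
#'
#' High disturbance iff the sub-plot's weighted dNPV strictly exceeds the
#' threshold; a plot at exactly the threshold is low (the low class is
#' defined by `dNPV < threshold` and the boundary is assigned there).
#'
#' @param dnpv_w Numeric vector of weighted dNPV values.
#' @param threshold Class threshold (default 0.16).
#' @return Character vector `"low"`/`"high"`.
#' @export
classify_disturbance <- function(dnpv_w, threshold = 0.16) {
  ifelse(dnpv_w > threshold, "high", "low")
}

#' Per-sub-plot disturbance summary
#'
#' Runs the full per-plot chain for every sub-plot: area-weighted dNPV,
#' sub-plot mortality (SP), neighboring mortality (NG), gap size (GS) and
#' the low/high disturbance class.
#'
#' @param subplots Sub-plot tibble with `subplot_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax` (see [generate_subplots()]).
#' @param dnpv A [bd_raster()] of dNPV at native resolution.
#' @param model A [mortality_model()].
#' @param gap_threshold dNPV threshold for gap delineation and the
#'   low/high split (default 0.16).
#' @param connectivity Gap contiguity, 4 or 8.
#' @param refine_factor Refinement for the weighted mean (default 10).
#' @return The input tibble with columns `dnpv_w`, `sp_mortality_pct`,
#'   `ng_mortality_pct`, `gap_ha`, `disturbance_class` appended.
#' @export
disturbance_summary <- function(subplots, dnpv, model = mortality_model(),
                                gap_threshold = 0.16, connectivity = 8,
                                refine_factor = 10) {
  stopifnot(inherits(dnpv, "bd_raster"))
  fine <- refine_grid(dnpv, refine_factor)
  gm <- label_gaps(dnpv, threshold = gap_threshold,
                   connectivity = connectivity)
  rows <- purrr::map(seq_len(nrow(subplots)), function(i) {
    sp <- subplots[i, ]
    w <- weighted_dnpv_fine(fine, sp)
    tibble::tibble(
      dnpv_w = w,
      sp_mortality_pct = mortality_from_dnpv(w, model),
      ng_mortality_pct = neighboring_mortality(dnpv, sp, model),
      gap_ha = gap_size_for_subplot(gm, sp)
    )
  })
  out <- dplyr::bind_cols(subplots, dplyr::bind_rows(rows))
  out$disturbance_class <- classify_disturbance(out$dnpv_w, gap_threshold)
  out
}
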