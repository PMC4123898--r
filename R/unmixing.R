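#' Multiband reflectance scene
#'
#' @param bands Named list of numeric matrices (one per spectral band), all
#'   the same dimension, reflectance in `[0, 1]`.
#' @param xmin,ymin Lower-left corner (m).
#' @param res Pixel size (m); Landsat native is 30.
#' @param date_tag `"pre"` or `"post"` disturbance.
#' @param mask Optional logical matrix; `TRUE` marks excluded pixels
#'   (cloud, cloud shadow, water). Masking is accepted as given; no masking
#'   algorithm is applied here.
#' @return A `bd_scene` object.
#' @export
bd_scene <- function(bands, xmin = 0, ymin = 0, res = 30,
                     date_tag = c("pre", "post"), mask = NULL) {
  date_tag <- match.arg(date_tag)
  stopifnot(is.list(bands), length(bands) >= 1)
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stop("all bands must share the same dimensions")
  if (!is.null(mask)) stopifnot(identical(dim(mask), dims[[1]]))
  if (is.null(names(bands))) names(bands) <- paste0("b", seq_along(bands))
  structure(
    list(bands = bands, xmin = xmin, ymin = ymin, res = res,
         date_tag = date_tag, mask = mask),
    class = "bd_scene"
  )
}

#' @export
print.bd_scene <- function(x, ...) {
  cat(sprintf("<bd_scene '%s'> %d bands, %d x %d pixels, %g m\n",
              x$date_tag, length(x$bands), nrow(x$bands[[1]]),
              ncol(x$bands[[1]]), x$res))
  invisible(x)
}

#' Endmember library for spectral mixture analysis
#'
#' Reference spectra for the three-endmember model: green vegetation (GV),
#' non-photosynthetic vegetation (NPV: wood, dead vegetation, surface
#' litter) and shade.
#'
#' @param gv,npv,shade Numeric reflectance vectors, one entry per band,
#'   equal lengths (at least 2) and linearly independent.
#' @return A tibble with columns `band`, `gv`, `npv`, `shade` of class
#'   `bd_endmembers`.
#' @export
endmember_library <- function(gv, npv, shade) {
  n <- length(gv)
  stopifnot(n >= 2, length(npv) == n, length(shade) == n)
  E <- cbind(gv, npv, shade)
  pairs <- utils::combn(3, 2)
  pairwise_dep <- any(apply(pairs, 2, function(p) {
    qr(E[, p, drop = FALSE])$rank < 2
  }))
  if (qr(E)$rank < min(3L, n) || pairwise_dep) {
    stop("endmember spectra must be linearly independent")
  }
  out <- tibble::tibble(band = paste0("b", seq_len(n)),
                        gv = gv, npv = npv, shade = shade)
  class(out) <- c("bd_endmembers", class(out))
  out
}

#' Default synthetic endmember library
#'
#' Six-band spectra shaped like Landsat TM bands 1-5 and 7: GV with the
#' chlorophyll red edge (high NIR, low red), NPV with the elevated
#' red/SWIR ligno-cellulose signature, and a dark near-flat shade spectrum.
#' These ship with the synthetic generator; for real imagery supply
#' scene-derived spectra.
#'
#' @return A `bd_endmembers` tibble.
#' @export
default_endmembers <- function() {
  endmember_library(
    gv    = c(0.010, 0.035, 0.020, 0.450, 0.220, 0.080),
    npv   = c(0.080, 0.120, 0.180, 0.300, 0.420, 0.300),
    shade = c(0.020, 0.020, 0.020, 0.010, 0.010, 0.010)
  )
}

#' Read or write an endmember library as CSV
#'
#' Rows are bands, columns `gv`, `npv`, `shade`.
#'
#' @param lib A `bd_endmembers` tibble.
#' @param path File path.
#' @export
write_endmembers_csv <- function(lib, path) {
  write.csv(as.data.frame(lib), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endmembers_csv
#' @export
read_endmembers_csv <- function(path) {
  df <- read.csv(path)
  endmember_library(df$gv, df$npv, df$shade)
}

endmember_matrix <- function(lib) {
  as.matrix(lib[, c("gv", "npv", "shade")])
}

#' Fully constrained linear spectral unmixing
#'
#' Decomposes every unmasked pixel spectrum into fractions of the GV, NPV
#' and shade endmembers minimising the squared spectral residual subject to
#' nonnegativity and sum-to-one. The sum-to-one equality-constrained least
#' squares solution is computed in closed form for all pixels at once; the
#' minority of pixels for which it violates nonnegativity are re-solved by
#' nonnegative least squares ([pracma::lsqnonneg()]) on a system augmented
#' with a heavily weighted sum-to-one row.
#'
#' @param scene A [bd_scene()].
#' @param lib A [endmember_library()] with one entry per scene band.
#' @return A `bd_fractions` object holding per-pixel `gv`, `npv`, `shade`
#'   matrices (shade-normalised slots empty until [shade_normalize()]).
#' @export
unmix_scene <- function(scene, lib = default_endmembers()) {
  stopifnot(inherits(scene, "bd_scene"))
  E <- endmember_matrix(lib)
  nb <- nrow(E)
  if (length(scene$bands) != nb) {
    stop("scene has ", length(scene$bands), " bands but the endmember ",
         "library has ", nb)
  }
  dims <- dim(scene$bands[[1]])
  S <- do.call(cbind, lapply(scene$bands, as.vector))  # npix x nb

  # closed-form sum-to-one least squares: KKT system is affine in the
  # spectrum, so one small solve gives fractions for every pixel
  A <- crossprod(E)
  K <- rbind(cbind(2 * A, 1), c(1, 1, 1, 0))
  Kinv <- solve(K)
  Ft <- Kinv %*% rbind(2 * t(E) %*% t(S), 1)  # 4 x npix
  Fr <- t(Ft[1:3, , drop = FALSE])            # npix x 3

  bad <- which(apply(Fr, 1, min) < -1e-9)
  if (length(bad)) {
    w <- 1e4
    Ea <- rbind(E, rep(w, 3))
    for (i in bad) {
      f <- pracma::lsqnonneg(Ea, c(S[i, ], w))$x
      Fr[i, ] <- f / sum(f)
    }
  }
  Fr[Fr < 0] <- 0
  Fr <- Fr / rowSums(Fr)

  if (!is.null(scene$mask)) Fr[as.vector(scene$mask), ] <- NA_real_

  structure(
    list(
      gv = matrix(Fr[, 1], dims[1], dims[2]),
      npv = matrix(Fr[, 2], dims[1], dims[2]),
      shade = matrix(Fr[, 3], dims[1], dims[2]),
      gv_n = NULL, npv_n = NULL,
      xmin = scene$xmin, ymin = scene$ymin, res = scene$res,
      date_tag = scene$date_tag
    ),
    class = "bd_fractions"
  )
}

#' @export
print.bd_fractions <- function(x, ...) {
  cat(sprintf("<bd_fractions '%s'> %d x %d pixels%s\n", x$date_tag,
              nrow(x$gv), ncol(x$gv),
              if (is.null(x$npv_n)) "" else ", shade-normalized"))
  invisible(x)
}

#' Shade-normalise unmixing fractions
#'
#' Normalises the pixels without shade as `GV/(GV + NPV)` and
#' `NPV/(GV + NPV)`; pixels where `GV + NPV = 0` become missing.
#'
#' @param fr A `bd_fractions` object from [unmix_scene()].
#' @return The same object with `gv_n` and `npv_n` filled.
#' @export
shade_normalize <- function(fr) {
  stopifnot(inherits(fr, "bd_fractions"))
  tot <- fr$gv + fr$npv
  tot[tot < 1e-9] <- NA_real_
  fr$gv_n <- fr$gv / tot
  fr$npv_n <- fr$npv / tot
  fr
}

#' Convert unmixing fractions to a long tibble
#'
#' @param fr A `bd_fractions` object.
#' @return Tibble with one row per pixel: `row`, `col`, `x`, `y`, `gv`,
#'   `npv`, `shade` and, when shade-normalised, `gv_n`, `npv_n`.
#' @export
fractions_to_tibble <- function(fr) {
  base <- raster_to_tibble(bd_raster(fr$gv, fr$xmin, fr$ymin, fr$res))
  out <- dplyr::rename(base, gv = "value")
  out$npv <- as.vector(fr$npv)
  out$shade <- as.vector(fr$shade)
  if (!is.null(fr$npv_n)) {
    out$gv_n <- as.vector(fr$gv_n)
    out$npv_n <- as.vector(fr$npv_n)
  }
  out
}

#' Change in shade-normalised NPV (dNPV)
#'
#' The disturbance-intensity proxy: post-storm minus pre-storm
#' shade-normalised NPV fraction per pixel. Rising NPV reflects the pulse
#' of wood, dead vegetation and surface litter left by wind-throw.
#'
#' @param pre,post Shade-normalised `bd_fractions` on the same grid.
#' @return A [bd_raster()] of dNPV with attribute `provenance`.
#' @export
delta_npv <- function(pre, post) {
  stopifnot(inherits(pre, "bd_fractions"), inherits(post, "bd_fractions"))
  if (is.null(pre$npv_n) || is.null(post$npv_n)) {
    stop("both inputs must be shade-normalized (see shade_normalize())")
  }
  if (!identical(dim(pre$npv_n), dim(post$npv_n)) ||
      !isTRUE(all.equal(c(pre$xmin, pre$ymin, pre$res),
                        c(post$xmin, post$ymin, post$res)))) {
    stop("pre and post fractions are not on the same grid")
  }
  out <- bd_raster(post$npv_n - pre$npv_n, pre$xmin, pre$ymin, pre$res)
  attr(out, "provenance") <- c(pre = pre$date_tag, post = post$date_tag)
  out
}
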