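#' Score deposited energy on a plane
#'
#' Emulates a piece of radiochromic film facing the source: hits whose
#' z-coordinate (normal to the film) lies within `[plane_offset,
#' plane_offset + slab_thickness)` are accumulated, energy-weighted, into a
#' square pixel grid over (x, y). The field lies in-plane along x. Film
#' response is taken as proportional to deposited energy; no dose-response
#' curve is modelled.
#'
#' @param x A `hit_cloud` or a [transport_config()] (which is run first).
#' @param plane_offset Distance from the source to the near face of the
#'   scoring slab, mm (the film-to-source distance).
#' @param slab_thickness Thickness of the scoring slab in mm (nominal film
#'   sensitive-layer scale).
#' @param pixel_size Pixel pitch in mm.
#' @param half_extent Half-width of the scored square in mm; the grid has an
#'   odd number of pixels so the source projects onto a pixel centre.
#' @return An object of class `dose_map2d`: a matrix (rows = x, columns = y)
#'   with attributes `pixel_size`, `centers` (pixel-centre coordinates) and
#'   `plane_offset`.
#' @export
score_dose_plane <- function(x, plane_offset = 0, slab_thickness = 0.3,
                             pixel_size = 0.1, half_extent = 12) {
  if (inherits(x, "transport_config")) x <- run_simulation(x)
  stopifnot(inherits(x, "hit_cloud"))
  if (slab_thickness <= 0) stop("slab_thickness must be positive")
  if (abs(plane_offset) >= x$config$sphere_radius)
    stop("scoring plane lies outside the sphere")
  h <- x$hits
  npix <- 2L * as.integer(ceiling(half_extent / pixel_size)) + 1L
  half <- (npix - 1L) %/% 2L
  centers <- (-half:half) * pixel_size
  sel <- h$z >= plane_offset & h$z < plane_offset + slab_thickness &
    abs(h$x) <= half_extent + pixel_size / 2 &
    abs(h$y) <= half_extent + pixel_size / 2
  grid <- matrix(0, npix, npix)
  if (any(sel)) {
    ix <- as.integer(round(h$x[sel] / pixel_size)) + half + 1L
    iy <- as.integer(round(h$y[sel] / pixel_size)) + half + 1L
    ok <- ix >= 1L & ix <= npix & iy >= 1L & iy <= npix
    lin <- (iy[ok] - 1L) * npix + ix[ok]
    s <- rowsum(h$energy[sel][ok], lin)
    grid[as.integer(rownames(s))] <- s[, 1]
  }
  structure(grid, class = c("dose_map2d", "matrix"),
            pixel_size = pixel_size, centers = centers,
            plane_offset = plane_offset)
}

#' Build a dose map from raw pixel values
#'
#' @param grid Square matrix of non-negative pixel values with odd dimensions.
#' @param pixel_size Pixel pitch in mm.
#' @param plane_offset Metadata only.
#' @return A `dose_map2d`.
#' @export
dose_map2d <- function(grid, pixel_size = 0.1, plane_offset = 0) {
  grid <- as.matrix(grid)
  if (nrow(grid) %% 2 == 0 || ncol(grid) %% 2 == 0)
    stop("grid dimensions must be odd so the source projection is a pixel centre")
  if (any(grid < 0)) stop("grid values must be non-negative")
  half <- (nrow(grid) - 1L) %/% 2L
  structure(grid, class = c("dose_map2d", "matrix"),
            pixel_size = pixel_size,
            centers = (-half:half) * pixel_size,
            plane_offset = plane_offset)
}

#' @export
print.dose_map2d <- function(x, ...) {
  cat(sprintf("<dose_map2d> %d x %d pixels, %g mm/pixel, offset %g mm, max %.4g\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), attr(x, "plane_offset"),
              max(x)))
  invisible(x)
}

#' @export
plot.dose_map2d <- function(x, ...) {
  cc <- attr(x, "centers")
  graphics::image(cc, cc, unclass(x), asp = 1, xlab = "x [mm] (parallel to B)",
                  ylab = "y [mm]", col = grDevices::hcl.colors(64, "inferno"),
                  ...)
  invisible(x)
}

.gaussian_smooth <- function(map, sigma_px) {
  if (sigma_px <= 0) return(map)
  EBImage::gblur(unclass(map), sigma = sigma_px)
}

#' Extract isodose diameters from a dose map
#'
#' The map is smoothed with a Gaussian kernel (to stabilise the maximum and
#' contours against Monte Carlo noise), each level thresholds the smoothed map
#' at `level * max`, and the diameter along an axis is the extent of the
#' thresholded region along the line through the dose maximum parallel to
#' that axis (outer pixel edges).
#'
#' @param map A `dose_map2d` with a strictly positive maximum.
#' @param levels Fractions of the maximum, strictly decreasing, in (0, 1].
#' @param smooth_sigma Gaussian smoothing width in pixels; 0 disables
#'   smoothing (used for closed-form synthetic checks).
#' @return An object of class `isodose_diameters`: a data frame with columns
#'   `level`, `diameter_x`, `diameter_y` (mm).
#' @export
extract_isodose_diameters <- function(map,
                                      levels = c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15),
                                      smooth_sigma = 2) {
  stopifnot(inherits(map, "dose_map2d"))
  if (max(map) <= 0) stop("dose map has no positive maximum")
  if (any(diff(levels) >= 0) || any(levels <= 0) || any(levels > 1))
    stop("levels must be strictly decreasing fractions in (0, 1]")
  px <- attr(map, "pixel_size")
  sm <- .gaussian_smooth(map, smooth_sigma)
  mx <- max(sm)
  peak <- which(sm == mx, arr.ind = TRUE)[1, ]
  dx <- dy <- numeric(length(levels))
  for (i in seq_along(levels)) {
    thr <- levels[i] * mx
    rowv <- sm[, peak[2]] >= thr   # along x through the maximum
    colv <- sm[peak[1], ] >= thr   # along y
    span <- function(v) {
      idx <- which(v)
      if (length(idx) == 0) { warning("empty region at an isodose level"); return(0) }
      (max(idx) - min(idx) + 1) * px
    }
    dx[i] <- span(rowv)
    dy[i] <- span(colv)
  }
  structure(data.frame(level = levels, diameter_x = dx, diameter_y = dy),
            class = c("isodose_diameters", "data.frame"))
}

#' Percent change of isodose diameters between field conditions
#'
#' @param d_field Diameters measured with the field on.
#' @param d_zero Diameters of the zero-field reference (same levels).
#' @return Data frame with columns `level`, `axis`, `percent`:
#'   `100 * (d_field - d_zero) / d_zero`; positive means the contour is larger
#'   under the field. A zero baseline diameter yields `NA` with a warning.
#' @export
percent_change <- function(d_field, d_zero) {
  if (!isTRUE(all.equal(d_field$level, d_zero$level)))
    stop("the two diameter sets use different levels")
  pc <- function(f, z) {
    out <- 100 * (f - z) / z
    if (any(z == 0)) { warning("zero baseline diameter"); out[z == 0] <- NA }
    out
  }
  data.frame(level = rep(d_field$level, 2),
             axis = rep(c("x", "y"), each = nrow(d_field)),
             percent = c(pc(d_field$diameter_x, d_zero$diameter_x),
                         pc(d_field$diameter_y, d_zero$diameter_y)))
}

#' Write a dose map as plain text and optionally grayscale PNG
#'
#' @param map A `dose_map2d`.
#' @param file Path for the plain-text grid (whitespace-separated values).
#' @param png_file Optional path for a grayscale PNG scaled to the
#'   maximum dose.
#' @return `file`, invisibly.
#' @export
write_dose_map <- function(map, file, png_file = NULL) {
  utils::write.table(unclass(map), file, row.names = FALSE, col.names = FALSE)
  if (!is.null(png_file)) {
    g <- unclass(map) / max(max(map), .Machine$double.eps)
    png::writePNG(t(g)[rev(seq_len(ncol(g))), , drop = FALSE], png_file,
                  dpi = 25.4 / attr(map, "pixel_size"))
  }
  invisible(file)
}
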