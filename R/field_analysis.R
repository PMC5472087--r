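#' Slice and stripe geometry
#'
#' Scoring geometry for the hit-count analysis: thin slices are cut
#' perpendicular to the slice axis (default y, with B along x), spaced 1 mm
#' apart, and each slice is divided into stripes both parallel (x) and
#' perpendicular (z) to the field.
#'
#' @param slice_axis Axis the slices are stacked along (`"x"`, `"y"` or `"z"`).
#' @param slice_thickness Thickness of each slice in mm.
#' @param slice_spacing Distance between slice centres in mm.
#' @param stripe_width Width of the counting stripes in mm.
#' @return An object of class `slice_spec`.
#' @export
slice_spec <- function(slice_axis = "y", slice_thickness = 0.1,
                       slice_spacing = 1.0, stripe_width = 0.5) {
  if (slice_thickness <= 0 || slice_spacing <= 0 || stripe_width <= 0)
    stop("thickness, spacing and stripe width must be positive")
  if (slice_thickness > slice_spacing)
    stop("slice_thickness must not exceed slice_spacing")
  slice_axis <- match.arg(slice_axis, c("x", "y", "z"))
  structure(list(slice_axis = slice_axis, slice_thickness = slice_thickness,
                 slice_spacing = slice_spacing, stripe_width = stripe_width),
            class = "slice_spec")
}

.stripe_axes <- function(slice_axis) setdiff(c("x", "y", "z"), slice_axis)

#' Count hits per slice and stripe
#'
#' For every slice centre k * spacing (k integer, both signs, within the
#' sphere), hits whose slice-axis coordinate lies within half a thickness of
#' the centre are histogrammed into stripes along each of the two remaining
#' axes. Stripe bins are half-open intervals `[c - w/2, c + w/2)` centred on
#' integer multiples of the stripe width, so counts are additive and gap-free.
#'
#' @param cloud A `hit_cloud`.
#' @param spec A [slice_spec()].
#' @return A data frame of class `stripe_counts` with columns `slice_center`,
#'   `axis`, `stripe_center`, `count`. Only populated stripes are listed, plus
#'   zero rows for empty slices are omitted.
#' @export
slice_and_count <- function(cloud, spec = slice_spec()) {
  stopifnot(inherits(cloud, "hit_cloud"), inherits(spec, "slice_spec"))
  h <- cloud$hits
  if (nrow(h) == 0) stop("hit cloud is empty")
  R <- cloud$config$sphere_radius
  kmax <- floor(R / spec$slice_spacing)
  centers <- seq(-kmax, kmax) * spec$slice_spacing
  axes <- .stripe_axes(spec$slice_axis)
  s_coord <- h[[spec$slice_axis]]
  out <- list()
  for (ctr in centers) {
    in_slice <- abs(s_coord - ctr) <= spec$slice_thickness / 2
    if (!any(in_slice)) next
    for (ax in axes) {
      v <- h[[ax]][in_slice]
      # half-open bins centred on multiples of the stripe width
      idx <- floor(v / spec$stripe_width + 0.5)
      tb <- table(idx)
      out[[length(out) + 1]] <- data.frame(
        slice_center = ctr, axis = ax,
        stripe_center = as.numeric(names(tb)) * spec$stripe_width,
        count = as.integer(tb))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(slice_center = numeric(0), axis = character(0),
               stripe_center = numeric(0), count = integer(0))
  rownames(res) <- NULL
  structure(res, class = c("stripe_counts", "data.frame"),
            spec = spec)
}

#' Write stripe counts, one CSV per slice
#'
#' @param counts A `stripe_counts` data frame from [slice_and_count()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return The written paths, invisibly.
#' @export
write_stripe_counts <- function(counts, dir, prefix = "slice") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ctr in unique(counts$slice_center)) {
    f <- file.path(dir, sprintf("%s_y%+05.1fmm.csv", prefix, ctr))
    utils::write.csv(counts[counts$slice_center == ctr, ], f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Extent of the hit cloud along one axis
#'
#' The range of the interaction points on an axis, estimated as a percentile
#' of the absolute coordinate; `percentile = 100` gives the maximum. The
#' default 99.5 trades a little bias for much better seed-to-seed stability
#' than the extreme value.
#'
#' @param cloud A `hit_cloud`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param percentile Percentile of `|coordinate|` in (0, 100].
#' @return Extent (semi-axis) in mm.
#' @export
axis_extent <- function(cloud, axis = c("x", "y", "z"), percentile = 99.5) {
  axis <- match.arg(axis)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  v <- abs(cloud$hits[[axis]])
  if (percentile == 100) max(v) else unname(quantile(v, percentile / 100))
}

#' Ellipsoid interaction volume of a hit cloud
#'
#' The interaction volume is modelled as an ellipsoid whose semi-axes a, b, c
#' are the per-axis extents of the hit cloud, V = (4/3) pi a b c.
#'
#' @param cloud A `hit_cloud`.
#' @param percentile Passed to [axis_extent()].
#' @return An object of class `interaction_volume` with fields `extent_x`,
#'   `extent_y`, `extent_z` (mm), `volume` (mm^3) and `percentile_used`.
#' @export
interaction_volume <- function(cloud, percentile = 99.5) {
  a <- axis_extent(cloud, "x", percentile)
  b <- axis_extent(cloud, "y", percentile)
  c_ <- axis_extent(cloud, "z", percentile)
  structure(list(extent_x = a, extent_y = b, extent_z = c_,
                 volume = 4 / 3 * pi * a * b * c_,
                 percentile_used = percentile),
            class = "interaction_volume")
}

#' @export
print.interaction_volume <- function(x, ...) {
  cat(sprintf("<interaction_volume> a = %.3f, b = %.3f, c = %.3f mm (percentile %g)\n",
              x$extent_x, x$extent_y, x$extent_z, x$percentile_used))
  cat(sprintf("  V = (4/3) pi a b c = %.2f mm^3\n", x$volume))
  invisible(x)
}

.source_energy_tag <- function(config) {
  if (is.numeric(config$source_energy)) config$source_energy else config$source_energy
}

#' Interaction-volume ratio between a field run and the zero-field reference
#'
#' @param cloud_B Hit cloud simulated with the field on.
#' @param cloud_0 Hit cloud at B = 0 with the same source energy.
#' @param percentile Passed to [interaction_volume()].
#' @return The ratio V(B)/V(0); the percent volume reduction is
#'   `100 * (1 - ratio)`.
#' @export
volume_ratio <- function(cloud_B, cloud_0, percentile = 99.5) {
  if (!identical(.source_energy_tag(cloud_B$config),
                 .source_energy_tag(cloud_0$config)))
    stop("clouds were generated with different source energies")
  interaction_volume(cloud_B, percentile)$volume /
    interaction_volume(cloud_0, percentile)$volume
}

#' Central hit enhancement under the field
#'
#' Ratio of hit counts in a central region between a field run and the
#' zero-field run with equal numbers of histories. By default the region is
#' the central stripe of the innermost slice read on the axis perpendicular
#' to the field: `|z| <= stripe_width/2` and `|y| <= slice_thickness/2`
#' (any x). A stripe count integrates the hit density over the remaining
#' in-slice coordinate, so reading it along the perpendicular axis integrates
#' over the field-invariant parallel coordinate and the count responds to the
#' transverse concentration; reading it along the parallel axis
#' (`stripe_axis = "x"`) integrates the compressed coordinate away and sees
#' only the much weaker residual effect. Alternatively a spherical central
#' region of given radius can be used.
#'
#' @param cloud_B,cloud_0 Hit clouds with and without field, equal
#'   `n_particles`.
#' @param spec A [slice_spec()] defining the central stripe.
#' @param stripe_axis Axis the counting stripe is centred on, one of the two
#'   in-slice axes.
#' @param central_region_radius If non-`NULL`, count hits with
#'   `|position| <= central_region_radius` instead of the stripe.
#' @return Count ratio N(B)/N(0).
#' @export
center_hit_ratio <- function(cloud_B, cloud_0, spec = slice_spec(),
                             stripe_axis = c("z", "x", "y"),
                             central_region_radius = NULL) {
  if (cloud_B$config$n_particles != cloud_0$config$n_particles)
    stop("runs must use equal n_particles")
  stripe_axis <- match.arg(stripe_axis)
  if (stripe_axis == spec$slice_axis)
    stop("stripe_axis must be one of the in-slice axes")
  count <- function(cl) {
    h <- cl$hits
    if (is.null(central_region_radius)) {
      sum(abs(h[[stripe_axis]]) <= spec$stripe_width / 2 &
            abs(h[[spec$slice_axis]]) <= spec$slice_thickness / 2)
    } else {
      sum(h$x^2 + h$y^2 + h$z^2 <= central_region_radius^2)
    }
  }
  n0 <- count(cloud_0)
  if (n0 == 0) stop("zero hits in the central region of the reference run")
  count(cloud_B) / n0
}
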