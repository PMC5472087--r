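.provenance_header <- function(seeds, extra = "") {
  sprintf("# magbeta %s | seeds=%s%s",
          as.character(utils::packageVersion("magbeta")),
          paste(seeds, collapse = ","),
          if (nzchar(extra)) paste0(" | ", extra) else "")
}

.write_csv_with_header <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Run the energy-by-field simulation matrix
#'
#' For every combination of source energy, field strength and seed: transport,
#' measure the ellipsoid interaction volume, and form the volume ratio against
#' the zero-field run of the same energy and seed. The per-cell results are
#' aggregated as mean and standard deviation over seeds. Defaults cover the
#' reference grid of four monoenergetic sources and seven field strengths.
#'
#' @param energies Source kinetic energies in MeV.
#' @param fields Field magnitudes in tesla; must contain 0 (the reference).
#' @param n_particles Histories per cell.
#' @param seeds Integer seeds (replicates).
#' @param percentile Extent percentile, see [axis_extent()].
#' @param output_dir If non-`NULL`, per-cell and aggregated CSVs (and stripe
#'   counts per slice) are written there with a provenance header.
#' @param stripe_counts Also compute and (if `output_dir` is set) write the
#'   slice/stripe histograms for each cell? Off by default: the tables are
#'   large.
#' @return A list with data frames `cells` (energy, B, seed, a, b, c, volume,
#'   ratio) and `summary` (mean and sd of the ratio per energy and B), plus
#'   `stripe_counts` when requested.
#' @export
run_matrix <- function(energies = c(0.5, 1, 1.5, 2),
                       fields = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                       n_particles = 1e5, seeds = 1:3, percentile = 99.5,
                       output_dir = NULL, stripe_counts = FALSE) {
  if (!0 %in% fields) stop("fields must include the 0 T reference")
  if (length(energies) == 0 || length(seeds) == 0) stop("empty matrix")
  fields <- sort(fields)
  cells <- list(); stripes <- list()
  for (E in energies) for (sd_ in seeds) {
    vol0 <- NULL
    for (B in fields) {
      cl <- run_simulation(transport_config(E, n_particles, B = B, seed = sd_))
      v <- interaction_volume(cl, percentile)
      if (B == 0) vol0 <- v$volume
      cells[[length(cells) + 1]] <- data.frame(
        energy = E, B = B, seed = sd_, extent_x = v$extent_x,
        extent_y = v$extent_y, extent_z = v$extent_z, volume = v$volume,
        ratio = v$volume / vol0)
      if (stripe_counts) {
        sc <- slice_and_count(cl)
        sc$energy <- E; sc$B <- B; sc$seed <- sd_
        stripes[[length(stripes) + 1]] <- sc
      }
      rm(cl)
    }
  }
  cells <- do.call(rbind, cells)
  agg <- do.call(rbind, lapply(split(cells, list(cells$energy, cells$B)), function(d)
    data.frame(energy = d$energy[1], B = d$B[1], ratio_mean = mean(d$ratio),
               ratio_sd = if (nrow(d) > 1) sd(d$ratio) else NA_real_,
               reduction_pct = 100 * (1 - mean(d$ratio)))))
  agg <- agg[order(agg$energy, agg$B), ]
  rownames(agg) <- NULL
  out <- list(cells = cells, summary = agg)
  if (stripe_counts) out$stripe_counts <- do.call(rbind, stripes)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    hdr <- .provenance_header(seeds, sprintf("n=%g percentile=%g", n_particles, percentile))
    .write_csv_with_header(cells, file.path(output_dir, "volume_cells.csv"), hdr)
    .write_csv_with_header(agg, file.path(output_dir, "volume_ratio_grid.csv"), hdr)
    if (stripe_counts)
      .write_csv_with_header(out$stripe_counts,
                             file.path(output_dir, "stripe_counts.csv"), hdr)
  }
  out
}

#' Run the film-plane experiment matrix
#'
#' Emulates the radiochromic-film measurement: a Y-90 point source, dose
#' scored on planes at the given source-to-film distances, at each field
#' strength, replicated over seeds. Isodose diameters are extracted per
#' replicate and summarised as mean and sd per level and axis; the percent
#' change of each field condition against the 0 T baseline (matched by offset
#' and seed) is reported.
#'
#' @param fields Field magnitudes in tesla; must include 0.
#' @param offsets Source-to-film distances in mm.
#' @param n_particles Histories per replicate.
#' @param seeds Integer seeds, one replicate each.
#' @param levels Isodose levels as fractions of the maximum.
#' @param pixel_size,slab_thickness,smooth_sigma Passed to the dose-plane
#'   scoring and contour extraction.
#' @param output_dir If non-`NULL`, diameter and percent-change CSVs are
#'   written there.
#' @return A list with data frames `diameters` (B, offset, seed, level,
#'   diameter per axis), `summary` (mean/sd per B, offset, level, axis) and
#'   `changes` (percent change vs the 0 T baseline).
#' @export
run_film_experiment <- function(fields = c(0, 1.5), offsets = c(0, 2),
                                n_particles = 1e5, seeds = 1:4,
                                levels = c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15),
                                pixel_size = 0.1, slab_thickness = 0.3,
                                smooth_sigma = 2, output_dir = NULL) {
  if (!0 %in% fields) stop("fields must include the 0 T baseline")
  rows <- list()
  for (B in fields) for (sd_ in seeds) {
    cl <- run_simulation(transport_config("Y90", n_particles, B = B, seed = sd_))
    for (off in offsets) {
      dm <- score_dose_plane(cl, plane_offset = off,
                             slab_thickness = slab_thickness,
                             pixel_size = pixel_size)
      di <- extract_isodose_diameters(dm, levels, smooth_sigma = smooth_sigma)
      rows[[length(rows) + 1]] <- data.frame(B = B, offset = off, seed = sd_,
                                             level = di$level,
                                             diameter_x = di$diameter_x,
                                             diameter_y = di$diameter_y)
    }
    rm(cl)
  }
  diam <- do.call(rbind, rows)
  key <- interaction(diam$B, diam$offset, diam$level)
  summ <- do.call(rbind, lapply(split(diam, key), function(d)
    data.frame(B = d$B[1], offset = d$offset[1], level = d$level[1],
               mean_x = mean(d$diameter_x), sd_x = sd(d$diameter_x),
               mean_y = mean(d$diameter_y), sd_y = sd(d$diameter_y))))
  summ <- summ[order(summ$B, summ$offset, -summ$level), ]
  rownames(summ) <- NULL
  base <- summ[summ$B == 0, ]
  changes <- do.call(rbind, lapply(which(summ$B != 0), function(i) {
    b <- base[base$offset == summ$offset[i] & base$level == summ$level[i], ]
    data.frame(B = summ$B[i], offset = summ$offset[i], level = summ$level[i],
               pct_x = 100 * (summ$mean_x[i] - b$mean_x) / b$mean_x,
               pct_y = 100 * (summ$mean_y[i] - b$mean_y) / b$mean_y)
  }))
  out <- list(diameters = diam, summary = summ, changes = changes)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    hdr <- .provenance_header(seeds, sprintf("n=%g levels=%s", n_particles,
                                             paste(levels, collapse = "/")))
    .write_csv_with_header(diam, file.path(output_dir, "isodose_diameters.csv"), hdr)
    .write_csv_with_header(summ, file.path(output_dir, "isodose_summary.csv"), hdr)
    if (!is.null(changes))
      .write_csv_with_header(changes, file.path(output_dir, "isodose_changes.csv"), hdr)
  }
  out
}
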