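.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a hit cloud with known ellipsoidal ground truth
#'
#' Test fixture for the extent/volume analysis: points drawn either uniformly
#' inside the ellipsoid (rejection from the bounding box) or as an anisotropic
#' Gaussian with the given axis scales, each carrying unit deposited energy.
#' Statistical structure (compact, axis-aligned anisotropy) mimics what the
#' analysis assumes, not the transport physics.
#'
#' @param semi_axes Length-3 vector of semi-axes (a, b, c) in mm.
#' @param n_points Number of points.
#' @param distribution `"uniform"` (in the ellipsoid) or `"gaussian"`.
#' @param seed Integer seed; output is bit-reproducible.
#' @return A `hit_cloud` whose config records the generator parameters.
#' @export
generate_ellipsoid_hit_cloud <- function(semi_axes, n_points,
                                         distribution = c("uniform", "gaussian"),
                                         seed = 1) {
  distribution <- match.arg(distribution)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (n_points < 1) stop("n_points must be >= 1")
  pts <- .with_seed(seed, {
    if (distribution == "uniform") {
      out <- matrix(numeric(0), 0, 3)
      while (nrow(out) < n_points) {
        m <- ceiling((n_points - nrow(out)) / 0.5) + 100
        cand <- cbind(runif(m, -1, 1), runif(m, -1, 1), runif(m, -1, 1))
        cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
        out <- rbind(out, cand)
      }
      out[seq_len(n_points), , drop = FALSE] %*% diag(semi_axes)
    } else {
      cbind(rnorm(n_points, sd = semi_axes[1]),
            rnorm(n_points, sd = semi_axes[2]),
            rnorm(n_points, sd = semi_axes[3]))
    }
  })
  hits <- data.frame(particle_id = seq_len(n_points), x = pts[, 1],
                     y = pts[, 2], z = pts[, 3], energy = 1)
  cfg <- list(source_energy = "synthetic-ellipsoid",
              n_particles = as.integer(n_points), B = 0,
              B_axis = c(1, 0, 0),
              sphere_radius = max(semi_axes) * 4, seed = as.integer(seed),
              semi_axes = semi_axes, distribution = distribution)
  class(cfg) <- "transport_config"
  particles <- data.frame(particle_id = seq_len(n_points), initial_energy = 1,
                          deposited = 1, escaped_energy = 0, escaped = FALSE,
                          final_x = pts[, 1], final_y = pts[, 2],
                          final_z = pts[, 3])
  structure(list(hits = hits, particles = particles, config = cfg),
            class = "hit_cloud")
}

#' Generate a dose map with known analytic isodose diameters
#'
#' Pixel values `amplitude * exp(-x^2/2 sigma_x^2 - y^2/2 sigma_y^2)`,
#' optionally degraded by multiplicative Gaussian noise. At noise 0 the
#' diameter of the level-f isodose along x is exactly
#' `2 sigma_x sqrt(2 ln(1/f))`.
#'
#' @param sigma_x,sigma_y Gaussian widths in mm.
#' @param amplitude Peak value (levels are relative, so it cancels).
#' @param pixel_size Pixel pitch in mm.
#' @param extent Half-width of the map in mm.
#' @param noise_fraction Relative standard deviation of multiplicative noise.
#' @param seed Seed for the noise.
#' @return A `dose_map2d`.
#' @export
generate_gaussian_dose_map <- function(sigma_x, sigma_y, amplitude = 1,
                                       pixel_size = 0.1, extent = 10,
                                       noise_fraction = 0, seed = 1) {
  if (sigma_x <= 0 || sigma_y <= 0) stop("sigmas must be positive")
  if (noise_fraction < 0) stop("noise_fraction must be non-negative")
  half <- as.integer(ceiling(extent / pixel_size))
  cc <- (-half:half) * pixel_size
  g <- amplitude * exp(-outer(cc^2 / (2 * sigma_x^2), cc^2 / (2 * sigma_y^2), "+"))
  if (noise_fraction > 0)
    g <- g * .with_seed(seed, matrix(pmax(0, 1 + rnorm(length(g), sd = noise_fraction)),
                                     nrow(g)))
  dose_map2d(g, pixel_size = pixel_size)
}

#' Analytic helix fixture
#'
#' Closed-form positions of a scatter-free, loss-free electron in a uniform
#' field, used as the independent oracle for the helical stepper: after a
#' total arc s the perpendicular component has turned by
#' phi = 0.29979 B s / p about the field axis.
#'
#' @param T Kinetic energy in MeV.
#' @param B Field magnitude in tesla (> 0), along `B_axis`.
#' @param n_steps Number of arc steps.
#' @param step_length Arc length per step in mm.
#' @param direction Initial direction (normalised internally).
#' @param B_axis Field axis.
#' @return Matrix `(n_steps + 1) x 3` of positions, first row the origin.
#' @export
generate_helix_fixture <- function(T, B, n_steps, step_length = 0.1,
                                   direction = c(0, 0, 1), B_axis = c(1, 0, 0)) {
  if (B <= 0) stop("B must be positive")
  bhat <- B_axis / sqrt(sum(B_axis^2))
  d <- direction / sqrt(sum(direction^2))
  p <- momentum_from_kinetic(T)
  dpar <- sum(d * bhat)
  dperp <- d - dpar * bhat
  dp <- sqrt(sum(dperp^2))
  s <- (0:n_steps) * step_length
  if (dp < 1e-14) return(outer(s, d))
  e1 <- dperp / dp
  e2 <- c(bhat[2] * e1[3] - bhat[3] * e1[2],
          bhat[3] * e1[1] - bhat[1] * e1[3],
          bhat[1] * e1[2] - bhat[2] * e1[1])
  r <- p * dp / (0.29979 * B)
  phi <- 0.29979 * B * s / p
  outer(s * dpar, bhat) + r * (outer(sin(phi), e1) + outer(1 - cos(phi), e2))
}
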