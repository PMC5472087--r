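#' @useDynLib magbeta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif integrate sd
#' @importFrom utils write.csv
NULL

# Electron rest mass [MeV] and the gyroradius constant p[MeV/c] = 0.29979 B[T] r[mm].
.me <- 0.510999
.pb <- 0.29979

#' Define a transport material
#'
#' Bundles the material constants the electron physics needs. Units are fixed
#' package-wide: mm, MeV, tesla, g/cm^3.
#'
#' @param name Preset name. Only `"water"` is predefined; pass the constants
#'   explicitly for anything else.
#' @param density Mass density in g/cm^3.
#' @param excitation_energy Mean excitation energy I in eV.
#' @param radiation_length Radiation length X0 in g/cm^2.
#' @param z_over_a Ratio of atomic number to mass number (electron density per
#'   unit mass, dimensionless).
#' @return An object of class `beta_material`.
#' @examples
#' water <- beta_material("water")
#' water$density
#' @export
beta_material <- function(name = "water", density = NULL,
                          excitation_energy = NULL, radiation_length = NULL,
                          z_over_a = NULL) {
  if (identical(name, "water")) {
    m <- list(name = "water", density = 1.0, excitation_energy = 75,
              radiation_length = 36.08, z_over_a = 0.55509)
  } else {
    m <- list(name = name, density = density,
              excitation_energy = excitation_energy,
              radiation_length = radiation_length, z_over_a = z_over_a)
  }
  if (!is.null(density)) m$density <- density
  if (!is.null(excitation_energy)) m$excitation_energy <- excitation_energy
  if (!is.null(radiation_length)) m$radiation_length <- radiation_length
  if (!is.null(z_over_a)) m$z_over_a <- z_over_a
  vals <- unlist(m[c("density", "excitation_energy", "radiation_length", "z_over_a")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material constants must be strictly positive")
  structure(m, class = "beta_material")
}

#' @export
print.beta_material <- function(x, ...) {
  cat(sprintf("<beta_material: %s>  rho = %g g/cm^3, I = %g eV, X0 = %g g/cm^2, Z/A = %g\n",
              x$name, x$density, x$excitation_energy, x$radiation_length, x$z_over_a))
  invisible(x)
}

#' Relativistic electron momentum from kinetic energy
#'
#' @param T Kinetic energy in MeV (vectorised).
#' @return Momentum in MeV/c.
#' @examples
#' momentum_from_kinetic(2)   # 2.4585 MeV/c
#' @export
momentum_from_kinetic <- function(T) {
  if (any(T < 0)) stop("kinetic energy must be non-negative")
  sqrt((T + .me)^2 - .me^2)
}

#' Electron kinetic energy from momentum
#'
#' Inverse of [momentum_from_kinetic()].
#'
#' @param p Momentum in MeV/c (vectorised).
#' @return Kinetic energy in MeV.
#' @export
kinetic_from_momentum <- function(p) {
  if (any(p < 0)) stop("momentum must be non-negative")
  sqrt(p^2 + .me^2) - .me
}

#' Gyroradius of an electron in a uniform magnetic field
#'
#' Radius of the circular component of the helical motion,
#' r = p_perp / (0.29979 B), with p in MeV/c, B in tesla, r in mm.
#'
#' @param T Kinetic energy in MeV.
#' @param B Field magnitude in tesla; must be positive (at B = 0 the radius is
#'   infinite and the trajectory is a straight line).
#' @param pitch_fraction Fraction of the momentum perpendicular to B, in
#'   `[0, 1]`.
#' @return Gyroradius in mm.
#' @examples
#' gyroradius(2, 2)  # 4.100 mm
#' @export
gyroradius <- function(T, B, pitch_fraction = 1) {
  if (any(B <= 0)) stop("B must be positive; at B = 0 the radius is infinite")
  if (any(pitch_fraction < 0 | pitch_fraction > 1))
    stop("pitch_fraction must lie in [0, 1]")
  momentum_from_kinetic(T) * pitch_fraction / (.pb * B)
}

#' Collision stopping power of electrons
#'
#' Moller-corrected Bethe collision stopping power (mean ionisation loss per
#' unit pathlength). The density-effect correction is omitted; below a few MeV
#' in water it is a sub-percent effect.
#'
#' @param T Kinetic energy in MeV (vectorised).
#' @param material A [beta_material()].
#' @return Stopping power in MeV/mm.
#' @examples
#' collision_stopping_power(1)  # about 0.187 MeV/mm in water
#' @export
collision_stopping_power <- function(T, material = beta_material("water")) {
  if (any(T <= 0)) stop("kinetic energy must be positive")
  tau <- T / .me
  g <- 1 + tau
  beta2 <- 1 - 1 / g^2
  I <- material$excitation_energy * 1e-6 # eV -> MeV
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / g^2
  s_mass <- 0.153536 * material$z_over_a / beta2 *
    (log(tau^2 * (tau + 2) / (2 * (I / .me)^2)) + Fm) # MeV cm^2/g
  s_mass * material$density / 10                      # MeV/mm
}

#' CSDA range of electrons
#'
#' Pathlength to rest in the continuous-slowing-down approximation, the
#' integral of 1/S(T) from the tracking cutoff up to T.
#'
#' @param T Kinetic energy in MeV (vectorised).
#' @param material A [beta_material()].
#' @param cutoff Lower integration limit in MeV (energy below which the
#'   residual pathlength is neglected).
#' @return Range in mm.
#' @examples
#' csda_range(2.28)  # about 11 mm in water
#' @export
csda_range <- function(T, material = beta_material("water"), cutoff = 0.010) {
  if (any(T < cutoff)) stop("T must exceed the cutoff energy")
  vapply(T, function(Ti) {
    if (Ti == cutoff) return(0)
    r <- integrate(function(t) 1 / collision_stopping_power(t, material),
                   lower = cutoff, upper = Ti, rel.tol = 1e-9,
                   subdivisions = 500L)
    if (r$message != "OK") stop("range quadrature failed: ", r$message)
    r$value
  }, numeric(1))
}

#' Highland multiple-scattering angle
#'
#' Gaussian width of the multiple Coulomb scattering polar angle accumulated
#' over one condensed step,
#' theta0 = 13.6 MeV / (beta p) * sqrt(t) * (1 + 0.038 ln t),
#' with t the step thickness in radiation lengths; clamped at zero where the
#' logarithmic term would drive it negative (very thin steps).
#'
#' @param T Kinetic energy in MeV.
#' @param step_length Step length in mm.
#' @param material A [beta_material()].
#' @return Scattering width in radians.
#' @export
highland_sigma <- function(T, step_length, material = beta_material("water")) {
  if (any(step_length <= 0)) stop("step_length must be positive")
  if (any(T <= 0)) stop("kinetic energy must be positive")
  p <- momentum_from_kinetic(T)
  beta <- p / (T + .me)
  t <- step_length * material$density / 10 / material$radiation_length
  pmax(0, 13.6 / (beta * p) * sqrt(t) * (1 + 0.038 * log(t)))
}

#' Unnormalised allowed beta spectrum of yttrium-90
#'
#' Allowed shape N(T) = p E_tot (Q - T)^2 F(Z, E) with endpoint
#' Q = 2.28 MeV, daughter Z = 40, and the non-relativistic Fermi function
#' F = 2 pi eta / (1 - exp(-2 pi eta)), eta = Z alpha E_tot / p, which
#' accounts for the Coulomb attraction of the emitted electron by the
#' daughter nucleus.
#'
#' @param T Kinetic energies in MeV.
#' @param endpoint Endpoint (Q) energy in MeV.
#' @param Z Atomic number of the daughter nucleus.
#' @param fermi Apply the Fermi Coulomb correction? Disabling it hardens the
#'   spectrum (larger mean energy).
#' @return Unnormalised density values; zero outside (0, endpoint).
#' @export
y90_spectrum_density <- function(T, endpoint = 2.28, Z = 40, fermi = TRUE) {
  d <- numeric(length(T))
  ok <- T > 0 & T < endpoint
  Tk <- T[ok]
  E <- Tk + .me
  p <- sqrt(E^2 - .me^2)
  w <- p * E * (endpoint - Tk)^2
  if (fermi) {
    eta <- Z / 137.035999 * E / p
    w <- w * 2 * pi * eta / (1 - exp(-2 * pi * eta))
  }
  d[ok] <- w
  d
}

#' Sample beta energies from the Y-90 spectrum
#'
#' Rejection sampling against the analytic allowed density with a precomputed
#' constant envelope, so the draw is exact (no tabulation error) and
#' reproducible for a fixed seed.
#'
#' @param n Number of energies to draw.
#' @param seed Integer seed; the draw is bit-reproducible for a fixed seed.
#' @param endpoint,Z,fermi Passed to [y90_spectrum_density()].
#' @return Numeric vector of kinetic energies in MeV, all in (0, endpoint).
#' @examples
#' e <- sample_y90_spectrum(1e4, seed = 1)
#' mean(e)  # about 0.95 MeV
#' @export
sample_y90_spectrum <- function(n, seed = 1, endpoint = 2.28, Z = 40,
                                fermi = TRUE) {
  if (n < 1) stop("n must be >= 1")
  grid <- seq(1e-4, endpoint - 1e-4, length.out = 4096)
  envelope <- 1.02 * max(y90_spectrum_density(grid, endpoint, Z, fermi))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 2.5) + 100
    Tc <- runif(m, 0, endpoint)
    u <- runif(m, 0, envelope)
    acc <- u < y90_spectrum_density(Tc, endpoint, Z, fermi)
    out <- c(out, Tc[acc])
  }
  out[seq_len(n)]
}
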