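# Build a hit_cloud by hand from explicit coordinates, for analysis-stage
# tests that must not depend on the transport engine.
make_cloud <- function(x, y, z, energy = rep(1, length(x)),
                       source_energy = 1, n_particles = length(x),
                       sphere_radius = 15, B = 0, seed = 1L) {
  hits <- data.frame(particle_id = seq_along(x), x = x, y = y, z = z,
                     energy = energy)
  cfg <- structure(list(source_energy = source_energy,
                        n_particles = as.integer(n_particles), B = B,
                        B_axis = c(1, 0, 0), sphere_radius = sphere_radius,
                        seed = seed),
                   class = "transport_config")
  particles <- data.frame(particle_id = seq_along(x),
                          initial_energy = energy, deposited = energy,
                          escaped_energy = rep(0, length(x)),
                          escaped = rep(FALSE, length(x)),
                          final_x = x, final_y = y, final_z = z)
  structure(list(hits = hits, particles = particles, config = cfg),
            class = "hit_cloud")
}

# Mean final radial displacement of the stopping points of a cloud.
final_radius <- function(cloud) {
  with(cloud$particles, sqrt(final_x^2 + final_y^2 + final_z^2))
}
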