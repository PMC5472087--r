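test_that("helix_advance reduces to straight lines without perpendicular momentum", {
  s <- particle_state(c(1, 2, 3), c(0.3, -0.5, 0.8), 1.3)
  out <- helix_advance(s, c(0, 0, 0), 2.5)
  expect_equal(out$position, s$position + 2.5 * s$direction, tolerance = 1e-12)
  expect_equal(out$direction, s$direction, tolerance = 1e-12)
  # motion parallel to B is unaffected by the field strength
  s2 <- particle_state(c(0, 0, 0), c(1, 0, 0), 2)
  out2 <- helix_advance(s2, c(3, 0, 0), 1.7)
  expect_equal(out2$position, c(1.7, 0, 0), tolerance = 1e-12)
  expect_equal(out2$direction, c(1, 0, 0), tolerance = 1e-12)
})

test_that("helix_advance agrees with the closed-form circle oracle", {
  T <- 2; B <- 2
  r <- gyroradius(T, B)
  n_steps <- 36                # even count so the arc samples phi = pi exactly
  arc <- 2 * pi * r / n_steps  # one full gyro-period in total
  fix <- generate_helix_fixture(T, B, n_steps, step_length = arc,
                                direction = c(0, 0, 1), B_axis = c(1, 0, 0))
  s <- particle_state(c(0, 0, 0), c(0, 0, 1), T)
  for (k in seq_len(n_steps)) {
    s <- helix_advance(s, c(B, 0, 0), arc)
    expect_equal(s$position, fix[k + 1, ], tolerance = 1e-9)
  }
  # after one period the direction returns and the perpendicular extent is 2r
  expect_equal(s$direction, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(s$position, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(diff(range(fix[, 2])), 2 * r, tolerance = 1e-6)
})

test_that("a particle born below the cutoff deposits everything at the source", {
  cfg <- transport_config(1, 1, seed = 3)
  cl <- transport_particle(particle_state(c(1, 0, 0), c(0, 0, 1), 0.005), cfg)
  expect_equal(nrow(cl$hits), 1L)
  expect_equal(cl$hits$energy, 0.005)
  expect_equal(unlist(cl$hits[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 0, 0))
})

test_that("scatter-free zero-field transport travels the CSDA range", {
  cfg <- transport_config(1, 1, B = 0, seed = 5, scattering = FALSE)
  cl <- transport_particle(particle_state(c(0, 0, 0), c(0, 1, 0), 1), cfg)
  expect_equal(final_radius(cl), csda_range(1), tolerance = 0.1)
  expect_equal(cl$hits$x, rep(0, nrow(cl$hits)))
})

test_that("scatter-free helical transport is confined near the field axis", {
  cfg <- transport_config(2, 1, B = 3, seed = 5, scattering = FALSE)
  cl <- transport_particle(particle_state(c(0, 0, 0), c(0, 0, 1), 2), cfg)
  perp <- sqrt(cl$hits$y^2 + cl$hits$z^2)
  expect_lte(max(perp), 2 * gyroradius(2, 3) + cfg$max_step)
})

test_that("histories are reproducible and independent of batch size", {
  cfg <- transport_config(0.5, 50, B = 1.5, seed = 42)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$hits, b$hits)
  # per-particle substreams: particle 3 is the same in a 3- and a 5-history run
  c3 <- run_simulation(transport_config(0.5, 3, B = 1.5, seed = 42))
  c5 <- run_simulation(transport_config(0.5, 5, B = 1.5, seed = 42))
  h3 <- c3$hits[c3$hits$particle_id == 3, ]; rownames(h3) <- NULL
  h5 <- c5$hits[c5$hits$particle_id == 3, ]; rownames(h5) <- NULL
  expect_equal(h3, h5)
})

test_that("hits respect the CSDA range bound and isotropy at zero field", {
  cl <- run_simulation(transport_config(2, 2000, B = 0, seed = 9))
  r <- with(cl$hits, sqrt(x^2 + y^2 + z^2))
  expect_lte(max(r), csda_range(2) + cl$config$max_step)
  # per-history mean positions average to the origin within 3 standard errors
  pm <- aggregate(cl$hits[c("x", "y", "z")], list(cl$hits$particle_id), mean)
  for (ax in c("x", "y", "z")) {
    se <- sd(pm[[ax]]) / sqrt(nrow(pm))
    expect_lt(abs(mean(pm[[ax]])), 3 * se)
  }
})

test_that("energy is conserved history by history", {
  # small sphere forces escapes, so both termination branches are exercised
  cfg <- transport_config("Y90", 400, B = 2, sphere_radius = 3, seed = 13)
  cl <- run_simulation(cfg)
  p <- cl$particles
  expect_true(any(p$escaped))
  expect_true(any(!p$escaped))
  expect_lt(max(abs(p$initial_energy - p$deposited - p$escaped_energy)), 1e-6)
  dep <- tapply(cl$hits$energy, cl$hits$particle_id, sum)
  expect_equal(as.numeric(dep[as.character(p$particle_id[p$deposited > 0])]),
               p$deposited[p$deposited > 0], tolerance = 1e-9)
  expect_true(all(with(cl$hits, sqrt(x^2 + y^2 + z^2)) <= 3))
})

test_that("one condensed step deposits S(T) times the step length", {
  cfg <- transport_config(1, 1, B = 0, seed = 1, scattering = FALSE)
  cl <- transport_particle(particle_state(c(0, 0, 0), c(0, 0, 1), 1), cfg)
  expect_equal(cl$hits$energy[1],
               collision_stopping_power(1) * cfg$max_step, tolerance = 1e-9)
})

test_that("per-axis extents are converged in the step controls", {
  base <- run_simulation(transport_config(1, 8000, B = 2, seed = 21))
  fine <- run_simulation(transport_config(1, 8000, B = 2, seed = 21,
                                          max_step = 0.05,
                                          max_frac_eloss = 0.01))
  for (ax in c("x", "y", "z")) {
    e1 <- axis_extent(base, ax)
    e2 <- axis_extent(fine, ax)
    expect_lt(abs(e1 - e2) / e1, 0.02)
  }
})

test_that("transport rejects an initial position outside the sphere", {
  cfg <- transport_config(1, 1, seed = 1)
  expect_error(transport_particle(particle_state(c(20, 0, 0), c(0, 0, 1), 1),
                                  cfg),
               "outside the sphere")
})
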