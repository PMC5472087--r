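test_that("slice/stripe counting matches a brute-force membership oracle", {
  cl <- make_cloud(x = c(0.1, -0.3, 1.2), y = c(0.02, 0.03, 1.01),
                   z = c(0.3, 0.6, -0.2), sphere_radius = 15)
  spec <- slice_spec()
  counts <- slice_and_count(cl, spec)
  # brute force: loop every hit over every slice/stripe definition
  centers <- seq(-15, 15, by = spec$slice_spacing)
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    n <- 0
    for (k in seq_len(nrow(cl$hits))) {
      h <- cl$hits[k, ]
      in_slice <- abs(h$y - row$slice_center) <= spec$slice_thickness / 2
      v <- h[[row$axis]]
      in_stripe <- v >= row$stripe_center - spec$stripe_width / 2 &&
        v < row$stripe_center + spec$stripe_width / 2
      if (in_slice && in_stripe) n <- n + 1
    }
    expect_equal(row$count, n)
  }
  # spot-check hand-derived values
  s0x <- counts[counts$slice_center == 0 & counts$axis == "x", ]
  expect_setequal(s0x$stripe_center, c(-0.5, 0))
  expect_true(all(s0x$count == 1))
  s0z <- counts[counts$slice_center == 0 & counts$axis == "z", ]
  expect_equal(s0z$count[s0z$stripe_center == 0.5], 2)
  expect_equal(sum(counts$count[counts$slice_center == 1 & counts$axis == "x"]), 1)
})

test_that("stripe counts are additive and handle empty selections", {
  cl <- make_cloud(x = c(0.1, -0.3), y = c(0.02, 0.03), z = c(0.3, 0.6))
  doubled <- make_cloud(x = rep(cl$hits$x, 2), y = rep(cl$hits$y, 2),
                        z = rep(cl$hits$z, 2))
  c1 <- slice_and_count(cl); c2 <- slice_and_count(doubled)
  merged <- merge(c1, c2, by = c("slice_center", "axis", "stripe_center"))
  expect_equal(merged$count.y, 2 * merged$count.x)
  # hits between the slice bands: no counts anywhere
  off <- make_cloud(x = 0, y = 0.4, z = 0)
  expect_equal(nrow(slice_and_count(off)), 0L)
  empty <- make_cloud(numeric(0), numeric(0), numeric(0))
  expect_error(slice_and_count(empty), "empty")
})

test_that("axis_extent recovers percentiles of |coordinate|", {
  cl <- make_cloud(x = c(-3, 0, 3), y = c(0, 0, 0), z = c(1, 1, 1))
  expect_equal(axis_extent(cl, "x", 100), 3)
  two <- make_cloud(x = c(-1.7, 1.7), y = c(0, 0), z = c(0, 0))
  expect_equal(axis_extent(two, "x", 50), 1.7)
  expect_error(axis_extent(cl, "x", 0), "percentile")
})

test_that("interaction volume recovers synthetic ellipsoid ground truth", {
  cl <- generate_ellipsoid_hit_cloud(c(2, 5, 5), 1e5, "uniform", seed = 4)
  v <- interaction_volume(cl, percentile = 100)
  expect_equal(v$extent_x, 2, tolerance = 0.02)
  expect_equal(v$extent_y, 5, tolerance = 0.02)
  expect_equal(v$extent_z, 5, tolerance = 0.02)
  expect_equal(v$volume, 4 / 3 * pi * 2 * 5 * 5, tolerance = 0.06)
  expect_equal(v$volume, 4 / 3 * pi * v$extent_x * v$extent_y * v$extent_z,
               tolerance = 1e-12)
  # spherical cloud
  sp <- generate_ellipsoid_hit_cloud(c(3, 3, 3), 2e4, "uniform", seed = 5)
  expect_equal(interaction_volume(sp, 100)$volume, 4 / 3 * pi * 27,
               tolerance = 0.08)
})

test_that("volumes scale with the cube of a coordinate scaling", {
  cl <- generate_ellipsoid_hit_cloud(c(1, 2, 3), 5000, seed = 6)
  scaled <- cl
  scaled$hits[c("x", "y", "z")] <- 2.5 * scaled$hits[c("x", "y", "z")]
  expect_equal(interaction_volume(scaled, 99.5)$volume,
               2.5^3 * interaction_volume(cl, 99.5)$volume, tolerance = 1e-9)
})

test_that("volume_ratio is 1 for identical clouds and guards energy mismatch", {
  cl <- generate_ellipsoid_hit_cloud(c(2, 2, 2), 2000, seed = 7)
  expect_equal(volume_ratio(cl, cl), 1.0)
  a <- make_cloud(1:3, 1:3, 1:3, source_energy = 1)
  b <- make_cloud(1:3, 1:3, 1:3, source_energy = 2)
  expect_error(volume_ratio(a, b), "different source energies")
})

test_that("center_hit_ratio counts the central stripe correctly", {
  inside <- make_cloud(x = c(0.1, -1, 2), y = c(0.01, 0.02, -0.01),
                       z = c(0.1, -0.2, 0.0))
  expect_equal(center_hit_ratio(inside, inside), 1.0)
  expect_equal(center_hit_ratio(inside, inside, stripe_axis = "x"), 1.0)
  # all field-run hits outside the central region -> ratio 0
  outside <- make_cloud(x = c(5, 6, 7), y = c(3, 3, 3), z = c(5, 5, 5))
  expect_equal(center_hit_ratio(outside, inside), 0)
  # zero reference denominator -> error
  expect_error(center_hit_ratio(inside, outside), "zero hits")
  # spherical central region override
  expect_equal(center_hit_ratio(inside, inside, central_region_radius = 0.5), 1.0)
  uneq <- make_cloud(x = 0, y = 0, z = 0)
  expect_error(center_hit_ratio(uneq, inside), "equal n_particles")
})

test_that("stripe-count files are written one per slice with the data intact", {
  cl <- make_cloud(x = c(0.1, -0.3, 1.2), y = c(0.02, 0.03, 1.01),
                   z = c(0.3, 0.6, -0.2))
  counts <- slice_and_count(cl)
  dir <- tempfile("stripes")
  paths <- write_stripe_counts(counts, dir)
  expect_length(paths, length(unique(counts$slice_center)))
  back <- read.csv(paths[1])
  expect_true(all(c("slice_center", "axis", "stripe_center", "count") %in%
                    names(back)))
})
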