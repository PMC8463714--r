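test_that("indexed nearest-point queries match the brute-force scan", {
  for (seed in 1:5) {
    mesh <- random_bumpy_mesh(seed)
    pts <- withr::with_seed(100 + seed,
                            matrix(runif(200 * 3, -60, 60), ncol = 3))
    nn <- nearest_on_surface(pts, mesh)
    for (i in seq_len(nrow(pts))) {
      bf <- brute_force_nearest(pts[i, ], mesh)
      expect_equal(nn$distance[i], bf$distance, tolerance = 1e-9)
    }
  }
})

test_that("nearest-point basics: on-surface points and radial geometry", {
  s <- icosphere(3, 50)
  nn <- nearest_on_surface(s$vertices[c(1, 10, 100), ], s)
  expect_true(all(nn$distance < 1e-12))

  out <- nearest_on_surface(rbind(c(0, 0, 60)), s)
  expect_equal(out$distance, 10, tolerance = 0.1)
  expect_equal(out$closest_z, 50, tolerance = 0.2)
  expect_lt(abs(out$closest_x), 1)
})

test_that("signed MMD is zero for identical meshes", {
  cast <- fixture_cast()
  map <- signed_mmd(cast, cast)
  expect_true(all(abs(map$values) < 1e-9))
})

test_that("concentric spheres give a uniform +2 mm addition field", {
  pre <- icosphere(4, 50)
  post <- icosphere(4, 52)
  map <- signed_mmd(pre, post)
  expect_true(all(map$values > 0))
  expect_lt(max(abs(map$values - 2)), 0.04) # within 2 %
  s <- summarize_mmd(map)
  expect_equal(s$pmmd, 2, tolerance = 0.02)
  expect_equal(s$pmmd, s$mmmd, tolerance = 1e-12)
  expect_true(is.na(s$nmmd))
  expect_equal(s$n_negative, 0L)

  # deflation gives the mirrored subtraction field
  map_rev <- signed_mmd(post, pre)
  expect_true(all(map_rev$values < 0))
  expect_equal(summarize_mmd(map_rev)$nmmd, 2, tolerance = 0.02)
})

test_that("a planted outward bump is recovered at its amplitude, far side untouched", {
  pre <- icosphere(4, 50)
  planted <- plant_modifications(
    pre, list(list(center = c(0, 0, 50), radius = 30, amplitude = 3)))
  map <- signed_mmd(pre, planted$mesh)
  expect_equal(max(map$values), 3, tolerance = 0.05)
  far <- map$values[pre$vertices[, 3] < 0]
  expect_true(all(abs(far) < 1e-9))
  # recovered field tracks the planted one
  expect_lt(sqrt(mean((map$values - planted$ground_truth)^2)), 0.1)
})

test_that("summary arithmetic follows the stated definitions", {
  fake_map <- structure(
    list(base = cube_mesh(1), values = c(2, 2, -1, -1, 0),
         query = matrix(0, 5, 3), direction_convention = "positive = addition",
         n_sign_fallback = 0L, n_undecided = 0L),
    class = "mmd_map")
  s <- summarize_mmd(fake_map)
  expect_equal(s$pmmd, 2)
  expect_equal(s$nmmd, 1)
  expect_equal(s$mmmd, 1.2)
  expect_equal(s$max_pmmd, 2)
  expect_equal(s$max_nmmd, 1)
  expect_equal(s$n_positive, 2L)
  expect_equal(s$n_negative, 2L)
  expect_equal(s$n_total, 5L)

  # ordering invariant whenever both signs occur
  expect_true(min(s$pmmd, s$nmmd) <= s$mmmd + 1e-12)
  expect_true(s$mmmd <= max(s$pmmd, s$nmmd) + 1e-12)

  # all-positive map: nmmd absent rather than zero
  pos_map <- fake_map
  pos_map$values <- c(1, 2, 3)
  s2 <- summarize_mmd(pos_map)
  expect_true(is.na(s2$nmmd))
  expect_true(is.na(s2$max_nmmd))
})

test_that("bidirectional pooling agrees with one-way at matched resolution and is antisymmetric", {
  pre <- icosphere(4, 50)
  planted <- plant_modifications(
    pre, list(list(center = c(0, 0, 50), radius = 30, amplitude = 3)))
  post <- planted$mesh
  fwd <- signed_mmd(pre, post)
  rev <- signed_mmd(post, pre)
  one <- summarize_mmd(fwd)
  bi <- summarize_mmd(fwd, rev, mode = "bidirectional")
  expect_equal(bi$pmmd, one$pmmd, tolerance = 0.05)
  expect_equal(bi$mmmd, one$mmmd, tolerance = 0.05)
  expect_equal(bi$n_total, 2L * one$n_total)
  # swapping roles negates the mean signed value (cross-sampling tolerance)
  expect_equal(mean(rev$values), -mean(fwd$values), tolerance = 0.05)
  expect_error(summarize_mmd(fwd, mode = "bidirectional"), "reverse_map")
})

test_that("MMD summaries are invariant when both meshes move rigidly together", {
  pre <- icosphere(3, 50)
  planted <- plant_modifications(
    pre, list(list(center = c(0, 0, 50), radius = 30, amplitude = 3)))
  t <- rigid_transform(rotation_about(c(1, 1, 0), 35), c(20, -10, 5))
  s0 <- summarize_mmd(signed_mmd(pre, planted$mesh))
  s1 <- summarize_mmd(signed_mmd(apply_transform(pre, t),
                                 apply_transform(planted$mesh, t)))
  expect_equal(s1$pmmd, s0$pmmd, tolerance = 1e-9)
  expect_equal(s1$mmmd, s0$mmmd, tolerance = 1e-9)
  expect_equal(s1$n_positive, s0$n_positive)
  expect_equal(s1$n_negative, s0$n_negative)
})

test_that("map export writes diverging colours, an mmd property and a CSV", {
  td <- withr::local_tempdir()
  s <- icosphere(2, 30)
  vals <- numeric(nrow(s$vertices))
  vals[1] <- 1.7
  vals[2] <- -1.7
  map <- structure(list(base = s, values = vals, query = s$vertices,
                        direction_convention = "positive = addition",
                        n_sign_fallback = 0L, n_undecided = 0L),
                   class = "mmd_map")
  out <- export_map(map, file.path(td, "map.ply"))
  expect_equal(out$color_range, 2) # 1.7 rounded up to the next 0.5
  back <- read_mesh(file.path(td, "map.ply"))
  expect_equal(attr(back, "vertex_scalars")$mmd, vals, tolerance = 1e-7)
  csv <- read.csv(file.path(td, "map.csv"))
  expect_equal(nrow(csv), nrow(s$vertices))
  expect_equal(csv$value, vals, tolerance = 1e-12)

  col <- map_colors(c(-2, 0, 2), color_range = 2)
  expect_equal(col$rgb[1, ], c(0, 0, 255))   # pure blue at -range
  expect_equal(col$rgb[2, ], c(255, 255, 255))
  expect_equal(col$rgb[3, ], c(255, 0, 0))   # pure red at +range
  expect_error(export_map(map, file.path(td, "map.stl")), "STL")
})
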