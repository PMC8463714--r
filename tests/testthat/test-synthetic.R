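test_that("generated casts are watertight, deterministic and child-scaled", {
  cast <- fixture_cast()
  m <- mesh_metrics(cast)
  expect_true(m$is_watertight)
  expect_gt(m$enclosed_volume, 0)
  # same parameters, same mesh, bitwise
  cast2 <- make_cast()
  expect_identical(cast$vertices, cast2$vertices)
  expect_identical(cast$faces, cast2$faces)
  # frame conventions: foot towards +x, sole at z = 0, shank up
  expect_equal(min(cast$vertices[, 3]), 0, tolerance = 1e-9)
  expect_gt(max(cast$vertices[, 1]), 150)
  expect_gt(max(cast$vertices[, 3]), 250)
})

test_that("refining the cast resolution preserves the shape", {
  coarse <- make_cast(resolution = 6)
  fine <- make_cast(resolution = 3)
  expect_gt(nrow(fine$faces), nrow(coarse$faces))
  v1 <- mesh_metrics(coarse)$enclosed_volume
  v2 <- mesh_metrics(fine)$enclosed_volume
  expect_lt(abs(v2 / v1 - 1), 0.005)
})

test_that("invalid cast parameters are refused", {
  expect_error(make_cast(resolution = 10), "too coarse")
  expect_error(make_cast(leg_length = -1), "positive")
})

test_that("zero-amplitude modification specs are identity with zero truth", {
  cast <- fixture_cast()
  out <- plant_modifications(cast, list(), plantar_depth = NULL)
  expect_identical(out$mesh$vertices, cast$vertices)
  expect_true(all(out$ground_truth == 0))
})

test_that("patch displacement peaks at its amplitude and respects the envelope", {
  cast <- fixture_cast()
  out <- plant_modifications(cast,
                             list(list(center = "calf", radius = 45, amplitude = 3)))
  expect_equal(max(out$ground_truth), 3, tolerance = 0.02)
  expect_true(all(out$ground_truth >= 0))
  expect_error(
    plant_modifications(cast, list(list(center = "calf", radius = 45,
                                        amplitude = 12))),
    "envelope")
  expect_error(
    plant_modifications(cast, list(list(center = "calf", radius = 2,
                                        amplitude = 3))),
    "self-intersect")
})

test_that("plantar flattening bounds its ground truth by the cut depth", {
  cast <- fixture_cast()
  out <- plant_modifications(cast, plantar_depth = 2)
  gt <- out$ground_truth
  expect_true(all(gt <= 0))
  expect_true(all(gt >= -2 - 1e-9))
  expect_gt(sum(gt < 0), 10) # a real strip of sole was flattened
  expect_equal(min(out$mesh$vertices[, 3]), 2, tolerance = 1e-9)
})

test_that("planting then mapping closes the loop on the ground truth", {
  cast <- fixture_cast()
  out <- plant_modifications(cast,
                             list(list(center = "calf", radius = 45, amplitude = 3)),
                             plantar_depth = 2)
  map <- signed_mmd(cast, out$mesh)
  expect_lt(sqrt(mean((map$values - out$ground_truth)^2)), 0.1)
  expect_equal(max(map$values), 3, tolerance = 0.05 * 3)
})

test_that("pose perturbation applies the reported transform plus jitter", {
  cast <- fixture_cast()
  p0 <- perturb_mesh(cast)
  expect_identical(p0$mesh$vertices, cast$vertices)

  p <- perturb_mesh(cast, rotation_deg = 10, axis = c(0, 0, 1),
                    translation = c(4, 4, -2), noise_sigma = 0.1, seed = 6)
  moved <- apply_transform(cast, p$transform)
  resid <- p$mesh$vertices - moved$vertices
  expect_equal(sd(as.vector(resid)), 0.1, tolerance = 0.05)
  # jitter at 0.1 mm changes the volume by well under 1 %
  expect_lt(abs(mesh_metrics(p$mesh)$enclosed_volume /
                  mesh_metrics(cast)$enclosed_volume - 1), 0.01)
})

test_that("cohort draws are reproducible and follow the clinic proportions", {
  s1 <- simulate_cohort(n = 50, seed = 99)
  s2 <- simulate_cohort(n = 50, seed = 99)
  expect_identical(s1$cohort, s2$cohort)
  expect_true(all(s1$cohort$age >= 1 & s1$cohort$age <= 18))
  h <- s1$cohort$height
  expect_true(all(is.na(h) | (h > 30 & h < 220)))
  expect_equal(sum(is.na(h)), 8L) # 16 % of 50

  # 2,000 draws: multinomial SEs are ~0.01, so +/-0.04 is a ~4 SE band
  big <- simulate_cohort(n = 2000, seed = 123)$cohort
  afo <- table(big$afo_type) / nrow(big)
  expect_lt(abs(afo[["fixed"]] - 30 / 50), 0.04)
  expect_lt(abs(afo[["hinged"]] - 16 / 50), 0.04)
  pat <- table(big$pathology) / nrow(big)
  expect_lt(abs(pat[["CP"]] - 25 / 50), 0.04)
  expect_lt(abs(pat[["Other"]] - 12 / 50), 0.04)
})

test_that("summary-mode cohorts carry coherent MMD summaries", {
  sim <- simulate_cohort(n = 30, seed = 5)
  co <- sim$cohort
  expect_true(all(co$pmmd > 0))
  expect_true(all(co$nmmd > 0))
  expect_true(all(co$max_pmmd >= co$pmmd))
  # mean magnitude sits between the one-signed means
  expect_true(all(co$mmmd <= pmax(co$pmmd, co$nmmd) + 1e-9))
  expect_true(all(co$mmmd >= pmin(co$pmmd, co$nmmd) - 1e-9))
  # pMMD scales monotonically with the planted amplitude at fixed depth
  expect_gt(cor(co$true_amplitude, co$pmmd, method = "spearman"), 0.9)
})

test_that("full-detail cohorts produce registered-comparable mesh pairs", {
  sim <- simulate_cohort(n = 5, seed = 17, mesh_detail = "full",
                         resolution = 6)
  expect_length(sim$pairs, 5L)
  p <- sim$pairs[[2]]
  expect_true(is_watertight(p$pre))
  expect_true(is_watertight(p$post))
  # landmark alignment alone must land close to the true pose
  est <- landmark_align(p$landmarks_pre, p$landmarks_post)
  expect_transform_close(est, p$true_transform, 0.5, 0.5)
})

test_that("calibration hits the requested population correlation", {
  b <- calibrate_height_slope(0.35, sigma = 0.5, n_pop = 20000L, seed = 20L)
  expect_gt(b, 0)
  # verify on an independent large draw
  check <- withr::with_seed(77, {
    age <- runif(20000, 1, 18)
    h <- castmap:::height_from_age(age)
    amp <- b * h + rnorm(20000, sd = 0.5)
    cor(h, amp, method = "spearman")
  })
  expect_equal(check, 0.35, tolerance = 0.05)
})
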