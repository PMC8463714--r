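test_that("Spearman matches hand-ranked and reference computations", {
  expect_equal(spearman_assoc(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_assoc(1:8, -(1:8))$statistic, -1)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # hand computation: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # r_s = 1 - 6*4 / (5 * 24) = 0.8
  r <- spearman_assoc(x, y)
  expect_equal(r$statistic, 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)
  expect_equal(r$statistic, unname(cor(x, y, method = "spearman")),
               tolerance = 1e-12)
  # asymptotic p agrees with cor.test's t approximation
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$statistic, unname(ct$estimate), tolerance = 1e-12)

  # ties handled by mid-ranks, matching base R
  xt <- c(1, 2, 2, 3, 4, 4, 4, 7)
  yt <- c(2, 2, 3, 5, 5, 8, 9, 9)
  expect_equal(spearman_assoc(xt, yt)$statistic,
               unname(cor(xt, yt, method = "spearman")), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  x <- withr::with_seed(1, rnorm(30))
  y <- withr::with_seed(2, rnorm(30))
  r0 <- spearman_assoc(x, y)$statistic
  expect_equal(spearman_assoc(exp(x), y)$statistic, r0, tolerance = 1e-12)
  expect_equal(spearman_assoc(x, y^3 + 5 * y)$statistic, r0, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive enumeration at n = 6", {
  x <- c(3, 9, 1, 7, 5, 11)
  y <- c(2, 10, 3, 6, 4, 12)
  robs <- spearman_assoc(x, y)$statistic
  rx <- rank(x)
  perms <- all_permutations(rank(y))
  ref <- vapply(perms, function(p) cor(rx, p), numeric(1))
  p_exact <- mean(abs(ref) >= abs(robs) - 1e-12)

  p_perm <- spearman_assoc(x, y, p_method = "permutation",
                           n_perm = 20000L, seed = 4)$p_value
  expect_equal(p_perm, p_exact, tolerance = 0.02)
  p_asym <- spearman_assoc(x, y)$p_value
  expect_equal(p_asym, p_exact, tolerance = 0.05)
})

test_that("degenerate correlation inputs are flagged, not computed", {
  r <- spearman_assoc(c(1, 1, 1, 1, 1), c(1, 2, 3, 4, 5))
  expect_true(is.na(r$statistic))
  expect_match(r$note, "zero variance")
  r2 <- spearman_assoc(c(1, 2, NA), c(1, 2, 3))
  expect_match(r2$note, "fewer than 4")
  expect_error(spearman_assoc(1:3, 1:4), "equal length")
})

test_that("association categories follow the stated boundaries", {
  r35 <- classify_association(0.35)
  expect_equal(r35$strength, "fair")
  expect_equal(r35$effect, "medium")
  expect_equal(classify_association(0.18)$strength, "little/none")
  expect_equal(classify_association(0.75)$strength, "excellent")
  expect_equal(classify_association(-0.6)$strength, "moderate")
  expect_equal(classify_association(-0.6)$effect, "large")
  expect_equal(classify_association(0.25)$strength, "fair")
  expect_equal(classify_association(0.30)$effect, "medium")
  expect_equal(classify_association(0.50)$effect, "medium")
  expect_equal(classify_association(0.05)$effect, "none")
  expect_error(classify_association(1.2), "\\[-1, 1\\]")
})

test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: rank means 2, 5, 8
  # H = 12/(9*10) * (3*4 + 3*25 + 3*64) - 3*10 = 7.2, no ties
  r <- kruskal_wallis_assoc(1:9, rep(1:3, each = 3))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)

  # identical group distributions: H = 0, p = 1
  r0 <- kruskal_wallis_assoc(rep(c(4, 4, 4), 3), rep(1:3, each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("Kruskal-Wallis with ties matches base kruskal.test", {
  vals <- c(2, 2, 5, 7, 7, 7, 1, 9, 9, 4, 6, 6, 3, 8, 2)
  grp <- rep(1:3, each = 5)
  mine <- kruskal_wallis_assoc(vals, grp)
  ref <- kruskal.test(vals, grp)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("H is invariant under strictly monotone transforms of the values", {
  vals <- withr::with_seed(5, rnorm(24))
  grp <- rep(1:4, each = 6)
  h0 <- kruskal_wallis_assoc(vals, grp)$statistic
  expect_equal(kruskal_wallis_assoc(exp(vals), grp)$statistic, h0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis_assoc(atan(vals), grp)$statistic, h0,
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis permutation p tracks the chi-square approximation", {
  vals <- withr::with_seed(11, rnorm(30))
  grp <- rep(1:3, each = 10)
  p_chi <- kruskal_wallis_assoc(vals, grp)$p_value
  p_perm <- kruskal_wallis_assoc(vals, grp, p_method = "permutation",
                                 n_perm = 10000L, seed = 12)$p_value
  expect_equal(p_perm, p_chi, tolerance = 0.02)
})

test_that("cohort_report builds the full 12-row association grid", {
  sim <- simulate_cohort(n = 40, seed = 31)
  rep <- cohort_report(sim$cohort)
  expect_equal(nrow(rep), 12L)
  expect_equal(sum(rep$test == "spearman"), 6L)
  expect_equal(sum(rep$test == "kruskal_wallis"), 6L)
  expect_setequal(unique(rep$variable), c("age", "height", "afo_type", "pathology"))
  # pairwise-complete deletion: height rows use fewer records than age rows
  n_height <- rep$n[rep$variable == "height"][1]
  n_age <- rep$n[rep$variable == "age"][1]
  expect_lt(n_height, n_age)
  expect_true(all(rep$n_tests == sum(!is.na(rep$p_value))))
})

test_that("cohort_report survives missing covariates and tiny groups", {
  sim <- simulate_cohort(n = 20, seed = 8)
  rec <- sim$cohort
  rec$height <- NA_real_
  rep <- cohort_report(rec)
  hrows <- rep[rep$variable == "height", ]
  expect_true(all(is.na(hrows$statistic)))
  expect_match(hrows$note[1], "missing")

  rec2 <- sim$cohort
  rec2$afo_type <- c("fixed", rep(c("fixed", "hinged"), length.out = 19))
  rec2$afo_type[1] <- "SMO" # singleton group must be excluded, not crash
  rep2 <- cohort_report(rec2)
  arow <- rep2[rep2$variable == "afo_type" & rep2$outcome == "pmmd", ]
  expect_match(arow$note, "SMO")
  expect_error(cohort_report(sim$cohort[0, ]), "empty")
})

test_that("the planted height effect is detected and the null is calm", {
  b <- calibrate_height_slope(0.35, sigma = 0.5)
  rs <- numeric(40)
  sig <- logical(40)
  for (s in seq_len(40)) {
    sim <- simulate_cohort(n = 50, seed = 500 + s,
                           effect = list(a = 2.4, b = b, sigma = 0.5))
    r <- spearman_assoc(sim$cohort$height, sim$cohort$pmmd)
    rs[s] <- r$statistic
    sig[s] <- r$p_value < 0.05
  }
  expect_gt(mean(rs), 0.25)
  expect_lt(mean(rs), 0.45)
  expect_true(all(rs > -0.1))
  # power at rho = 0.35, n = 42 is ~0.6; require clearly-above-null detection
  expect_gt(mean(sig), 0.35)

  rs0 <- vapply(seq_len(40), function(s) {
    sim <- simulate_cohort(n = 50, seed = 900 + s,
                           effect = list(a = 2.4, b = 0, sigma = 0.5))
    spearman_assoc(sim$cohort$height, sim$cohort$pmmd)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs0)), 0.08)
})
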