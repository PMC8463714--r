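test_that("identical sessions give ICC exactly 1 in both forms", {
  m <- cbind(c(9.2, 8.1, 7.4, 6.9, 11.3), c(9.2, 8.1, 7.4, 6.9, 11.3))
  fit <- icc_single_absolute(m)
  expect_identical(fit$icc, 1)
  expect_identical(fit$icc_consistency, 1)
  expect_false(fit$degenerate)
})

test_that("all-equal cells are flagged degenerate with ICC defined as 1", {
  fit <- icc_single_absolute(matrix(5, 4, 2))
  expect_identical(fit$icc, 1)
  expect_true(fit$degenerate)
})

test_that("ICC matches the explicit-sums ANOVA oracle", {
  for (seed in 1:25) {
    m <- withr::with_seed(seed, matrix(runif(12, 10, 20), nrow = 6, ncol = 2))
    fit <- icc_single_absolute(m)
    ora <- icc_oracle(m)
    expect_equal(fit$icc, ora$icc_agreement, tolerance = 1e-10)
    expect_equal(fit$icc_consistency, ora$icc_consistency, tolerance = 1e-10)
    expect_equal(fit$msr, ora$msr, tolerance = 1e-10)
    expect_equal(fit$msc, ora$msc, tolerance = 1e-10)
    expect_equal(fit$mse, ora$mse, tolerance = 1e-8)
  }
})

test_that("ICC mean squares agree with a two-way aov fit", {
  m <- withr::with_seed(3, matrix(rnorm(20, 100, 5), nrow = 10, ncol = 2))
  fit <- icc_single_absolute(m)
  d <- data.frame(value = as.vector(m),
                  subject = factor(rep(1:10, 2)),
                  session = factor(rep(1:2, each = 10)))
  ms <- summary(aov(value ~ subject + session, data = d))[[1]][["Mean Sq"]]
  expect_equal(fit$msr, ms[1], tolerance = 1e-10)
  expect_equal(fit$msc, ms[2], tolerance = 1e-10)
  expect_equal(fit$mse, ms[3], tolerance = 1e-10)
})

test_that("a constant session offset separates agreement from consistency", {
  base <- c(12, 15, 9, 20, 17, 11)
  m <- cbind(base, base + 3)
  fit <- icc_single_absolute(m)
  expect_identical(fit$icc_consistency, 1)
  expect_lt(fit$icc, 1)
})

test_that("both ICC forms are invariant to shift and positive scaling", {
  m <- withr::with_seed(8, matrix(rnorm(16, 50, 4), nrow = 8, ncol = 2))
  f0 <- icc_single_absolute(m)
  f_shift <- icc_single_absolute(m + 100)
  f_scale <- icc_single_absolute(m * 3.7)
  expect_equal(f_shift$icc, f0$icc, tolerance = 1e-9)
  expect_equal(f_scale$icc, f0$icc, tolerance = 1e-9)
  expect_equal(f_shift$icc_consistency, f0$icc_consistency, tolerance = 1e-9)
  expect_equal(f_scale$icc_consistency, f0$icc_consistency, tolerance = 1e-9)
})

test_that("session offsets penalise agreement but never consistency", {
  # in the reliability regime (real subject signal, MSR > MSE) agreement
  # cannot exceed consistency whenever the estimated session variance
  # component is non-negative (MSC >= MSE); a session offset then always
  # costs agreement while leaving consistency untouched
  for (seed in 1:30) {
    subj <- withr::with_seed(200 + seed, rnorm(7, 30, 10))
    m <- cbind(subj, subj) + withr::with_seed(300 + seed,
                                              matrix(rnorm(14, 0, 1), 7, 2))
    fit <- icc_single_absolute(m)
    if (fit$msc >= fit$mse) {
      expect_lte(fit$icc, fit$icc_consistency + 1e-12)
    }
    fit_off <- icc_single_absolute(m + cbind(0, rep(10, 7)))
    expect_lte(fit_off$icc, fit_off$icc_consistency + 1e-12)
    expect_lt(fit_off$icc, fit$icc)
    expect_equal(fit_off$icc_consistency, fit$icc_consistency, tolerance = 1e-9)
  }
})

test_that("percentage error follows the symmetric-mean formula", {
  expect_identical(percentage_error(100, 100), 0)
  expect_equal(percentage_error(100, 101), 100 * 1 / 100.5, tolerance = 1e-12)
  expect_equal(percentage_error(101, 100), percentage_error(100, 101))
  expect_equal(percentage_error(50, 51), 100 * 1 / 50.5, tolerance = 1e-12)
  expect_error(percentage_error(0, 1), "positive")
  expect_error(percentage_error(10, -1), "positive")
})

test_that("reliability_report: exact replicates give ICC 1 and zero error", {
  base <- data.frame(subject = rep(1:5, times = 2),
                     measure = rep(c("volume", "area"), each = 5),
                     value = c(1000, 600, 1420, 810, 995,
                               640, 1210, 702, 1500, 590))
  d <- rbind(transform(base, session = 1), transform(base, session = 2))
  rep <- reliability_report(d)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$icc == 1))
  expect_true(all(rep$pct_error_mean == 0))
})

test_that("0.3 % multiplicative noise produces the expected error regime", {
  vols <- c(5e5, 7e5, 9e5, 1.1e6, 1.3e6, 1.5e6, 1.7e6, 2e6, 2.4e6, 2.8e6)
  pe <- numeric(50)
  icc <- numeric(50)
  for (s in 1:50) {
    noisy <- withr::with_seed(s, vols * (1 + matrix(rnorm(20, sd = 0.003), 10, 2)))
    d <- data.frame(subject = rep(1:10, 2), session = rep(1:2, each = 10),
                    measure = "volume", value = as.vector(noisy))
    r <- reliability_report(d)
    pe[s] <- r$pct_error_mean
    icc[s] <- r$icc
  }
  expect_gt(mean(pe), 0.2)
  expect_lt(mean(pe), 0.5)
  expect_gt(mean(icc), 0.99)
})

test_that("reliability_report validates its input", {
  expect_error(reliability_report(data.frame(subject = 1, session = 1,
                                             measure = "v", value = 1)),
               "fewer than 2")
  expect_error(reliability_report(data.frame(x = 1)), "columns")
})
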