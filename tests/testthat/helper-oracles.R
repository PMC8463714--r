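# Independent oracles and shared fixtures for the test suite. Oracles use a
# different formulation than the implementation on purpose (brute-force scans,
# explicit double-loop sums, exhaustive enumeration).

# memoised expensive fixtures (persist across test files within one run)
.fixture_env <- new.env(parent = emptyenv())

fixture_cast <- function() {
  if (is.null(.fixture_env$cast)) .fixture_env$cast <- make_cast()
  .fixture_env$cast
}

# ---- brute-force point-to-mesh distance -----------------------------------
# Barycentric projection + edge clamping, vectorised over all triangles for
# one query point: structurally different from the BVH kernel's Voronoi-region
# walk, and with no spatial pruning.

.seg_dist2 <- function(p, a, b) {
  ab <- b - a
  ap <- sweep(a, 2, p, "-") * -1
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), .Machine$double.xmin)
  t <- pmin(pmax(t, 0), 1)
  d <- ap - ab * t
  rowSums(d^2)
}

brute_force_nearest <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e0 <- b - a
  e1 <- cc - a
  w <- sweep(a, 2, p, "-") * -1
  d00 <- rowSums(e0^2)
  d01 <- rowSums(e0 * e1)
  d11 <- rowSums(e1^2)
  dv0 <- rowSums(w * e0)
  dv1 <- rowSums(w * e1)
  denom <- d00 * d11 - d01^2
  u <- (d11 * dv0 - d01 * dv1) / denom
  s <- (d00 * dv1 - d01 * dv0) / denom
  inside <- is.finite(u) & is.finite(s) & u >= 0 & s >= 0 & (u + s) <= 1
  resid <- w - e0 * u - e1 * s
  d2 <- rowSums(resid^2)
  d2_edge <- pmin(.seg_dist2(p, a, b), .seg_dist2(p, b, cc), .seg_dist2(p, a, cc))
  d2[!inside] <- d2_edge[!inside]
  list(distance = sqrt(min(d2)), triangle = which.min(d2))
}

# ---- explicit-sums two-way ANOVA / ICC oracle ------------------------------

icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  g <- 0
  for (i in 1:n) for (j in 1:k) g <- g + m[i, j]
  g <- g / (n * k)
  ssr <- 0
  for (i in 1:n) {
    rm <- 0
    for (j in 1:k) rm <- rm + m[i, j]
    ssr <- ssr + k * (rm / k - g)^2
  }
  ssc <- 0
  for (j in 1:k) {
    cm <- 0
    for (i in 1:n) cm <- cm + m[i, j]
    ssc <- ssc + n * (cm / n - g)^2
  }
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - g)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  list(
    msr = msr, msc = msc, mse = mse,
    icc_agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    icc_consistency = (msr - mse) / (msr + (k - 1) * mse)
  )
}

# ---- exhaustive permutations ----------------------------------------------

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# random closed test mesh: radially jittered icosphere (seeded)
random_bumpy_mesh <- function(seed, subdivisions = 2, radius = 40) {
  s <- icosphere(subdivisions, radius)
  withr::with_seed(seed, {
    r <- 1 + runif(nrow(s$vertices), -0.25, 0.25)
    s$vertices <- s$vertices * r
  })
  validate_mesh(s)
}

expect_transform_close <- function(est, truth, max_deg, max_mm) {
  rot_err <- rotation_angle_deg(t(truth$rotation) %*% est$rotation)
  tr_err <- sqrt(sum((est$translation - truth$translation)^2))
  expect_lt(rot_err, max_deg)
  expect_lt(tr_err, max_mm)
  invisible(c(rot_err, tr_err))
}
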