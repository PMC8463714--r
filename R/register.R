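#' Landmark sets
#'
#' Labelled 3D points (mm) marked on both casts (physical pen marks on the
#' plaster, digitised with the scan). Labels pair the points across the
#' pre/post meshes.
#'
#' @param points numeric matrix (`n x 3`), mm.
#' @param labels character vector of length `n`.
#' @return an object of class `landmark_set` (a tibble with columns `label`,
#'   `x`, `y`, `z`).
#' @export
landmark_set <- function(points, labels) {
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("`points` must have 3 columns")
  if (length(labels) != nrow(points)) abort("one label per point required")
  out <- tibble::tibble(label = as.character(labels),
                        x = points[, 1], y = points[, 2], z = points[, 3])
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read landmarks from CSV
#'
#' Expected columns: `label,x,y,z` (mm).
#' @param path CSV file path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(sprintf("landmark file %s must have columns label,x,y,z", path))
  }
  landmark_set(as.matrix(df[, c("x", "y", "z")]), df$label)
}

lm_matrix <- function(lm) unname(as.matrix(lm[, c("x", "y", "z")]))

# Kabsch: least-squares rotation+translation mapping src -> dst (no scaling,
# reflections excluded by the sign correction on the smallest singular value).
kabsch <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Align landmark sets with a least-squares rigid transform
#'
#' Matches points by label, then solves the orthogonal Procrustes problem
#' (Kabsch, via SVD) for the proper rigid transform minimising the sum of
#' squared distances between matched pairs. At least three non-collinear
#' matched pairs are required to pin down a unique rotation.
#'
#' @param source,target `landmark_set`s (or plain `label,x,y,z` data frames)
#'   for the moving (pre) and fixed (post) casts.
#' @return a `rigid_transform` mapping source to target, with attribute
#'   `"rms_residual"` (mm).
#' @export
landmark_align <- function(source, target) {
  source <- as.data.frame(source)
  target <- as.data.frame(target)
  common <- intersect(source$label, target$label)
  if (length(common) < 3) {
    abort(sprintf("insufficient landmarks: %d matched labels, need >= 3",
                  length(common)))
  }
  src <- as.matrix(source[match(common, source$label), c("x", "y", "z")])
  dst <- as.matrix(target[match(common, target$label), c("x", "y", "z")])
  # collinearity: centered source points must span a plane
  sv <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    abort("degenerate landmark configuration: matched points are collinear")
  }
  t <- kabsch(src, dst)
  res <- transform_points(src, t) - dst
  attr(t, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  t
}

# area-weighted uniform surface sampling; returns an n x 3 point matrix
sample_surface <- function(mesh, n, seed = NULL) {
  draw <- function() {
    areas <- face_areas(mesh$vertices, mesh$faces)
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# principal-axes initialisation: centroid + covariance eigenvectors, trying
# the 4 proper axis-sign hypotheses and keeping the one with lowest median
# nearest-surface distance on a small sample.
principal_axes_init <- function(source, target, seed = 1L) {
  sp <- sample_surface(source, 500L, seed = seed)
  tp <- sample_surface(target, 500L, seed = seed + 1L)
  es <- eigen(stats::cov(sp), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(tp), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_score <- Inf
  cs <- colMeans(sp)
  ct <- colMeans(tp)
  for (fl in flips) {
    R <- et %*% diag(fl) %*% t(es)
    cand <- rigid_transform(R, ct - as.numeric(R %*% cs))
    nn <- cpp_nearest_on_surface(transform_points(sp, cand),
                                 target$vertices, target$faces)
    score <- median(nn$distance)
    if (score < best_score) {
      best_score <- score
      best <- cand
    }
  }
  best
}

#' Refine an alignment with trimmed iterative closest point
#'
#' Point-to-point ICP with trimmed outlier rejection: source surface points
#' (area-uniform sample, seeded) are matched to their nearest points on the
#' target surface, the worst `trim_fraction` of pairs by distance are
#' discarded, and the rigid transform is re-estimated by Kabsch on the
#' survivors. Trimming matters here because the pre- and post-modification
#' casts genuinely differ where plaster was added or removed; discarding the
#' largest residuals keeps those regions from biasing the rigid fit.
#'
#' @param source,target `cast_mesh`es (source moves onto target).
#' @param init initial `rigid_transform`; `NULL` uses [landmark_align()]-style
#'   initialisation from principal axes.
#' @param max_iterations iteration cap.
#' @param convergence_tol_mm stop when the trimmed RMS changes less than this.
#' @param trim_fraction fraction of worst correspondences discarded (0-0.5).
#' @param sample_count number of source surface samples.
#' @param seed RNG seed for the surface sample.
#' @return an object of class `icp_result`: list with `transform`
#'   (`rigid_transform`), `rms_residual` (mm, trimmed), `inlier_fraction`,
#'   `iterations`, `converged`, and the per-iteration `rms_trace`.
#' @export
icp_refine <- function(source, target, init = NULL,
                       max_iterations = 200L, convergence_tol_mm = 1e-4,
                       trim_fraction = 0.2, sample_count = 5000L, seed = 1L) {
  stopifnot(inherits(source, "cast_mesh"), inherits(target, "cast_mesh"))
  if (trim_fraction < 0 || trim_fraction >= 0.95) {
    abort("`trim_fraction` must be in [0, 0.95)")
  }
  if (is.null(init)) init <- principal_axes_init(source, target, seed = seed)
  pts <- sample_surface(source, sample_count, seed = seed)
  keep_n <- max(3L, floor(sample_count * (1 - trim_fraction)))

  t_cur <- init
  rms_prev <- Inf
  rms <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iterations)) {
    moved <- transform_points(pts, t_cur)
    nn <- cpp_nearest_on_surface(moved, target$vertices, target$faces)
    ord <- order(nn$distance)[seq_len(keep_n)]
    if (length(ord) < 3L) abort("degenerate overlap: no samples survive trimming")
    rms <- sqrt(mean(nn$distance[ord]^2))
    trace <- c(trace, rms)
    if (is.finite(rms_prev) && abs(rms_prev - rms) < convergence_tol_mm) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    # re-fit the absolute transform on the kept pairs (original source coords
    # -> current nearest target points), so the composite stays exactly rigid
    t_cur <- kabsch(pts[ord, , drop = FALSE], nn$closest[ord, , drop = FALSE])
  }
  structure(list(transform = t_cur, rms_residual = rms,
                 inlier_fraction = keep_n / sample_count,
                 iterations = it, converged = converged, rms_trace = trace),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %s after %d iterations, trimmed RMS %.4g mm (inliers %.0f%%)\n",
              if (x$converged) "converged" else "stopped", x$iterations,
              x$rms_residual, 100 * x$inlier_fraction))
  print(x$transform)
  invisible(x)
}

#' @method tidy icp_result
#' @export
tidy.icp_result <- function(x, ...) {
  tibble::tibble(
    rotation_deg = rotation_angle_deg(x$transform$rotation),
    translation_mm = sqrt(sum(x$transform$translation^2)),
    rms_residual = x$rms_residual,
    inlier_fraction = x$inlier_fraction,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Register a cast pair
#'
#' Convenience wrapper: landmark initialisation when both landmark sets are
#' given (principal axes otherwise), then trimmed ICP refinement.
#'
#' @inheritParams icp_refine
#' @param landmarks_source,landmarks_target optional `landmark_set`s.
#' @param ... passed to [icp_refine()].
#' @return an `icp_result`.
#' @export
register_pair <- function(source, target, landmarks_source = NULL,
                          landmarks_target = NULL, ...) {
  init <- if (!is.null(landmarks_source) && !is.null(landmarks_target)) {
    landmark_align(landmarks_source, landmarks_target)
  } else {
    NULL
  }
  icp_refine(source, target, init = init, ...)
}
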