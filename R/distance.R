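#' Nearest point on a mesh surface
#'
#' Exact minimum-distance closest point over all triangles of the target,
#' pruned by an axis-aligned bounding-box hierarchy (so it scales to scan
#' resolution meshes while agreeing with a brute-force all-triangle scan to
#' floating-point precision).
#'
#' @param points numeric matrix (`n x 3`) of query points, mm.
#' @param target a `cast_mesh`.
#' @return a tibble: `distance` (mm, unsigned), `triangle` (1-based face id),
#'   `closest_x/y/z`, `bary1/2/3` (barycentric coordinates of the closest
#'   point in its triangle).
#' @export
nearest_on_surface <- function(points, target) {
  stopifnot(inherits(target, "cast_mesh"))
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("`points` must have 3 columns")
  if (nrow(target$faces) == 0L) abort("empty target mesh")
  nn <- cpp_nearest_on_surface(points, target$vertices, target$faces)
  tibble::tibble(
    distance = nn$distance, triangle = nn$triangle,
    closest_x = nn$closest[, 1], closest_y = nn$closest[, 2],
    closest_z = nn$closest[, 3],
    bary1 = nn$bary[, 1], bary2 = nn$bary[, 2], bary3 = nn$bary[, 3]
  )
}

# parity of +x axis ray crossings: TRUE if point inside the watertight mesh.
# Used only as a fallback for the rare queries where the pseudonormal dot
# product is numerically zero.
ray_parity_inside <- function(point, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  # Moller-Trumbore along direction (1, 0, 0), with a tiny direction jitter
  # to dodge edge-on hits
  dir <- c(1, 3.5e-7, 7.1e-7)
  e1 <- b - a
  e2 <- cc - a
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- sweep(a[ok, , drop = FALSE], 2, point, "-") * -1
  pv <- pv[ok, , drop = FALSE]
  e1 <- e1[ok, , drop = FALSE]
  e2 <- e2[ok, , drop = FALSE]
  det <- det[ok]
  u <- rowSums(tv * pv) / det
  qv <- cross3(tv, e1)
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  hits <- u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0
  sum(hits) %% 2L == 1L
}

#' Signed mesh-to-mesh difference (MMD)
#'
#' For every vertex of the pre-modification cast, the Euclidean distance to
#' the post-modification surface, signed by material change: positive where
#' the pre vertex lies inside the post solid (plaster was added over it),
#' negative where it lies outside (plaster was removed). The sign comes from
#' the dot product of the offset vector with the angle-weighted pseudonormal
#' at the closest point on the post surface (face, edge or vertex
#' pseudonormal according to where the closest point falls); when that dot
#' product is numerically zero the inside/outside decision falls back to ray
#' parity if the post mesh is watertight, otherwise the vertex is flagged
#' `NA` and excluded from summaries.
#'
#' @param pre,post `cast_mesh`es already in a common frame (apply the
#'   registration transform to `pre` first).
#' @param registered assertion flag: set `TRUE` once the caller has aligned
#'   the meshes. A warning is emitted when `FALSE`, because an unregistered
#'   comparison conflates pose with modification.
#' @param query_points optional `n x 3` matrix of sample points on `pre` to
#'   use instead of its vertices (for resolution-matched bidirectional
#'   pooling).
#' @return an object of class `mmd_map`: list with `base` (the pre mesh),
#'   `values` (signed mm per query, `NA` where the sign was undecidable),
#'   `query` (the query points), `direction_convention`
#'   (`"positive = addition"`), and `n_sign_fallback` / `n_undecided` counts.
#' @export
signed_mmd <- function(pre, post, registered = TRUE, query_points = NULL) {
  stopifnot(inherits(pre, "cast_mesh"), inherits(post, "cast_mesh"))
  if (!registered) {
    warn("meshes are flagged as unregistered; MMD will mix pose with modification")
  }
  q <- query_points %||% pre$vertices
  nn <- cpp_nearest_on_surface(q, post$vertices, post$faces)
  d <- nn$distance
  offset <- q - nn$closest

  # pick the pseudonormal of the region the closest point falls in
  eps_b <- 1e-9
  bary <- nn$bary
  tri <- nn$triangle
  f <- post$faces
  fn <- face_normals(post)
  n_zero <- (bary < eps_b)
  region <- rowSums(n_zero) # 0 face, 1 edge, 2 vertex
  normals <- fn[tri, , drop = FALSE]
  if (any(region == 1L)) {
    en <- edge_pseudonormals(post)
    idx <- which(region == 1L)
    # the edge opposite the (near-)zero barycentric coordinate
    zc <- max.col(n_zero[idx, , drop = FALSE] + 0, ties.method = "first")
    i1 <- f[cbind(tri[idx], zc %% 3L + 1L)]
    i2 <- f[cbind(tri[idx], (zc + 1L) %% 3L + 1L)]
    key <- paste(pmin(i1, i2), pmax(i1, i2))
    normals[idx, ] <- en$normal[match(key, en$key), , drop = FALSE]
  }
  if (any(region == 2L)) {
    vn <- vertex_pseudonormals(post)
    idx <- which(region == 2L)
    vc <- max.col(bary[idx, , drop = FALSE], ties.method = "first")
    normals[idx, ] <- vn[f[cbind(tri[idx], vc)], , drop = FALSE]
  }

  dot <- rowSums(offset * normals)
  values <- ifelse(dot > 0, -d, d) # outside post => plaster removed => negative
  undecided <- which(abs(dot) < 1e-9 & d > 1e-9)
  n_fallback <- 0L
  n_undecided <- 0L
  if (length(undecided)) {
    if (is_watertight(post)) {
      n_fallback <- length(undecided)
      inside <- vapply(undecided, function(i) ray_parity_inside(q[i, ], post),
                       logical(1))
      values[undecided] <- ifelse(inside, d[undecided], -d[undecided])
    } else {
      n_undecided <- length(undecided)
      values[undecided] <- NA_real_
      warn(sprintf("%d points with undecidable sign on a non-watertight target excluded",
                   n_undecided))
    }
  }
  values[d <= 1e-9] <- 0 # on-surface points carry no modification

  structure(list(base = pre, values = values, query = q,
                 direction_convention = "positive = addition",
                 n_sign_fallback = n_fallback, n_undecided = n_undecided),
            class = "mmd_map")
}

#' @export
print.mmd_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<mmd_map> %d samples on '%s' (%s)\n", length(x$values),
              x$base$name, x$direction_convention))
  cat(sprintf("  range [%.3f, %.3f] mm, %d positive, %d negative, %d undecided\n",
              min(v), max(v), sum(v > 0), sum(v < 0), x$n_undecided))
  invisible(x)
}

#' @method tidy mmd_map
#' @export
tidy.mmd_map <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$values),
                 x = x$query[, 1], y = x$query[, 2], z = x$query[, 3],
                 mmd = x$values)
}

#' Summarise a modification map
#'
#' The per-cast outcome measures: `pmmd` is the mean of positive signed
#' distances (plaster additions), `nmmd` the mean magnitude of negative ones
#' (subtractions), `mmmd` the mean of absolute values over all samples
#' (zeros included), plus the positive/negative maxima and counts. In
#' bidirectional mode the reverse (post-to-pre) map is pooled after negating
#' its signs, so addition/subtraction stay expressed relative to the pre
#' cast.
#'
#' @param map an `mmd_map` from pre to post.
#' @param reverse_map optional `mmd_map` from post to pre, required for
#'   `mode = "bidirectional"`.
#' @param mode `"one_way"` or `"bidirectional"`.
#' @return a one-row tibble of class `mmd_summary`: `pmmd`, `nmmd`, `mmmd`,
#'   `max_pmmd`, `max_nmmd` (all mm; `NA` when a sign is absent), `n_positive`,
#'   `n_negative`, `n_total`, `n_excluded`, `mode`. Magnitude columns are
#'   reported as positive numbers.
#' @examples
#' # values {+2, +2, -1, -1, 0}: pmmd 2, nmmd 1, mmmd 1.2
#' @export
summarize_mmd <- function(map, reverse_map = NULL,
                          mode = c("one_way", "bidirectional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "mmd_map"))
  values <- map$values
  if (mode == "bidirectional") {
    if (is.null(reverse_map)) {
      abort("bidirectional mode needs `reverse_map` (the post-to-pre map)")
    }
    values <- c(values, -reverse_map$values)
  }
  n_excluded <- sum(is.na(values))
  v <- values[!is.na(values)]
  pos <- v[v > 0]
  neg <- v[v < 0]
  out <- tibble::tibble(
    pmmd = if (length(pos)) mean(pos) else NA_real_,
    nmmd = if (length(neg)) mean(-neg) else NA_real_,
    mmmd = mean(abs(v)),
    max_pmmd = if (length(pos)) max(pos) else NA_real_,
    max_nmmd = if (length(neg)) max(-neg) else NA_real_,
    n_positive = length(pos),
    n_negative = length(neg),
    n_total = length(values),
    n_excluded = n_excluded,
    mode = mode
  )
  class(out) <- c("mmd_summary", class(out))
  out
}

#' Map, summarise and (optionally) export one registered cast pair
#'
#' Runs [signed_mmd()] in both directions as requested and returns the map
#' plus its summary.
#'
#' @inheritParams signed_mmd
#' @param mode `"one_way"` or `"bidirectional"`.
#' @return list with `map` (pre-to-post `mmd_map`), `reverse_map` (or `NULL`)
#'   and `summary` (an `mmd_summary` tibble).
#' @export
compare_casts <- function(pre, post, mode = c("bidirectional", "one_way"),
                          registered = TRUE) {
  mode <- match.arg(mode)
  map <- signed_mmd(pre, post, registered = registered)
  rev <- if (mode == "bidirectional") {
    signed_mmd(post, pre, registered = registered)
  }
  list(map = map, reverse_map = rev,
       summary = summarize_mmd(map, rev, mode = mode))
}
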