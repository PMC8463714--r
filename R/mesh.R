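#' Triangle surface mesh
#'
#' The basic container for a scanned or synthetic cast surface: an indexed
#' triangle mesh in millimetres. Vertices are an `n x 3` numeric matrix,
#' faces an `m x 3` integer matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix (`n x 3`), coordinates in mm.
#' @param faces integer matrix (`m x 3`), 1-based vertex indices.
#' @param name free-text identifier carried through reports.
#' @param validate run [validate_mesh()] on the result (recommended).
#'
#' @return An object of class `cast_mesh`: a list with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' cube <- cube_mesh(10)
#' mesh_metrics(cube)
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) abort("`vertices` must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L) abort("`faces` must have 3 columns of vertex indices")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1]),
    class = "cast_mesh"
  )
  if (validate) mesh <- validate_mesh(mesh)
  mesh
}

#' @export
print.cast_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  cat(sprintf("<cast_mesh '%s'> %d vertices, %d faces\n", x$name,
              m$vertex_count, m$face_count))
  cat(sprintf("  surface area %.2f mm^2, %s, volume %s\n", m$surface_area,
              if (m$is_watertight) "watertight" else "open surface",
              if (is.na(m$enclosed_volume)) "n/a" else
                sprintf("%.2f mm^3", m$enclosed_volume)))
  invisible(x)
}

#' Validate a triangle mesh
#'
#' Checks finiteness and index validity, merges vertices closer than
#' `merge_tol` (1e-6 mm, i.e. exact duplicates at scanner scale), drops faces
#' that repeat a vertex or have area below `area_tol`, and flips the global
#' orientation if the mesh is watertight with negative signed volume so that
#' face normals point outward. A repair report is attached as attribute
#' `"repairs"`.
#'
#' @param mesh a `cast_mesh`.
#' @param merge_tol vertex merge tolerance, mm.
#' @param area_tol minimum face area, mm^2.
#' @return The repaired `cast_mesh` with a `repairs` attribute (named list:
#'   `merged_vertices`, `dropped_faces`, `flipped_orientation`).
#' @export
validate_mesh <- function(mesh, merge_tol = 1e-6, area_tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L) abort("empty mesh: no vertices or faces")
  if (!all(is.finite(v))) abort("mesh has non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) abort("face index out of range")

  # merge duplicate vertices on a merge_tol grid
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- !duplicated(key)
  n_merged <- sum(!first)
  if (n_merged > 0L) {
    remap <- match(key, key[first])
    v <- v[first, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
    storage.mode(f) <- "integer"
  }

  # drop degenerate faces: repeated vertex or (near-)zero area
  repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  areas <- face_areas(v, f)
  bad <- repeated | areas <= area_tol
  n_dropped <- sum(bad)
  if (n_dropped > 0L) f <- f[!bad, , drop = FALSE]
  if (nrow(f) == 0L) abort("mesh has no valid faces after repair")

  # drop vertices no longer referenced (keeps indices tight after merging)
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
    storage.mode(f) <- "integer"
  }

  mesh$vertices <- v
  mesh$faces <- f
  flipped <- FALSE
  if (is_watertight(mesh)) {
    vol <- signed_volume(v, f)
    if (vol < 0) {
      mesh$faces <- f[, c(1L, 3L, 2L), drop = FALSE]
      flipped <- TRUE
    }
  }
  attr(mesh, "repairs") <- list(merged_vertices = n_merged,
                                dropped_faces = n_dropped,
                                flipped_orientation = flipped)
  mesh
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cross3(e1, e2)
  sqrt(rowSums(cx^2)) / 2
}

# rowwise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

signed_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# undirected edge table: one row per directed half-edge
half_edges <- function(f) {
  rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
}

#' Is a mesh watertight?
#'
#' A surface is watertight (closed and consistently oriented) when every
#' undirected edge is shared by exactly two faces traversing it in opposite
#' directions.
#'
#' @param mesh a `cast_mesh`.
#' @return logical flag.
#' @export
is_watertight <- function(mesh) {
  he <- half_edges(mesh$faces)
  dir_key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dir_key) > 0L) return(FALSE) # inconsistent orientation
  und_key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(tabulate(factor(und_key)) == 2L)
}

#' Surface area, volume and integrity metrics
#'
#' Area is the sum of triangle areas; enclosed volume comes from the
#' divergence theorem over oriented faces and is only reported for watertight
#' meshes (an open scan has no well-defined volume, so `NA` is returned
#' rather than a fabricated number).
#'
#' @param mesh a `cast_mesh`.
#' @return A one-row tibble: `name`, `vertex_count`, `face_count`,
#'   `surface_area` (mm^2), `enclosed_volume` (mm^3 or `NA`), `is_watertight`.
#' @examples
#' mesh_metrics(cube_mesh(10)) # area 600, volume 1000
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "cast_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  wt <- is_watertight(mesh)
  tibble::tibble(
    name = mesh$name,
    vertex_count = nrow(v),
    face_count = nrow(f),
    surface_area = sum(face_areas(v, f)),
    enclosed_volume = if (wt) abs(signed_volume(v, f)) else NA_real_,
    is_watertight = wt
  )
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

face_normals <- function(mesh, normalized = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
              v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  if (normalized) unit_rows(n) else n
}

#' Angle-weighted vertex pseudonormals
#'
#' Each vertex normal is the average of incident face normals weighted by the
#' interior angle of the face at that vertex, then normalised. Pseudonormals
#' give a consistent inside/outside test at closest points on a watertight
#' surface, which is how the mesh-to-mesh difference gets its sign.
#'
#' @param mesh a consistently oriented `cast_mesh`.
#' @return numeric matrix (`n x 3`) of unit vectors.
#' @export
vertex_pseudonormals <- function(mesh) {
  f <- mesh$faces
  he <- half_edges(f)
  dir_key <- paste(he[, 1], he[, 2])
  dup <- anyDuplicated(dir_key)
  if (dup > 0L) {
    abort(sprintf(
      "inconsistent face orientation: edge %d-%d traversed twice in the same direction",
      he[dup, 1], he[dup, 2]))
  }
  v <- mesh$vertices
  fn <- face_normals(mesh)
  n <- matrix(0, nrow(v), 3)
  corner <- function(i, j, k) {
    a <- unit_rows(v[j, , drop = FALSE] - v[i, , drop = FALSE])
    b <- unit_rows(v[k, , drop = FALSE] - v[i, , drop = FALSE])
    acos(pmin(pmax(rowSums(a * b), -1), 1))
  }
  for (c_idx in 1:3) {
    i <- f[, c_idx]
    j <- f[, c_idx %% 3L + 1L]
    k <- f[, (c_idx + 1L) %% 3L + 1L]
    w <- corner(i, j, k)
    acc <- rowsum(fn * w, group = i)
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  unit_rows(n)
}

# pseudonormal of each undirected edge: mean of the two incident face normals
# (the natural angle weighting for an edge is pi on each side). Returns a list
# with the edge keys and the normal matrix, for lookup during signing.
edge_pseudonormals <- function(mesh) {
  f <- mesh$faces
  fn <- face_normals(mesh)
  he <- half_edges(f)
  face_of <- rep(seq_len(nrow(f)), times = 3L)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  acc <- rowsum(fn[face_of, , drop = FALSE], group = key)
  list(key = rownames(acc), normal = unit_rows(acc))
}

#' Unit cube test mesh
#'
#' Axis-aligned, outward-oriented cube with one corner at the origin; a
#' standard fixture for closed-form checks (area `6 s^2`, volume `s^3`).
#'
#' @param size edge length, mm.
#' @return a watertight `cast_mesh` with 8 vertices and 12 faces.
#' @export
cube_mesh <- function(size = 1) {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))) * size
  # 12 outward-oriented triangles over the 8 expand.grid-ordered corners
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6)    # x = 1, normal +x
  )
  triangle_mesh(v, f, name = "cube")
}

#' Subdivided icosahedron sphere
#'
#' Icosphere of the given radius: each subdivision splits every triangle in
#' four and reprojects new vertices to the sphere. Subdivision 4 gives 2562
#' vertices / 5120 faces, enough for area and volume within 1% of the closed
#' forms.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius, mm.
#' @param center sphere centre (length-3).
#' @return a watertight `cast_mesh`.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- unit_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uniq <- !duplicated(ekey)
    mid_of <- match(ekey, ekey[uniq]) + nrow(v)
    mids <- unit_rows((v[edges[uniq, 1], , drop = FALSE] +
                       v[edges[uniq, 2], , drop = FALSE]) / 2)
    v <- rbind(v, mids)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  v <- sweep(v * radius, 2, center, "+")
  triangle_mesh(v, f, name = sprintf("icosphere_s%d", subdivisions))
}
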