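#' Rigid transform (rotation + translation)
#'
#' Proper rigid motion in mm: `x -> R x + t` with `R` a 3x3 rotation matrix
#' (orthonormal, determinant +1) and `t` a translation vector. No scaling or
#' reflection — pre- and post-modification casts are the same physical object
#' in the same units.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3, 3))) abort("`rotation` must be 3x3")
  if (length(translation) != 3) abort("`translation` must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort("`rotation` is not orthonormal (||R'R - I|| > 1e-9)")
  }
  if (det(rotation) <= 0) abort("`rotation` must be proper (det > 0), not a reflection")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotation_about
#' @param R 3x3 rotation matrix.
#' @return `rotation_angle_deg()`: the rotation angle of `R` in degrees.
#' @export
rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is "t1 first, then t2":
#' `x -> R2 (R1 x + t1) + t2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

transform_points <- function(points, t) {
  sweep(points %*% t(t$rotation), 2, t$translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are mapped by `R v + t`; connectivity is untouched, so area,
#' volume and watertightness are invariant.
#'
#' @param mesh a `cast_mesh`.
#' @param t a `rigid_transform`.
#' @return the transformed `cast_mesh`.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "cast_mesh"), inherits(t, "rigid_transform"))
  mesh$vertices <- transform_points(mesh$vertices, t)
  mesh
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Row-major rotation plus translation, for interchange with the CLI.
#'
#' @param t a `rigid_transform`.
#' @param path file path.
#' @return `write_transform_json` returns `path` invisibly;
#'   `read_transform_json` returns a `rigid_transform`.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(t$rotation)), translation = t$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
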