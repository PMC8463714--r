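#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supported formats: STL (ASCII or binary, auto-detected), PLY (ASCII) and
#' Wavefront OBJ. Units are taken to be millimetres — none of these formats
#' carries unit metadata. After parsing, the mesh is validated: duplicate
#' vertices within 1e-6 mm are merged, degenerate faces dropped, and
#' orientation flipped to outward (positive signed volume) if needed; the
#' repair report is attached as attribute `"repairs"`.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default inferred from the file
#'   extension.
#' @param name mesh identifier; defaults to the file name.
#' @return a validated `cast_mesh`. PLY per-vertex scalar properties beyond
#'   x/y/z (e.g. a stored `mmd` field) are attached as attribute
#'   `"vertex_scalars"` (a named list, in file vertex order before repair).
#' @export
read_mesh <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("stl", "ply", "obj")) {
    abort(sprintf("unsupported mesh format '%s' (need stl, ply or obj)", format))
  }
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path)
  )
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L) {
    abort(sprintf("empty mesh in %s", path))
  }
  mesh <- triangle_mesh(raw$vertices, raw$faces,
                        name = name %||% basename(path), validate = TRUE)
  if (!is.null(raw$vertex_scalars)) {
    attr(mesh, "vertex_scalars") <- raw$vertex_scalars
  }
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a `cast_mesh`.
#' @param path output file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default from the extension.
#'   STL is written in ASCII unless `binary = TRUE`.
#' @param vertex_scalars optional named list of per-vertex numeric vectors,
#'   stored as float vertex properties — PLY only (STL and OBJ cannot carry
#'   per-vertex scalars).
#' @param vertex_colors optional `n x 3` matrix of RGB values in 0-255 —
#'   PLY or OBJ only (STL has no vertex attributes).
#' @param binary write binary STL (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, vertex_scalars = NULL,
                       vertex_colors = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "cast_mesh"))
  format <- tolower(format %||% tools::file_ext(path))
  n <- nrow(mesh$vertices)
  if (!is.null(vertex_scalars)) {
    if (format != "ply") {
      abort(sprintf("vertex scalars are only supported for PLY, not %s",
                    toupper(format)))
    }
    if (is.null(names(vertex_scalars)) || !is.list(vertex_scalars)) {
      abort("`vertex_scalars` must be a named list of numeric vectors")
    }
    bad <- vapply(vertex_scalars, function(s) length(s) != n, logical(1))
    if (any(bad)) {
      abort(sprintf("vertex scalar '%s' has wrong length (need one value per vertex)",
                    names(vertex_scalars)[which(bad)[1]]))
    }
  }
  if (!is.null(vertex_colors)) {
    if (format == "stl") abort("STL cannot carry vertex colors")
    vertex_colors <- as.matrix(vertex_colors)
    if (nrow(vertex_colors) != n || ncol(vertex_colors) != 3) {
      abort("`vertex_colors` must be an n x 3 RGB matrix (0-255)")
    }
  }
  switch(format,
    stl = write_stl(mesh, path, binary = binary),
    ply = write_ply(mesh, path, vertex_scalars, vertex_colors),
    obj = write_obj(mesh, path, vertex_colors),
    abort(sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

# binary STL: 80-byte header, uint32 n, then n * 50 bytes
is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(size, 84 + 50 * as.numeric(n))
}

read_stl <- function(path) {
  if (is_binary_stl(path)) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3 != 0L) {
    abort(sprintf("cannot parse %s as ASCII STL: %d vertex lines (need a multiple of 3)",
                  path, length(vl)))
  }
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(coords)) {
    abort(sprintf("unreadable STL %s: non-numeric vertex near line %d",
                  path, grep("^\\s*vertex\\s", lines)[which(is.na(rowSums(coords)))[1]]))
  }
  nf <- nrow(coords) / 3
  list(vertices = coords, faces = matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", nf * 50)
  if (length(rec) < nf * 50) {
    abort(sprintf("unreadable binary STL %s: truncated at byte %d",
                  path, 84 + length(rec)))
  }
  idx <- rep(seq(0, (nf - 1) * 50, by = 50), each = 36) +
    rep(12 + seq_len(36), times = nf)
  vals <- readBin(rec[idx], "numeric", n = nf * 9, size = 4, endian = "little")
  coords <- matrix(vals, ncol = 3, byrow = TRUE)
  list(vertices = coords, faces = matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- cbind(fn, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
    return(invisible(path))
  }
  num <- function(x) formatC(x, format = "g", digits = 17)
  out <- character(2 + 7 * nrow(f))
  out[1] <- sprintf("solid %s", mesh$name)
  k <- 2L
  for (i in seq_len(nrow(f))) {
    out[k] <- sprintf("  facet normal %s %s %s", num(fn[i, 1]), num(fn[i, 2]), num(fn[i, 3]))
    out[k + 1L] <- "    outer loop"
    for (j in 1:3) {
      p <- v[f[i, j], ]
      out[k + 1L + j] <- sprintf("      vertex %s %s %s", num(p[1]), num(p[2]), num(p[3]))
    }
    out[k + 5L] <- "    endloop"
    out[k + 6L] <- "  endfacet"
    k <- k + 7L
  }
  out[k] <- sprintf("endsolid %s", mesh$name)
  writeLines(out, path)
  invisible(path)
}

# ---- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    abort(sprintf("unreadable PLY %s: missing 'ply' magic at byte 0", path))
  }
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort(sprintf("unreadable PLY %s: no end_header", path))
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header))) {
    abort(sprintf("PLY %s: only ASCII PLY is supported", path))
  }
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = character(0),
                  list_props = character(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$list_props <- c(cur$list_props, tok[5])
      } else {
        cur$props <- c(cur$props, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    abort(sprintf("PLY %s: need vertex and face elements", path))
  }
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  take <- function(n) {
    out <- body[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  read_block <- NULL
  verts <- NULL
  scalars <- NULL
  faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      vals <- scan(text = take(el$count), quiet = TRUE)
      m <- matrix(vals, nrow = el$count, byrow = TRUE)
      if (ncol(m) != length(el$props)) {
        abort(sprintf("PLY %s: vertex rows have %d values, header declares %d",
                      path, ncol(m), length(el$props)))
      }
      colnames(m) <- el$props
      if (!all(c("x", "y", "z") %in% el$props)) {
        abort(sprintf("PLY %s: vertex element lacks x/y/z", path))
      }
      verts <- m[, c("x", "y", "z"), drop = FALSE]
      extra <- setdiff(el$props, c("x", "y", "z", "red", "green", "blue", "alpha",
                                   "nx", "ny", "nz"))
      if (length(extra)) {
        scalars <- lapply(setNames(extra, extra), function(p) unname(m[, p]))
      }
    } else if (el$name == "face") {
      rows <- strsplit(trimws(take(el$count)), "\\s+")
      fl <- lapply(rows, function(r) {
        r <- as.integer(r)
        k <- r[1]
        poly <- r[1 + seq_len(k)] + 1L  # PLY is 0-based
        if (k == 3L) return(matrix(poly, 1))
        # fan-triangulate larger polygons
        cbind(poly[1], poly[2:(k - 1)], poly[3:k])
      })
      faces <- do.call(rbind, fl)
    } else {
      invisible(take(el$count))
    }
  }
  list(vertices = unname(verts), faces = faces, vertex_scalars = scalars)
}

write_ply <- function(mesh, path, vertex_scalars = NULL, vertex_colors = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  scalar_names <- names(vertex_scalars) %||% character(0)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("comment %s", mesh$name),
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("property float %s", scalar_names),
    if (!is.null(vertex_colors)) c("property uchar red", "property uchar green",
                                   "property uchar blue"),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  cols <- list(v)
  if (length(scalar_names)) {
    # store at float32 precision, matching the declared property type
    cols <- c(cols, lapply(vertex_scalars, as_float32))
  }
  num <- do.call(cbind, cols)
  # full double precision for coordinates (scalars are float32 already)
  vtxt <- apply(matrix(formatC(num, format = "g", digits = 17), nrow = nrow(num)),
                1, paste, collapse = " ")
  if (!is.null(vertex_colors)) {
    rgb <- matrix(as.integer(round(pmin(pmax(vertex_colors, 0), 255))), ncol = 3)
    vtxt <- paste(vtxt, rgb[, 1], rgb[, 2], rgb[, 3])
  }
  ftxt <- paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vtxt, ftxt), path)
  invisible(path)
}

# round-trip a double vector through float32 precision
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L || length(fl) == 0L) {
    abort(sprintf("unreadable OBJ %s: no v/f records", path))
  }
  vtok <- strsplit(vl, "\\s+")
  verts <- t(vapply(vtok, function(x) as.numeric(x[2:4]), numeric(3)))
  ftok <- strsplit(fl, "\\s+")
  faces <- do.call(rbind, lapply(ftok, function(x) {
    idx <- as.integer(vapply(x[-1], function(t) strsplit(t, "/")[[1]][1], ""))
    if (any(idx < 0)) idx <- nrow(verts) + idx + 1L  # relative indices
    k <- length(idx)
    if (k == 3L) matrix(idx, 1) else cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path, vertex_colors = NULL) {
  v <- mesh$vertices
  num <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
  if (!is.null(vertex_colors)) {
    # common OBJ extension: per-vertex RGB (0-1) appended to v records
    rgb <- format(pmin(pmax(vertex_colors / 255, 0), 1), digits = 6, trim = TRUE)
    vtxt <- paste("v", num[, 1], num[, 2], num[, 3], rgb[, 1], rgb[, 2], rgb[, 3])
  } else {
    vtxt <- paste("v", num[, 1], num[, 2], num[, 3])
  }
  f <- mesh$faces
  writeLines(c(sprintf("# %s", mesh$name), vtxt,
               paste("f", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}
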