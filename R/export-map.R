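#' Diverging modification-map colours
#'
#' Red for additions, blue for subtractions, white at zero, symmetric about
#' zero over `color_range`. Values at `+color_range` map to pure red
#' (255, 0, 0), `-color_range` to pure blue (0, 0, 255); values beyond the
#' range are clamped.
#'
#' @param values signed distances, mm (`NA` renders grey).
#' @param color_range half-width of the symmetric colour scale, mm;
#'   `NULL` uses `max(abs(values))` rounded up to the next 0.5 mm.
#' @return list with `rgb` (`n x 3` integer 0-255) and the `color_range` used.
#' @export
map_colors <- function(values, color_range = NULL) {
  finite <- values[is.na(values) == FALSE]
  if (is.null(color_range)) {
    m <- if (length(finite)) max(abs(finite)) else 0
    color_range <- max(ceiling(m / 0.5) * 0.5, 0.5)
  }
  t <- pmin(pmax(values / color_range, -1), 1)
  rgb <- cbind(
    ifelse(t >= 0, 255, 255 * (1 + t)),
    255 * (1 - abs(t)),
    ifelse(t <= 0, 255, 255 * (1 - t))
  )
  rgb[is.na(values), ] <- 128
  list(rgb = round(rgb), color_range = color_range)
}

#' Export a modification map as coloured PLY and CSV
#'
#' Writes the pre-modification cast with the signed mesh-to-mesh difference
#' stored as vertex property `mmd` (float) and diverging red/white/blue
#' vertex colours, plus a `vertex_id,value` CSV beside it. STL cannot carry
#' vertex attributes and is refused.
#'
#' @param map an `mmd_map` whose values are per-vertex on its base mesh.
#' @param path output PLY path (the CSV replaces the extension with `.csv`,
#'   or pass `csv_path`).
#' @param color_range see [map_colors()].
#' @param csv_path optional explicit CSV path; `NULL` derives it, `NA` skips
#'   the CSV.
#' @return invisible list with the paths written and the `color_range` used.
#' @export
export_map <- function(map, path, color_range = NULL, csv_path = NULL) {
  stopifnot(inherits(map, "mmd_map"))
  if (tolower(tools::file_ext(path)) == "stl") {
    abort("STL has no vertex attributes; export modification maps as PLY")
  }
  if (length(map$values) != nrow(map$base$vertices)) {
    abort("map values are not per-vertex on the base mesh; export needs vertex sampling")
  }
  col <- map_colors(map$values, color_range)
  vals <- map$values
  vals[is.na(vals)] <- 0
  write_mesh(map$base, path, format = "ply",
             vertex_scalars = list(mmd = vals),
             vertex_colors = col$rgb)
  if (is.null(csv_path)) {
    csv_path <- sub("\\.[^.]+$", ".csv", path)
  }
  if (!is.na(csv_path)) {
    write.csv(data.frame(vertex_id = seq_along(map$values), value = map$values),
              csv_path, row.names = FALSE)
  }
  invisible(list(ply = path, csv = if (!is.na(csv_path)) csv_path,
                 color_range = col$color_range))
}

#' Plot a modification map
#'
#' Orthographic scatter projection of the map's sample points, coloured with
#' the same diverging scale as the PLY export. `view = "medial"` projects on
#' the x-z plane, `"plantar"` on the x-y plane (looking up at the sole); far
#' points are drawn first so near geometry overpaints them.
#'
#' @param object an `mmd_map`.
#' @param view `"medial"` or `"plantar"`.
#' @param color_range see [map_colors()].
#' @param point_size passed to [ggplot2::geom_point()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot mmd_map
#' @export
autoplot.mmd_map <- function(object, view = c("medial", "plantar"),
                             color_range = NULL, point_size = 0.6, ...) {
  view <- match.arg(view)
  df <- tidy(object)
  df <- df[!is.na(df$mmd), ]
  if (view == "medial") {
    df$h <- df$x; df$v <- df$z; df$depth <- df$y
  } else {
    df$h <- df$x; df$v <- df$y; df$depth <- -df$z
  }
  df <- df[order(df$depth), ]
  rng <- map_colors(df$mmd, color_range)$color_range
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v, colour = .data$mmd)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_gradient2(low = "#0000FF", mid = "#FFFFFF",
                                    high = "#FF0000", midpoint = 0,
                                    limits = c(-rng, rng), oob = scales_squish,
                                    name = "MMD (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = if (view == "medial") "z (mm)" else "y (mm)",
                  title = sprintf("Modification map (%s view)", view)) +
    ggplot2::theme_minimal()
}

# minimal squish, avoids depending on scales directly
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
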