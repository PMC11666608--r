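# Distance heatmap rendering: per-vertex correspondence distances mapped to a
# perceptually ordered colour ramp, clipped at a cap (distances above the cap
# render at the cap colour, dark red), displayed on the right plafond in
# axial view (looking proximally along the longitudinal axis).

#' Distance-to-colour mapping
#'
#' Linear ramp over `[0, cap_mm]`; values at or above the cap (and `NA`,
#' rendered grey) are handled explicitly. The colour table used is attached
#' as attributes so the clipping rule can be inspected.
#'
#' @param values numeric distances (mm); `NA` allowed.
#' @param cap_mm cap distance; larger values render at the cap colour.
#' @param n_colors ramp resolution.
#' @return Character vector of colours with attributes `table` (the ramp) and
#'   `cap_color`.
#' @export
distance_colormap <- function(values, cap_mm = 2, n_colors = 255L) {
  ramp <- grDevices::colorRampPalette(
    c("#313695", "#4575B4", "#74ADD1", "#ABD9E9", "#E0F3F8", "#FEE090",
      "#FDAE61", "#F46D43", "#D73027", "#A50026"))(n_colors)
  cap_color <- "#67001F"   # dark red
  idx <- pmin(n_colors, floor(values / cap_mm * (n_colors - 1L)) + 1L)
  cols <- ramp[idx]
  cols[!is.na(values) & values >= cap_mm] <- cap_color
  cols[is.na(values)] <- "#BBBBBB"
  attr(cols, "table") <- ramp
  attr(cols, "cap_color") <- cap_color
  cols
}

#' Render a distance heatmap of a pair result
#'
#' Draws the right plafond projected along the longitudinal axis (axial view,
#' looking proximally) with triangles coloured by mean vertex distance, and
#' optionally writes the coloured mesh as a PLY with distances in the
#' `quality` property.
#'
#' @param result a `pair_result` from [run_pair()].
#' @param view `"axial"` (projection onto the mediolateral/anteroposterior
#'   plane) or `"custom"` (uses `proj_axes`).
#' @param proj_axes for `view = "custom"`: 3 x 2 matrix of projection axes.
#' @param cap_mm cap distance (defaults to the 2 mm reporting convention).
#' @param ply_file optional path for the coloured PLY export.
#' @return Invisibly, a list with the per-vertex `colors` (including the
#'   colour table attributes) and the face drawing order.
#' @export
render_heatmap <- function(result, view = c("axial", "custom"),
                           proj_axes = NULL, cap_mm = 2, ply_file = NULL) {
  view <- match.arg(view)
  mesh <- result$heatmap_mesh
  d <- result$heatmap_distances
  frame <- result$frame
  if (view == "axial")
    proj_axes <- cbind(frame$axis_ml, frame$axis_ap)
  else if (is.null(proj_axes)) stop("custom view requires proj_axes")
  cols <- distance_colormap(d, cap_mm)

  v <- mesh$vertices
  uv <- v %*% proj_axes
  depth <- drop(v %*% frame$axis_si)
  f <- mesh$faces
  face_depth <- (depth[f[, 1]] + depth[f[, 2]] + depth[f[, 3]]) / 3
  ord <- order(face_depth, decreasing = TRUE)  # looking distally-up: far first
  face_val <- rowMeans(matrix(d[f], ncol = 3L))
  face_col <- distance_colormap(face_val, cap_mm)

  graphics::plot.new()
  graphics::plot.window(range(uv[, 1]), range(uv[, 2]), asp = 1)
  for (i in ord) {
    idx <- f[i, ]
    graphics::polygon(uv[idx, 1], uv[idx, 2], col = face_col[i],
                      border = NA)
  }
  graphics::title(main = sprintf("%s - axial view, cap %.1f mm",
                                 result$specimen_id, cap_mm),
                  xlab = "mediolateral (mm)", ylab = "anteroposterior (mm)")
  graphics::axis(1); graphics::axis(2)

  if (!is.null(ply_file))
    save_mesh(mesh, ply_file, per_vertex_scalar = d)
  invisible(list(colors = cols, face_order = ord, face_colors = face_col))
}
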