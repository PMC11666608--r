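# Plane clipping with exact re-triangulation.
#
# Triangles straddling the plane are clipped at the exact intersection points
# (Sutherland-Hodgman on each triangle, preserving winding); intersection
# vertices are shared along edges and snapped onto the plane so the cut
# boundary lies on the plane to within 1e-9 mm. Vertices exactly on the plane
# are assigned to BOTH parts (the tie rule includes them in the distal part).

clip_by_plane <- function(mesh, point, normal, tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  normal <- unitize(as.numeric(normal))
  s <- drop(sweep(v, 2L, as.numeric(point)) %*% normal)
  side <- integer(length(s))
  side[s > tol] <- 1L
  side[s < -tol] <- -1L

  fs <- matrix(side[f], ncol = 3L)
  has_above <- rowSums(fs == 1L) > 0L
  has_below <- rowSums(fs == -1L) > 0L
  strad <- has_above & has_below
  below_faces <- which(!has_above)            # ties go below
  above_faces <- which(has_above & !has_below)

  new_pts <- list()
  edge_id <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  isect <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- edge_id[[key]]
    if (!is.null(id)) return(id)
    t <- s[i] / (s[i] - s[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p <- p - drop(sum((p - point) * normal)) * normal  # snap onto the plane
    new_pts[[length(new_pts) + 1L]] <<- p
    id <- nv0 + length(new_pts)
    edge_id[[key]] <- id
    id
  }

  tris_below <- list(); tris_above <- list()
  clip_tri <- function(idx, keep_sign) {
    # Sutherland-Hodgman against the halfspace keep_sign * s <= 0 (with ties kept)
    poly <- integer(0)
    for (k in 1:3) {
      a <- idx[k]; b <- idx[if (k == 3L) 1L else k + 1L]
      sa <- side[a] * keep_sign; sb <- side[b] * keep_sign
      if (sa <= 0L) poly <- c(poly, a)
      if (sa * sb < 0L) poly <- c(poly, isect(a, b))
    }
    if (length(poly) == 3L) list(poly)
    else if (length(poly) == 4L) list(poly[c(1L, 2L, 3L)], poly[c(1L, 3L, 4L)])
    else list()
  }
  for (fi in which(strad)) {
    idx <- f[fi, ]
    tris_below <- c(tris_below, clip_tri(idx, 1L))
    tris_above <- c(tris_above, clip_tri(idx, -1L))
  }

  vall <- if (length(new_pts)) rbind(v, do.call(rbind, new_pts)) else v
  s_all <- c(s, rep(0, length(new_pts)))

  build_part <- function(face_rows, extra_tris) {
    fmat <- rbind(f[face_rows, , drop = FALSE],
                  if (length(extra_tris)) do.call(rbind, extra_tris))
    if (is.null(fmat) || nrow(fmat) == 0L) return(NULL)
    # drop slivers created when an intersection lands next to an on-plane vertex
    a2 <- row_norms(cross_rows(vall[fmat[, 2], , drop = FALSE] - vall[fmat[, 1], , drop = FALSE],
                               vall[fmat[, 3], , drop = FALSE] - vall[fmat[, 1], , drop = FALSE]))
    fmat <- fmat[a2 > 1e-12, , drop = FALSE]
    if (nrow(fmat) == 0L) return(NULL)
    used <- sort(unique(as.vector(fmat)))
    remap <- integer(nrow(vall)); remap[used] <- seq_along(used)
    mesh_out <- tri_surface(vall[used, , drop = FALSE],
                            matrix(remap[fmat], ncol = 3L), validate = FALSE,
                            boundary = remap[used[abs(s_all[used]) <= tol]])
    mesh_out$boundary <- mesh_out$boundary[mesh_out$boundary > 0L]
    mesh_out
  }

  list(below = build_part(below_faces, tris_below),
       above = build_part(above_faces, tris_above))
}

# Order the open on-plane boundary of a clipped part into loops; returns the
# longest loop's coordinates (matrix, one row per point), or NULL.
boundary_loop_of <- function(part) {
  if (is.null(part) || length(part$boundary) < 3L) return(NULL)
  f <- part$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  open_e <- e[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
  onb <- rep(FALSE, nrow(part$vertices)); onb[part$boundary] <- TRUE
  open_e <- open_e[onb[open_e[, 1]] & onb[open_e[, 2]], , drop = FALSE]
  if (nrow(open_e) < 3L) return(NULL)
  nxt <- open_e[, 2]; names(nxt) <- open_e[, 1]
  visited <- character(0)
  best <- integer(0)
  for (start in unique(open_e[, 1])) {
    if (as.character(start) %in% visited) next
    loop <- start
    cur <- start
    repeat {
      nx <- nxt[as.character(cur)]
      if (is.na(nx)) break
      visited <- c(visited, as.character(cur))
      if (nx == start) break
      loop <- c(loop, nx)
      cur <- nx
      if (length(loop) > nrow(open_e)) break
    }
    if (length(loop) > length(best)) best <- loop
  }
  part$vertices[as.integer(best), , drop = FALSE]
}

#' Cut a mesh at a height above its most distal point
#'
#' Returns the portion of the surface at longitudinal coordinate at or below
#' `height_mm` above the most distal point (or above `anchor_level`, if
#' given), mirroring the incremental cutting protocol in which bone models
#' are cut 50 mm and 30 mm above the most distal point of the medial
#' malleolus. Straddling triangles are clipped exactly at the plane; the cut
#' boundary is left open (no cap) and its vertices are recorded in the distal
#' part's `boundary` field so correspondence extraction and ROI selection can
#' exclude them. Vertices exactly on the plane are included in the distal
#' part.
#'
#' @param mesh a [tri_surface()].
#' @param frame an [anatomical_frame()]; cutting is along its longitudinal
#'   (superoinferior) axis.
#' @param height_mm positive cut height above the anchor level.
#' @param anchor_level optional longitudinal coordinate (in frame coordinates)
#'   of the anchor; defaults to this mesh's own most distal point. Supply the
#'   contralateral bone's level to cut both bones at the same world plane.
#' @return An object of class `cut_result`: list with `distal_part`
#'   ([tri_surface()] with `boundary` marked), `cut_height_mm`, and
#'   `boundary_loop` (ordered points on the cut plane, or `NULL` when the
#'   plane clears the mesh).
#' @export
cut_at_height <- function(mesh, frame, height_mm, anchor_level = NULL) {
  if (height_mm <= 0) stop("height_mm must be positive")
  ell <- drop(sweep(mesh$vertices, 2L, frame$origin) %*% frame$axis_si)
  anchor <- if (is.null(anchor_level)) min(ell) else anchor_level
  level <- anchor + height_mm
  if (level >= max(ell) - 1e-9) {
    return(structure(list(distal_part = mesh, cut_height_mm = height_mm,
                          boundary_loop = NULL), class = "cut_result"))
  }
  if (level < min(ell) - 1e-9) stop("cut plane lies below the entire mesh")
  plane_point <- frame$origin + level * frame$axis_si
  parts <- clip_by_plane(mesh, plane_point, frame$axis_si)
  if (is.null(parts$below)) stop("cut produced an empty distal part")
  structure(list(distal_part = parts$below, cut_height_mm = height_mm,
                 boundary_loop = boundary_loop_of(parts$below)),
            class = "cut_result")
}

#' @export
print.cut_result <- function(x, ...) {
  cat(sprintf("cut_result: height %.1f mm, distal part %d vertices (%d on cut boundary)\n",
              x$cut_height_mm, n_vertices(x$distal_part), length(x$distal_part$boundary)))
  invisible(x)
}
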