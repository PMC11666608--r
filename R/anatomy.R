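# Anatomical coordinate frame, landmarking, and the articulating-surface
# (region-of-interest) rule.

#' Anatomical coordinate frame
#'
#' Origin plus right-handed orthonormal axes: mediolateral (`+` toward
#' lateral), anteroposterior (`+` toward anterior) and superoinferior /
#' longitudinal (`+` toward proximal).
#'
#' @param origin length-3 origin (mm).
#' @param axis_ml,axis_ap,axis_si unit axes; must be orthonormal and
#'   right-handed (`ml x ap = si`) within 1e-9.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), axis_ml = c(1, 0, 0),
                             axis_ap = c(0, 1, 0), axis_si = c(0, 0, 1)) {
  B <- cbind(as.numeric(axis_ml), as.numeric(axis_ap), as.numeric(axis_si))
  if (max(abs(crossprod(B) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal (tolerance 1e-9)")
  if (abs(det(B) - 1) > 1e-9)
    stop("frame axes must be right-handed (ml x ap = si)")
  structure(list(origin = as.numeric(origin), axis_ml = B[, 1],
                 axis_ap = B[, 2], axis_si = B[, 3]),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n")
  cat(sprintf("  origin [%.2f %.2f %.2f] mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("axis_ml", "axis_ap", "axis_si"))
    cat(sprintf("  %s [%.4f %.4f %.4f]\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

frame_rotation <- function(frame) cbind(frame$axis_ml, frame$axis_ap, frame$axis_si)

#' Express points or a mesh in frame coordinates
#'
#' Maps world coordinates into the frame so that mediolateral, anteroposterior
#' and longitudinal become the x, y and z axes.
#'
#' @param x n x 3 matrix or [tri_surface()].
#' @param frame an [anatomical_frame()].
#' @return Object of the same kind as `x` in frame coordinates.
#' @export
to_frame_coords <- function(x, frame) {
  tf <- rigid_transform(t(frame_rotation(frame)),
                        drop(-t(frame_rotation(frame)) %*% frame$origin))
  apply_transform(x, tf)
}

#' Fit an anatomical frame from inertia axes
#'
#' Principal axes of the vertex scatter, with deterministic sign rules: the
#' longitudinal axis is the dominant principal axis, signed so the wider
#' (epiphyseal) end is distal; the mediolateral axis is the second principal
#' axis, signed via the medial malleolus (the most distal vertex), which lies
#' medial — negative mediolateral for a right bone, positive for an
#' (unmirrored) left bone; the anteroposterior axis completes the
#' right-handed frame. This is a self-contained alternative to published
#' anatomical coordinate-system constructions; a user-built
#' [anatomical_frame()] can be supplied anywhere a frame is accepted.
#'
#' @param mesh a [tri_surface()] of a full or distal tibia with a dominant
#'   long axis (largest principal extent at least twice the next).
#' @param side `"right"` or `"left"` — the anatomical side of the bone as
#'   meshed (before any mirroring).
#' @return An [anatomical_frame()] with origin at the vertex centroid.
#' @export
fit_anatomical_frame <- function(mesh, side = c("right", "left")) {
  side <- match.arg(side)
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  ev <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  E <- ev$vectors                      # columns: decreasing variance
  scores <- vc %*% E
  extents <- apply(scores, 2L, function(u) diff(range(u)))
  if (extents[1] < 2 * extents[2])
    stop("no dominant long axis (extent ratio ", sprintf("%.2f", extents[1] / extents[2]),
         " < 2); supply an anatomical_frame manually")
  u <- scores[, 1]
  qs <- stats::quantile(u, c(0.25, 0.75), names = FALSE)
  spread <- function(mask) sqrt(mean(rowSums(scores[mask, 2:3, drop = FALSE]^2)))
  # the flared (epiphyseal) end is distal; si points proximal
  si <- if (spread(u <= qs[1]) > spread(u >= qs[2])) E[, 1] else -E[, 1]
  ell <- drop(vc %*% si)
  tip <- vc[which.min(ell), ]
  tip_tr <- tip - sum(tip * si) * si   # transverse offset of the malleolus
  e2 <- E[, 2]
  proj <- sum(tip_tr * e2)
  sgn <- if (side == "right") -sign(proj) else sign(proj)
  if (sgn == 0) sgn <- 1
  ml <- sgn * e2
  ap <- cross3(si, ml)
  anatomical_frame(ctr, ml, ap, si)
}

#' Most distal point of a mesh
#'
#' The vertex with minimal longitudinal coordinate in the given frame;
#' anatomically, the tip of the medial malleolus is the tibia's most distal
#' point. Ties are broken toward the smallest vertex index.
#'
#' @param mesh a [tri_surface()].
#' @param frame an [anatomical_frame()].
#' @return Length-3 point (mm) with attribute `"index"` (the vertex index).
#' @export
most_distal_point <- function(mesh, frame) {
  ell <- drop(sweep(mesh$vertices, 2L, frame$origin) %*% frame$axis_si)
  i <- which.min(ell)           # which.min returns the first (smallest) index
  structure(mesh$vertices[i, ], index = i)
}

#' Reference point at the centre of the distal tibia
#'
#' Mean mediolateral and anteroposterior coordinate over all vertices of the
#' distal (plafond) mesh, at the longitudinal height of the most distal
#' point of the medial malleolus.
#'
#' @param distal_mesh the distal tibia mesh (the 30 mm plafond region).
#' @param frame an [anatomical_frame()].
#' @return Length-3 point (mm, world coordinates).
#' @export
reference_point <- function(distal_mesh, frame) {
  vc <- sweep(distal_mesh$vertices, 2L, frame$origin)
  ml <- drop(vc %*% frame$axis_ml)
  ap <- drop(vc %*% frame$axis_ap)
  ell <- drop(vc %*% frame$axis_si)
  frame$origin + mean(ml) * frame$axis_ml + mean(ap) * frame$axis_ap +
    min(ell) * frame$axis_si
}

#' Select the articulating surface (region of interest)
#'
#' A vertex belongs to the articulating surface iff the angle between its
#' outward normal and the line from the vertex to the reference point is
#' strictly smaller than `angle_deg` (default 90 degrees, i.e. a strictly
#' positive dot product; a dot product of exactly zero is not selected).
#' Cut-boundary vertices are excluded regardless — their normals are
#' artefacts of clipping, not anatomy — as are vertices with zero normals.
#'
#' @param distal_mesh a [tri_surface()] with outward-oriented normals
#'   (computed on demand).
#' @param ref length-3 reference point from [reference_point()].
#' @param angle_deg selection half-angle in degrees.
#' @return An object of class `surface_mask`: list with `mesh` and `selected`
#'   (logical, one flag per vertex).
#' @export
select_articulating_surface <- function(distal_mesh, ref, angle_deg = 90) {
  nrm <- mesh_normals(distal_mesh)
  to_ref <- -sweep(distal_mesh$vertices, 2L, as.numeric(ref))
  len <- row_norms(to_ref)
  len[len < 1e-300] <- 1
  dotp <- rowSums(nrm * to_ref) / len
  thr <- cospi(angle_deg / 180)       # exactly 0 at 90 degrees
  selected <- dotp > thr
  selected[row_norms(nrm) < 0.5] <- FALSE       # isolated vertices
  selected[distal_mesh$boundary] <- FALSE
  structure(list(mesh = distal_mesh, selected = selected),
            class = "surface_mask")
}

#' @export
print.surface_mask <- function(x, ...) {
  cat(sprintf("surface_mask: %d of %d vertices selected\n",
              sum(x$selected), length(x$selected)))
  invisible(x)
}
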