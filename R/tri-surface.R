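#' Triangulated surface mesh
#'
#' The geometric carrier used throughout the package: vertices in millimetres
#' and counter-clockwise-wound triangles whose winding encodes the outward
#' normal. Closed meshes are oriented so the signed volume (divergence
#' theorem) is positive.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise when seen from outside.
#' @param validate check invariants (finite coordinates, in-range indices,
#'   no degenerate faces).
#' @param boundary integer vector of vertex indices lying on an open cut
#'   boundary (artefacts of plane cutting; excluded from correspondence and
#'   ROI selection downstream).
#' @return An object of class `tri_surface` with elements `vertices`, `faces`,
#'   `normals` (per-vertex unit normals, `NULL` until
#'   [compute_vertex_normals()] is called) and `boundary`.
#' @export
tri_surface <- function(vertices, faces, validate = TRUE, boundary = integer(0)) {
  v <- as_point_matrix(vertices)
  f <- as.matrix(faces)
  if (nrow(f) == 0L) stop("empty mesh: zero faces")
  if (ncol(f) != 3L) stop("faces must be an m x 3 index matrix (triangles only)")
  storage.mode(f) <- "integer"
  f <- unname(f)
  if (validate) {
    if (!all(is.finite(v))) stop("non-finite vertex coordinates")
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("degenerate face: repeated vertex index")
    a2 <- row_norms(cross_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                               v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]))
    if (any(a2 <= 1e-12)) stop("degenerate face: area below tolerance")
  }
  structure(list(vertices = v, faces = f, normals = NULL,
                 boundary = as.integer(boundary)),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (length(x$boundary)) cat(sprintf(", %d cut-boundary vertices", length(x$boundary)))
  cat(sprintf("\n  bbox x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2]),
              min(x$vertices[, 3]), max(x$vertices[, 3])))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a [tri_surface()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Unnormalized face normals (cross products); norm = 2 * triangle area.
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  cross_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
             v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
}

#' Total surface area of a mesh
#' @param mesh a [tri_surface()].
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) sum(row_norms(face_cross(mesh))) / 2

#' Signed volume of a (closed) mesh
#'
#' Divergence-theorem volume; positive for a closed, outward-oriented surface.
#' @param mesh a [tri_surface()].
#' @return Volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  sum(rowSums(a * cross_rows(v[f[, 2], , drop = FALSE] - a,
                             v[f[, 3], , drop = FALSE] - a))) / 6
}

#' Compute per-vertex unit normals
#'
#' Area-weighted average of incident face normals (summing raw cross products
#' weights each face by its area), normalized to unit length. Isolated
#' vertices (no incident face) receive a zero normal and are excluded from
#' downstream region-of-interest selection.
#'
#' @param mesh a [tri_surface()].
#' @return The mesh with `$normals` filled (n x 3, unit rows or zero rows for
#'   isolated vertices).
#' @export
compute_vertex_normals <- function(mesh) {
  fc <- face_cross(mesh)
  acc <- matrix(0, n_vertices(mesh), 3L)
  s <- rowsum(rbind(fc, fc, fc), group = as.vector(mesh$faces))
  acc[as.integer(rownames(s)), ] <- s
  len <- row_norms(acc)
  ok <- len > 1e-300
  acc[ok, ] <- acc[ok, , drop = FALSE] / len[ok]
  acc[!ok, ] <- 0
  mesh$normals <- acc
  mesh
}

# Normals, computing them if absent.
mesh_normals <- function(mesh) {
  if (is.null(mesh$normals)) mesh <- compute_vertex_normals(mesh)
  mesh$normals
}

#' Merge duplicate vertices
#'
#' Vertices whose coordinates agree within `tol` (bucketed rounding) are
#' merged; faces that collapse to fewer than three distinct vertices or to
#' near-zero area are dropped. STL files, which repeat vertices per facet,
#' rely on this to recover shared connectivity.
#'
#' @param mesh a [tri_surface()].
#' @param tol merge tolerance in mm.
#' @return A `tri_surface` with merged vertices.
#' @export
merge_duplicate_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  if (nrow(f)) {
    a2 <- row_norms(cross_rows(newv[f[, 2], , drop = FALSE] - newv[f[, 1], , drop = FALSE],
                               newv[f[, 3], , drop = FALSE] - newv[f[, 1], , drop = FALSE]))
    f <- f[a2 > 1e-12, , drop = FALSE]
  }
  tri_surface(newv, f, validate = FALSE,
              boundary = unique(map[mesh$boundary]))
}

#' Taubin smoothing
#'
#' Optional mesh fairing (off by default in the pipeline): alternating
#' Laplacian steps with positive and negative weights, which smooths without
#' the shrinkage of plain Laplacian smoothing. A stand-in for unspecified
#' automatic mesh-quality improvement in upstream segmentation toolchains.
#'
#' @param mesh a [tri_surface()].
#' @param lambda positive step (default 0.5).
#' @param mu negative step (default -0.53).
#' @param iterations number of lambda/mu sweeps.
#' @return Smoothed `tri_surface`.
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = -0.53, iterations = 10) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  deg <- tabulate(e[, 1], nbins = nrow(v))
  step <- function(v, w) {
    nb <- rowsum(v[e[, 2], , drop = FALSE], e[, 1])
    mean_nb <- v
    idx <- as.integer(rownames(nb))
    mean_nb[idx, ] <- nb / pmax(deg[idx], 1L)
    v + w * (mean_nb - v)
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  out <- mesh
  out$vertices <- v
  out$normals <- NULL
  out
}

#' Mirror a mesh in the sagittal plane
#'
#' Reflects across the plane through the anatomical frame's origin,
#' perpendicular to its mediolateral axis; with no frame, the global `x = 0`
#' plane is used (with a warning). Face winding is reversed so that outward
#' orientation — and hence the signed volume of a closed mesh — is preserved.
#'
#' @param mesh a [tri_surface()].
#' @param frame optional [anatomical_frame()] defining the mediolateral axis.
#' @return The mirrored `tri_surface`.
#' @export
mirror_sagittal <- function(mesh, frame = NULL) {
  v <- mesh$vertices
  if (is.null(frame)) {
    warning("no anatomical frame supplied; mirroring across the global x = 0 plane")
    v[, 1] <- -v[, 1]
  } else {
    d <- drop((v - matrix(frame$origin, nrow(v), 3L, byrow = TRUE)) %*% frame$axis_ml)
    v <- v - 2 * tcrossprod(d, frame$axis_ml)
  }
  out <- mesh
  out$vertices <- v
  out$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  out$normals <- NULL
  out
}
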