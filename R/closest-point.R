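# Closest point on a triangulated surface.
#
# For each query, the nearest mesh vertex is found by (chunked) exhaustive
# distance computation, and the exact closest point is then taken over the
# triangles incident to that vertex and its one-ring neighbours. The
# candidate point can never be worse than the nearest vertex itself, and for
# the smooth, well-sampled surfaces handled here the one-ring contains the
# true foot point.

# Closest points on a set of triangles (A, B, C: k x 3) to a single point p.
closest_point_triangles <- function(p, A, B, C) {
  k <- nrow(A)
  P <- matrix(p, k, 3L, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  out <- matrix(NA_real_, k, 3L)
  done <- rep(FALSE, k)
  set <- function(mask, val) {
    m <- mask & !done
    out[m, ] <<- val[m, , drop = FALSE]
    done[m] <<- TRUE
  }
  set(d1 <= 0 & d2 <= 0, A)
  set(d3 >= 0 & d4 <= d3, B)
  set(d6 >= 0 & d5 <= d6, C)
  v_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + v_ab * ab)
  v_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + v_ac * ac)
  v_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + v_bc * (C - B))
  denom <- 1 / (va + vb + vc)
  set(rep(TRUE, k), A + (vb * denom) * ab + (vc * denom) * ac)
  out
}

#' Closest point on a surface mesh
#'
#' Exact point-to-triangle projection over the triangles around each query's
#' nearest vertex.
#'
#' @param points n x 3 query matrix.
#' @param mesh a [tri_surface()].
#' @return List with `points` (n x 3 closest points on the surface), `face`
#'   (triangle index of each foot point) and `distance` (mm).
#' @export
closest_point_on_surface <- function(points, mesh) {
  q <- as_point_matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  nq <- nrow(q)

  # vertex -> incident faces, vertex -> one-ring vertices
  v2f <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  ekey <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  eval_ <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  v2v <- split(eval_, ekey)

  # nearest vertex per query, chunked to bound memory
  nv <- integer(nq)
  chunk <- 512L
  for (st in seq(1L, nq, by = chunk)) {
    en <- min(st + chunk - 1L, nq)
    d2 <- dist2_matrix(q[st:en, , drop = FALSE], v)
    nv[st:en] <- max.col(-d2, ties.method = "first")
  }

  out <- matrix(0, nq, 3L)
  face <- integer(nq)
  for (i in seq_len(nq)) {
    ring <- unique(c(nv[i], v2v[[as.character(nv[i])]]))
    cand <- unique(unlist(v2f[as.character(ring)], use.names = FALSE))
    cps <- closest_point_triangles(q[i, ], v[f[cand, 1], , drop = FALSE],
                                   v[f[cand, 2], , drop = FALSE],
                                   v[f[cand, 3], , drop = FALSE])
    d2 <- rowSums(sweep(cps, 2L, q[i, ])^2)
    j <- which.min(d2)
    out[i, ] <- cps[j, ]
    face[i] <- cand[j]
  }
  list(points = out, face = face, distance = row_norms(out - q))
}
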