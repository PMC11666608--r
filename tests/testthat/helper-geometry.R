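# Fixtures (built in code) and independent oracles used across the suite.

# Unit tetrahedron: vertices at origin + unit basis points, outward winding,
# signed volume exactly 1/6.
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_surface(v, f)
}

# Axis-aligned unit cube centred at the origin, outward winding.
cube_mesh <- function() {
  g <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5)))
  idx <- function(x, y, z) which(g[, 1] == x & g[, 2] == y & g[, 3] == z)
  quads <- list(
    c(idx(-.5, -.5, -.5), idx(-.5, .5, -.5), idx(.5, .5, -.5), idx(.5, -.5, -.5)),  # bottom
    c(idx(-.5, -.5, .5), idx(.5, -.5, .5), idx(.5, .5, .5), idx(-.5, .5, .5)),      # top
    c(idx(-.5, -.5, -.5), idx(.5, -.5, -.5), idx(.5, -.5, .5), idx(-.5, -.5, .5)),  # y-
    c(idx(-.5, .5, -.5), idx(-.5, .5, .5), idx(.5, .5, .5), idx(.5, .5, -.5)),      # y+
    c(idx(-.5, -.5, -.5), idx(-.5, -.5, .5), idx(-.5, .5, .5), idx(-.5, .5, -.5)),  # x-
    c(idx(.5, -.5, -.5), idx(.5, .5, -.5), idx(.5, .5, .5), idx(.5, -.5, .5)))      # x+
  f <- do.call(rbind, lapply(quads, function(q) rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  tri_surface(g, f)
}

# Icosphere by repeated subdivision of an icosahedron; n_subdiv = 3 gives the
# classic 642-vertex tessellation.
icosphere <- function(n_subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(n_subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    nf <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[[length(nf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  tri_surface(v * radius, f)
}

# Open (or capped) vertical cylinder, base at z = 0.
cylinder_mesh <- function(radius = 10, height = 100, ntheta = 64, nz = 50,
                          caps = FALSE) {
  theta <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  zs <- seq(0, height, length.out = nz + 1L)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(theta), radius * sin(theta), z)))
  nxt <- c(seq_len(ntheta)[-1L], 1L)
  id <- function(k, j) (k - 1L) * ntheta + j
  f <- do.call(rbind, lapply(seq_len(nz), function(k)
    do.call(rbind, lapply(seq_len(ntheta), function(j)
      rbind(c(id(k, j), id(k, nxt[j]), id(k + 1L, nxt[j])),
            c(id(k, j), id(k + 1L, nxt[j]), id(k + 1L, j)))))))
  if (caps) {
    cb <- nrow(v) + 1L; ct <- nrow(v) + 2L
    v <- rbind(v, c(0, 0, 0), c(0, 0, height))
    f <- rbind(f,
               do.call(rbind, lapply(seq_len(ntheta), function(j)
                 c(id(1L, nxt[j]), id(1L, j), cb))),
               do.call(rbind, lapply(seq_len(ntheta), function(j)
                 c(id(nz + 1L, j), id(nz + 1L, nxt[j]), ct))))
  }
  tri_surface(v, f)
}

# Flat triangulated square in the z = plane, CCW as seen from +z.
plate_mesh <- function(n = 10, size = 20, z = 0) {
  xs <- seq(0, size, length.out = n + 1L)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  id <- function(i, j) (j - 1L) * (n + 1L) + i
  f <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, lapply(seq_len(n), function(j)
      rbind(c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
            c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))))))
  tri_surface(cbind(g, z), f)
}

# Cube with each face split at its centre: all eight corners symmetric,
# used for the corner-normal symmetry check.
cube_symmetric <- function() {
  cube <- cube_mesh()
  v <- cube$vertices
  f <- NULL
  for (q in seq(1, 12, by = 2)) {
    tri1 <- cube$faces[q, ]; tri2 <- cube$faces[q + 1, ]
    quad <- c(tri1, tri2[3])        # (a, b, c) + (a, c, d) -> a b c d
    ctr <- colMeans(v[quad, ])
    v <- rbind(v, ctr)
    ci <- nrow(v)
    f <- rbind(f, cbind(quad, c(quad[-1], quad[1]), ci))
  }
  tri_surface(v, f)
}

# Sort-based quantile oracle: linear interpolation between closest ranks,
# (1 - g) x_(j) + g x_(j+1) at rank h = 1 + (n - 1) p, computed scalar by
# scalar exactly as the textbook definition writes it.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- 1 + (n - 1) * pp
    j <- floor(h)
    g <- h - j
    if (j >= n) return(x[n])
    (1 - g) * x[j] + g * x[j + 1]
  }, 0)
}

# Brute-force nearest-vertex distance between two vertex sets.
oracle_nearest_vertex <- function(A, B) {
  apply(A, 1L, function(p) sqrt(min(colSums((t(B) - p)^2))))
}

# Small symmetric synthetic pair used by several pipeline tests.
quick_pair <- function(seed = 1, noise_sd = 0, sites = list(),
                       resolution = 2.5) {
  generate_pair(synthetic_pair_spec(seed = seed, noise_sd = noise_sd,
                                    asymmetry_sites = sites,
                                    mesh_resolution = resolution))
}

row_norms_test <- function(m) sqrt(rowSums(m^2))
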