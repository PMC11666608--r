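#' Rigid transform (rotation + translation)
#'
#' A proper rigid motion in 3D: `x -> R x + t`. The rotation must be orthogonal
#' with determinant +1 (no reflection, no scale); reflections are handled
#' explicitly by [mirror_sagittal()] so that mirroring and superposition stay
#' separate steps.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("non-finite values in rigid transform")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthogonal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must have determinant +1 (proper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x n x 3 point matrix or a [tri_surface()].
#' @param tf a [rigid_transform()].
#' @return Object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "tri_surface")) {
    x$vertices <- apply_transform(x$vertices, tf)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(tf$rotation)
    return(x)
  }
  p <- as_point_matrix(x)
  sweep(p %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is "apply `b`, then `a`".
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), drop(-t(tf$rotation) %*% tf$translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula.
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Rotation angle in degrees.
#' @export
rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Draw a random proper rigid transform
#'
#' Uniform random axis, angle uniform on `[0, max_angle_deg]`, translation
#' components uniform on `[-max_translation, max_translation]`. Uses the
#' current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param max_angle_deg maximum rotation angle (degrees).
#' @param max_translation maximum per-axis translation (mm).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle_deg = 30, max_translation = 20) {
  ax <- stats::rnorm(3)
  rigid_transform(axis_angle_rotation(ax, stats::runif(1, 0, max_angle_deg)),
                  stats::runif(3, -max_translation, max_translation))
}

#' Evaluate code with a fixed seed, preserving the caller's RNG state
#'
#' Every stochastic step in the package funnels through this so that a seed
#' fully determines the result without disturbing the session's RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

as_point_matrix <- function(x) {
  if (inherits(x, "tri_surface")) return(x$vertices)
  p <- as.matrix(x)
  if (is.null(dim(p)) || ncol(p) != 3L) {
    if (length(p) == 3L) p <- matrix(as.numeric(p), 1L, 3L)
    else stop("points must be an n x 3 matrix")
  }
  storage.mode(p) <- "double"
  unname(p)
}

unitize <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of n x 3 matrices.
cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

row_norms <- function(A) sqrt(rowSums(A^2))

# Squared Euclidean distance matrix between rows of A (m x 3) and B (n x 3).
dist2_matrix <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
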