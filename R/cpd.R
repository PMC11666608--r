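# Coherent Point Drift registration (rigid and nonrigid).
#
# One point set ("moving") is treated as the centroids of an isotropic
# Gaussian mixture fitted to the other ("fixed") by EM, with a uniform outlier
# component of weight w. The rigid variant recovers rotation + translation in
# closed form via SVD of the weighted cross-covariance (scale fixed at 1:
# allowing scale would absorb true left-right size asymmetry, the quantity
# being measured). The nonrigid variant parameterizes the displacement field
# as a Gaussian-kernel expansion over the moving points with a motion-
# coherence penalty lambda * tr(W' G W) / 2.

#' CPD registration parameters
#'
#' @param outlier_weight weight `w` of the uniform outlier component, in
#'   `[0, 1)`.
#' @param max_iterations maximum EM iterations.
#' @param tolerance convergence threshold on the relative change of the EM
#'   objective.
#' @param beta Gaussian kernel width of the nonrigid displacement field (mm).
#' @param lambda nonrigid motion-coherence regularization weight.
#' @param subsample point sets larger than this are reduced by seeded
#'   farthest-point sampling before EM (or `Inf` for all points).
#' @param seed seed for the (deterministic) subsampling step.
#' @return An object of class `cpd_params`.
#' @export
cpd_params <- function(outlier_weight = 0.1, max_iterations = 150,
                       tolerance = 1e-8, beta = 2, lambda = 3,
                       subsample = 1500, seed = 0L) {
  if (outlier_weight < 0 || outlier_weight >= 1)
    stop("outlier_weight must be in [0, 1)")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(outlier_weight = outlier_weight,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, beta = beta, lambda = lambda,
                 subsample = subsample, seed = as.integer(seed)),
            class = "cpd_params")
}

#' Farthest-point subsampling
#'
#' Deterministic given the seed (which picks the starting point); greedily
#' adds the point farthest from the current sample, giving near-uniform
#' coverage of the surface.
#'
#' @param points n x 3 matrix or [tri_surface()].
#' @param n target sample size.
#' @param seed RNG seed for the starting point.
#' @return Integer vector of row indices (length `min(n, nrow)`).
#' @export
farthest_point_sample <- function(points, n, seed = 0L) {
  p <- as_point_matrix(points)
  N <- nrow(p)
  if (N <= n) return(seq_len(N))
  idx <- integer(n)
  idx[1] <- with_seed(seed, sample.int(N, 1L))
  d2 <- rowSums(sweep(p, 2L, p[idx[1], ])^2)
  for (k in 2:n) {
    idx[k] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(p, 2L, p[idx[k], ])^2))
  }
  idx
}

validate_cloud <- function(p, min_n, label, min_rank = 3L) {
  if (!all(is.finite(p))) stop(label, " point set contains non-finite coordinates")
  if (nrow(p) < min_n) stop(label, " point set needs at least ", min_n, " points")
  sv <- svd(sweep(p, 2L, colMeans(p)), nu = 0, nv = 0)$d
  if (sv[min_rank] < 1e-9 * sv[1])
    stop(label, " point set is degenerate (",
         if (min_rank == 3L) "coplanar or collinear" else "collinear", ")")
  invisible(TRUE)
}

cpd_subsample <- function(p, params, salt = 0L) {
  if (is.finite(params$subsample) && nrow(p) > params$subsample)
    p[farthest_point_sample(p, params$subsample, params$seed + salt), , drop = FALSE]
  else p
}

# E-step: TY are the (transformed) moving points, X the fixed points.
# Returns posteriors P (M x N, columns sum with the outlier mass to 1) and
# the negative log-likelihood of X under the mixture.
cpd_estep <- function(TY, X, sigma2, w) {
  M <- nrow(TY); N <- nrow(X)
  K <- exp(-dist2_matrix(TY, X) / (2 * sigma2))
  ck <- colSums(K)
  c0 <- (2 * pi * sigma2)^1.5 * w / (1 - w) * M / N
  den <- ck + c0
  den[den < 1e-300] <- 1e-300
  P <- K * rep(1 / den, each = M)
  nll <- -sum(log((1 - w) / (M * (2 * pi * sigma2)^1.5) * ck + w / N + 1e-300))
  list(P = P, nll = nll)
}

# Moment-based initial rotation: align principal axes of the two clouds,
# choosing among the four proper sign combinations by a nearest-neighbour
# cost on a deterministic subsample. Removes the large-rotation local
# minima of identity-initialized EM.
pca_init_rotation <- function(Y, X) {
  EY <- eigen(stats::cov(Y), symmetric = TRUE)$vectors
  EX <- eigen(stats::cov(X), symmetric = TRUE)$vectors
  Yc <- sweep(Y, 2L, colMeans(Y))
  Xc <- sweep(X, 2L, colMeans(X))
  iy <- unique(round(seq(1L, nrow(Yc), length.out = min(256L, nrow(Yc)))))
  ix <- unique(round(seq(1L, nrow(Xc), length.out = min(512L, nrow(Xc)))))
  best <- diag(3); best_cost <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    s3 <- s1 * s2 * det(EX) * det(EY)   # keep det(R0) = +1
    R0 <- EX %*% diag(c(s1, s2, s3)) %*% t(EY)
    d2 <- dist2_matrix(Yc[iy, , drop = FALSE] %*% t(R0), Xc[ix, , drop = FALSE])
    cost <- mean(sqrt(apply(d2, 1L, min)))
    if (cost < best_cost) { best <- R0; best_cost <- cost }
  }
  best
}

init_sigma2 <- function(Y, X) {
  M <- nrow(Y); N <- nrow(X)
  (N * sum(Y^2) + M * sum(X^2) - 2 * sum(colSums(Y) * colSums(X))) / (3 * M * N)
}

registration_report <- function(trace, iters, sigma2, converged) {
  structure(list(iterations_run = iters, final_sigma2 = sigma2,
                 objective_trace = trace, converged = converged),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("CPD registration: %d iterations, final sigma^2 = %.3g mm^2, %s\n",
              x$iterations_run, x$final_sigma2,
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}

#' Rigid CPD registration
#'
#' Recovers the rotation and translation superimposing `moving` onto `fixed`
#' by EM over the CPD Gaussian mixture. Initialization is the identity with
#' the standard mean-pairwise-squared-distance sigma^2; no multi-start is
#' used because mirroring plus anatomical-frame alignment provides gross
#' pre-alignment.
#'
#' @param moving,fixed n x 3 point matrices or [tri_surface()] objects (at
#'   least 4 non-coplanar points each).
#' @param params a [cpd_params()].
#' @return List with `transform` ([rigid_transform()]) and `report`
#'   (`registration_report`: iterations, final sigma^2, objective trace,
#'   convergence flag).
#' @export
rigid_cpd <- function(moving, fixed, params = cpd_params()) {
  Y0 <- as_point_matrix(moving)
  X0 <- as_point_matrix(fixed)
  validate_cloud(Y0, 4L, "moving")
  validate_cloud(X0, 4L, "fixed")
  Y <- cpd_subsample(Y0, params, 0L)
  X <- cpd_subsample(X0, params, 1L)
  M <- nrow(Y); N <- nrow(X)
  w <- params$outlier_weight
  sigma2 <- init_sigma2(Y, X)
  R <- pca_init_rotation(Y, X)
  t <- colMeans(X) - drop(R %*% colMeans(Y))
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    TY <- sweep(Y %*% t(R), 2L, t, "+")
    es <- cpd_estep(TY, X, sigma2, w)
    trace <- c(trace, es$nll)
    P <- es$P
    P1 <- rowSums(P); Pt1 <- colSums(P); Np <- sum(P1)
    if (Np < 1e-12) break
    mu_x <- colSums(Pt1 * X) / Np
    mu_y <- colSums(P1 * Y) / Np
    Xc <- sweep(X, 2L, mu_x)
    Yc <- sweep(Y, 2L, mu_y)
    A <- crossprod(Xc, crossprod(P, Yc))  # 3 x 3 weighted cross-covariance
    sv <- svd(A)
    C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% C %*% t(sv$v)
    t <- mu_x - drop(R %*% mu_y)
    sigma2 <- (sum(Pt1 * rowSums(Xc^2)) + sum(P1 * rowSums(Yc^2)) -
                 2 * sum(diag(crossprod(A, R)))) / (3 * Np)
    sigma2 <- max(sigma2, 1e-10)
    if (sigma2 <= 1e-10) { converged <- TRUE; break }  # exact match reached
    if (it > 1L && abs(trace[it - 1L] - trace[it]) <=
        params$tolerance * abs(trace[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  list(transform = rigid_transform(R, t),
       report = registration_report(trace, iters, sigma2, converged))
}

#' Nonrigid CPD registration
#'
#' Fits a coherent displacement field (Gaussian kernel of width `beta`,
#' coherence penalty `lambda`) warping `moving` onto `fixed` with the CPD EM
#' scheme. The field is an expansion over the (possibly subsampled) moving
#' points and can be evaluated anywhere with [warp_points()], so the final
#' correspondence step can use every vertex of the moving surface.
#'
#' @inheritParams rigid_cpd
#' @return List with `warp` (class `nonrigid_warp`: `source_points`,
#'   `kernel_width_beta`, `coefficients`) and `report`.
#' @export
nonrigid_cpd <- function(moving, fixed, params = cpd_params()) {
  Y0 <- as_point_matrix(moving)
  X0 <- as_point_matrix(fixed)
  validate_cloud(Y0, 10L, "moving", min_rank = 2L)  # flat patches are legitimate
  validate_cloud(X0, 10L, "fixed", min_rank = 2L)
  if (params$lambda == 0)
    warning("lambda = 0: unregularized nonrigid CPD is ill-posed")
  Y <- cpd_subsample(Y0, params, 2L)
  X <- cpd_subsample(X0, params, 3L)
  M <- nrow(Y)
  w <- params$outlier_weight
  G <- exp(-dist2_matrix(Y, Y) / (2 * params$beta^2))
  W <- matrix(0, M, 3L)
  sigma2 <- init_sigma2(Y, X)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    TY <- Y + G %*% W
    es <- cpd_estep(TY, X, sigma2, w)
    penalty <- params$lambda / 2 * sum(W * (G %*% W))
    trace <- c(trace, es$nll + penalty)
    P <- es$P
    P1 <- rowSums(P); Pt1 <- colSums(P); Np <- sum(P1)
    if (Np < 1e-12) break
    PX <- P %*% X
    LHS <- P1 * G
    diag(LHS) <- diag(LHS) + params$lambda * sigma2 + 1e-12
    W <- solve(LHS, PX - P1 * Y)
    TY <- Y + G %*% W
    sigma2 <- (sum(Pt1 * rowSums(X^2)) - 2 * sum(PX * TY) +
                 sum(P1 * rowSums(TY^2))) / (3 * Np)
    sigma2 <- max(sigma2, 1e-10)
    if (sigma2 <= 1e-10) { converged <- TRUE; break }  # exact match reached
    if (it > 1L && abs(trace[it - 1L] - trace[it]) <=
        params$tolerance * abs(trace[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  warp <- structure(list(source_points = Y, kernel_width_beta = params$beta,
                         coefficients = W),
                    class = "nonrigid_warp")
  list(warp = warp, report = registration_report(trace, iters, sigma2, converged))
}

#' Evaluate a nonrigid warp at arbitrary points
#'
#' Displacement at `p` is the Gaussian-kernel-weighted combination of the
#' fitted coefficients; with all coefficients zero this is exactly the
#' identity map.
#'
#' @param warp a `nonrigid_warp` from [nonrigid_cpd()].
#' @param points n x 3 matrix or [tri_surface()].
#' @return n x 3 matrix of displaced points.
#' @export
warp_points <- function(warp, points) {
  p <- as_point_matrix(points)
  Gp <- exp(-dist2_matrix(p, warp$source_points) / (2 * warp$kernel_width_beta^2))
  p + Gp %*% warp$coefficients
}

#' Build correspondences from a fitted warp
#'
#' For each moving point, the corresponding point is the closest point on the
#' fixed surface (triangle-projected, not nearest vertex) to its warped
#' position; the recorded distance is the Euclidean distance between the
#' ORIGINAL (unwarped) moving point and that corresponding point, so the
#' distance between correspondence points measures the distance between the
#' surfaces.
#'
#' @param moving n x 3 matrix (or [tri_surface()]) of original moving points.
#' @param warp a `nonrigid_warp` fitted from `moving` onto a sampling of
#'   `fixed_surface`.
#' @param fixed_surface a [tri_surface()].
#' @return An object of class `correspondence_set`: `right_points` (the
#'   original moving points), `left_points` (matched points on the fixed
#'   surface), `distances_mm`, and `articular_mask` (`NULL` until the ROI
#'   rule is applied).
#' @export
correspondence_from_warp <- function(moving, warp, fixed_surface) {
  p <- as_point_matrix(moving)
  if (!inherits(fixed_surface, "tri_surface") || n_faces(fixed_surface) == 0L)
    stop("fixed_surface must be a non-empty tri_surface")
  warped <- warp_points(warp, p)
  cp <- closest_point_on_surface(warped, fixed_surface)
  d <- row_norms(p - cp$points)
  structure(list(right_points = p, left_points = cp$points,
                 distances_mm = d, articular_mask = NULL),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("correspondence_set: %d pairs, median distance %.3f mm\n",
              length(x$distances_mm), stats::median(x$distances_mm)))
  invisible(x)
}
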