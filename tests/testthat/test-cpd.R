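bone_sample <- function(n = 500, seed = 1) {
  bone <- quick_pair(seed)$truth$right_canonical
  bone$vertices[farthest_point_sample(bone$vertices, n, seed = seed), ]
}

test_that("rigid CPD self-registration returns the identity", {
  pts <- bone_sample(200)
  reg <- rigid_cpd(pts, pts, cpd_params(outlier_weight = 0))
  expect_lt(max(abs(reg$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(reg$transform$translation)), 1e-6)
  expect_lt(reg$report$final_sigma2, 1e-8)
})

test_that("rigid CPD recovers a known transform", {
  pts <- bone_sample(500)
  # 10 degrees about the long axis plus a (1, 2, 3) mm shift
  tf <- rigid_transform(axis_angle_rotation(c(0, 0, 1), 10), c(1, 2, 3))
  moved <- apply_transform(pts, tf)
  reg <- rigid_cpd(moved, pts, cpd_params())
  inv <- invert_transform(tf)
  expect_lt(rotation_angle(reg$transform$rotation %*% t(inv$rotation)), 1e-4)
  expect_lt(sqrt(sum((reg$transform$translation - inv$translation)^2)), 1e-4)
})

test_that("rigid CPD with outliers still recovers the translation", {
  pts <- bone_sample(500)
  tf <- rigid_transform(axis_angle_rotation(c(0.2, 0.1, 1), 8), c(4, -2, 6))
  moved <- apply_transform(pts, tf)
  moved_out <- with_seed(7, {
    k <- round(0.05 * nrow(moved))
    bad <- sample.int(nrow(moved), k)
    rng <- apply(moved, 2, range)
    moved[bad, ] <- cbind(runif(k, rng[1, 1], rng[2, 1]),
                          runif(k, rng[1, 2], rng[2, 2]),
                          runif(k, rng[1, 3], rng[2, 3]))
    moved
  })
  reg <- rigid_cpd(moved_out, pts, cpd_params(outlier_weight = 0.1))
  inv <- invert_transform(tf)
  expect_lt(sqrt(sum((reg$transform$translation - inv$translation)^2)), 0.1)
})

test_that("rigid CPD is equivariant under pre-applied rigid motion", {
  pts <- bone_sample(300)
  fixed <- bone_sample(300, seed = 2)
  base <- rigid_cpd(pts, fixed, cpd_params())
  for (s in 1:3) {
    tf <- with_seed(s, random_rigid_transform(10, 5))
    reg <- rigid_cpd(apply_transform(pts, tf), fixed, cpd_params())
    combined <- compose_transform(reg$transform, tf)
    expect_lt(rotation_angle(combined$rotation %*% t(base$transform$rotation)),
              1e-3)
    expect_lt(max(abs(combined$translation - base$transform$translation)), 1e-3)
  }
})

test_that("CPD objective is non-increasing and posteriors are normalized", {
  pts <- bone_sample(300)
  tf <- rigid_transform(axis_angle_rotation(c(0, 1, 0.3), 12), c(3, 1, -2))
  reg <- rigid_cpd(apply_transform(pts, tf), pts, cpd_params())
  tr <- reg$report$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
  # posterior column masses: mixture + outlier sums to 1 per data point
  TY <- apply_transform(apply_transform(pts, tf), reg$transform)
  es <- bisym:::cpd_estep(TY, pts, reg$report$final_sigma2, 0.1)
  c0 <- (2 * pi * reg$report$final_sigma2)^1.5 * 0.1 / 0.9
  K <- exp(-bisym:::dist2_matrix(TY, pts) / (2 * reg$report$final_sigma2))
  outlier_mass <- c0 / (colSums(K) + c0)
  expect_equal(colSums(es$P) + outlier_mass, rep(1, nrow(pts)),
               tolerance = 1e-10)
})

test_that("rigid CPD rejects degenerate input", {
  expect_error(rigid_cpd(matrix(rnorm(9), 3, 3), bone_sample(100)),
               "at least 4")
  flat <- cbind(matrix(rnorm(40), 20, 2), 0)
  expect_error(rigid_cpd(flat, bone_sample(100)), "degenerate")
  bad <- bone_sample(100); bad[1, 1] <- NaN
  expect_error(rigid_cpd(bad, bone_sample(100)), "non-finite")
})

test_that("nonrigid CPD: identity fit, bump fit, and lambda smoothing", {
  g <- as.matrix(expand.grid(x = seq(-15, 15, 1.5), y = seq(-15, 15, 1.5)))
  Y <- cbind(g, 0)
  # self-registration: zero displacement
  nr0 <- nonrigid_cpd(Y, Y, cpd_params())
  expect_lt(max(abs(warp_points(nr0$warp, Y) - Y)), 1e-6)
  # smooth synthetic bump: residual to the fixed surface under 0.05 mm
  X <- cbind(g, exp(-rowSums(g^2) / (2 * 5^2)))
  nr <- nonrigid_cpd(Y, X, cpd_params())
  warped <- warp_points(nr$warp, Y)
  resid <- mean(sqrt(apply(bisym:::dist2_matrix(warped, X), 1, min)))
  expect_lt(resid, 0.05)
  # large lambda approaches a smooth (near-affine) fit: displacement-field
  # roughness decreases with lambda
  roughness <- function(lam) {
    w <- nonrigid_cpd(Y, X, cpd_params(lambda = lam))$warp
    d <- warp_points(w, Y) - Y
    mean(row_norms_test(d[-1, , drop = FALSE] - d[-nrow(d), , drop = FALSE]))
  }
  expect_lt(roughness(1e6), roughness(3))
  expect_warning(nonrigid_cpd(Y, X, cpd_params(lambda = 0)), "ill-posed")
})

test_that("zero-coefficient warps are exactly the identity", {
  Y <- bone_sample(50)
  warp <- structure(list(source_points = Y, kernel_width_beta = 2,
                         coefficients = matrix(0, nrow(Y), 3)),
                    class = "nonrigid_warp")
  p <- bone_sample(120, seed = 4)
  expect_identical(warp_points(warp, p), p)
})

test_that("correspondences measure surface separation", {
  # coincident surfaces, identity warp: all distances zero
  plate <- plate_mesh(10, 20)
  warp0 <- structure(list(source_points = plate$vertices,
                          kernel_width_beta = 2,
                          coefficients = matrix(0, n_vertices(plate), 3)),
                     class = "nonrigid_warp")
  corr0 <- correspondence_from_warp(plate$vertices, warp0, plate)
  expect_lt(max(corr0$distances_mm), 1e-12)
  # two parallel plates 2 mm apart: every distance 2 mm
  upper <- plate_mesh(10, 20, z = 2)
  nr <- nonrigid_cpd(plate$vertices, upper$vertices, cpd_params())
  corr <- correspondence_from_warp(plate$vertices, nr$warp, upper)
  expect_lt(max(abs(corr$distances_mm - 2)), 1e-3)
  # offset sphere: median distance equals the analytic offset 0.5 mm
  sph <- icosphere(3, radius = 20)
  off <- icosphere(3, radius = 20.5)
  nr2 <- nonrigid_cpd(sph$vertices, off$vertices, cpd_params())
  corr2 <- correspondence_from_warp(sph$vertices, nr2$warp, off)
  expect_lt(abs(stats::median(corr2$distances_mm) - 0.5), 0.025)
  # stored distances re-derive from the stored pairs exactly
  expect_equal(corr2$distances_mm,
               row_norms_test(corr2$right_points - corr2$left_points),
               tolerance = 1e-12)
})

test_that("farthest-point sampling is deterministic and well spread", {
  pts <- bone_sample(2000, seed = 9)
  i1 <- farthest_point_sample(pts, 100, seed = 3)
  i2 <- farthest_point_sample(pts, 100, seed = 3)
  expect_identical(i1, i2)
  i3 <- farthest_point_sample(pts, 100, seed = 4)
  expect_false(identical(i1, i3))
  # spread: sampled points cover the cloud better than the first 100 rows
  cover <- function(idx) max(oracle_nearest_vertex(pts, pts[idx, ]))
  expect_lt(cover(i1), cover(seq_len(100)))
})
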