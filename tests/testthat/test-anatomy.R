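test_that("anatomical frames validate orthonormality and handedness", {
  expect_s3_class(anatomical_frame(), "anatomical_frame")
  expect_error(anatomical_frame(axis_ml = c(1, 0.1, 0)), "orthonormal")
  # left-handed triple
  expect_error(anatomical_frame(axis_ml = c(-1, 0, 0)), "right-handed")
})

test_that("frame fitting recovers the generator's canonical axes", {
  pair <- quick_pair(4)
  truth_frame <- pair$truth$frame
  fr <- fit_anatomical_frame(pair$truth$right_canonical, "right")
  ang <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi
  expect_lt(ang(fr$axis_si, truth_frame$axis_si), 3)
  expect_lt(ang(fr$axis_ml, truth_frame$axis_ml), 3)
  expect_lt(ang(fr$axis_ap, truth_frame$axis_ap), 3)
  # signs: si toward proximal, ml toward lateral (+x for a canonical right)
  expect_gt(sum(fr$axis_si * truth_frame$axis_si), 0)
  expect_gt(sum(fr$axis_ml * truth_frame$axis_ml), 0)
  # the mirrored (left) bone with side = "left" gives a consistent frame
  # for a left bone the frame keeps the malleolus at +x, so that negating
  # the frame's x axis (sagittal mirroring) yields right-bone handedness
  left_can <- pair$truth$left_canonical
  fl <- fit_anatomical_frame(left_can, "left")
  expect_lt(ang(fl$axis_si, truth_frame$axis_si), 3)
  expect_lt(ang(fl$axis_ml, c(1, 0, 0)), 3)
  tip_left <- left_can$vertices[which.min(left_can$vertices[, 3]), ]
  expect_gt(sum(tip_left * fl$axis_ml), 0)  # malleolus on the +ml side
})

test_that("frame fitting is equivariant under rigid motion", {
  bone <- quick_pair(5)$truth$right_canonical
  fr0 <- fit_anatomical_frame(bone, "right")
  for (s in 1:3) {
    tf <- with_seed(100 + s, random_rigid_transform(25, 15))
    fr <- fit_anatomical_frame(apply_transform(bone, tf), "right")
    for (ax in c("axis_ml", "axis_ap", "axis_si")) {
      rotated <- drop(tf$rotation %*% fr0[[ax]])
      ang <- acos(min(1, sum(rotated * fr[[ax]]))) * 180 / pi
      expect_lt(ang, 3)
    }
  }
})

test_that("frame fitting rejects meshes without a dominant axis", {
  expect_error(fit_anatomical_frame(icosphere(2, 10), "right"),
               "no dominant long axis")
})

test_that("the most distal point is the malleolus tip, ties to lowest index", {
  pair <- quick_pair(6)
  bone <- pair$truth$right_canonical
  fr <- pair$truth$frame
  mdp <- most_distal_point(bone, fr)
  expect_equal(attr(mdp, "index"), attr(pair$truth$malleolus_tip, "index"))
  expect_equal(unclass(mdp), unname(pair$truth$malleolus_tip),
               ignore_attr = TRUE)
  # translation equivariance
  shifted <- bone
  shifted$vertices <- sweep(shifted$vertices, 2, c(0, 0, 5), "+")
  mdp2 <- most_distal_point(shifted, fr)
  expect_equal(unclass(mdp2) - unclass(mdp), c(0, 0, 5), ignore_attr = TRUE)
  # flat-bottomed cylinder: tie broken toward the smallest vertex index
  cyl <- cylinder_mesh(5, 20, ntheta = 16, nz = 4)
  expect_equal(attr(most_distal_point(cyl, anatomical_frame()), "index"), 1L)
})

test_that("reference point is the distal centre at malleolus-tip height", {
  # vertically-axised cylinder: reference point on the axis at the base
  cyl <- cylinder_mesh(radius = 8, height = 30, ntheta = 32, nz = 6)
  ref <- reference_point(cyl, anatomical_frame())
  expect_equal(ref, c(0, 0, 0), tolerance = 1e-9)
  # hand-computed componentwise mean on a listed vertex table
  v <- cbind(x = c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4),
             y = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4),
             z = c(5, 4, 6, 7, 3, 8, 9, 4, 6, 7))
  mesh <- tri_surface(v, rbind(c(1, 2, 3)), validate = FALSE)
  ref2 <- reference_point(mesh, anatomical_frame())
  expect_equal(ref2, c(mean(v[, 1]), mean(v[, 2]), min(v[, 3])))
  # translation equivariance
  mesh2 <- mesh
  mesh2$vertices <- sweep(v, 2, c(-2, 4, 1), "+")
  expect_equal(reference_point(mesh2, anatomical_frame()), ref2 + c(-2, 4, 1))
})

test_that("articular selection matches the dot-product oracle on fixtures", {
  oracle <- function(mesh, ref) {
    nrm <- compute_vertex_normals(mesh)$normals
    sel <- rowSums(nrm * (-sweep(mesh$vertices, 2, ref))) > 0
    sel[mesh$boundary] <- FALSE
    sel
  }
  # downward-facing plate with the reference point beneath it: all selected
  plate <- plate_mesh(8, 20)
  plate$faces <- plate$faces[, c(1, 3, 2)]  # normals now (0, 0, -1)
  ref <- c(10, 10, -10)
  m <- select_articulating_surface(compute_vertex_normals(plate), ref)
  expect_true(all(m$selected))
  expect_identical(m$selected, oracle(plate, ref))
  # vertical shaft wall, reference on the axis at the base: none selected
  cyl <- cylinder_mesh(radius = 6, height = 40, ntheta = 24, nz = 8)
  m2 <- select_articulating_surface(compute_vertex_normals(cyl), c(0, 0, 0))
  expect_false(any(m2$selected))
  expect_identical(m2$selected, oracle(cyl, c(0, 0, 0)))
  # sphere centred on the reference point: angle exactly 180, none selected
  sph <- icosphere(2, 10)
  m3 <- select_articulating_surface(compute_vertex_normals(sph), c(0, 0, 0))
  expect_false(any(m3$selected))
  expect_identical(m3$selected, oracle(sph, c(0, 0, 0)))
})

test_that("articular selection on the plafond has high recall, excludes shaft", {
  pair <- quick_pair(7)
  bone <- pair$truth$right_canonical
  fr <- pair$truth$frame
  cut <- cut_at_height(bone, fr, 30)
  distal <- compute_vertex_normals(cut$distal_part)
  ref <- reference_point(distal, fr)
  mask <- select_articulating_surface(distal, ref)
  # map generator labels onto the cut mesh by coordinates
  lab_of <- function(idx_set) {
    lab_pts <- bone$vertices[idx_set, , drop = FALSE]
    d <- oracle_nearest_vertex(distal$vertices, lab_pts)
    d < 1e-9
  }
  plaf <- lab_of(pair$truth$plafond_mask) & !seq_len(n_vertices(distal)) %in% distal$boundary
  expect_gt(sum(mask$selected & plaf) / sum(plaf), 0.9)
  shaft_wall <- lab_of(which(pair$truth$labels %in% "shaft_wall"))
  expect_false(any(mask$selected & shaft_wall))
})
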