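test_that("PLY round-trips preserve geometry and connectivity", {
  tet <- tetra_mesh()
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    save_mesh(tet, path, binary = binary)
    back <- load_mesh(path)
    expect_equal(n_vertices(back), 4L)
    expect_equal(n_faces(back), 4L)
    expect_equal(signed_volume(back), 1 / 6, tolerance = 1e-12)
  }
  sph <- icosphere(3, radius = 25)
  expect_equal(n_vertices(sph), 642L)
  path <- withr::local_tempfile(fileext = ".ply")
  save_mesh(sph, path)
  back <- load_mesh(path)
  # vertex order may change through the duplicate merge; compare as sets
  d <- oracle_nearest_vertex(back$vertices, sph$vertices)
  expect_lt(max(d), 1e-6)
  expect_equal(n_faces(back), n_faces(sph))
})

test_that("STL files round-trip with duplicated vertices merged", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  save_mesh(tet, path)
  txt <- readLines(path)
  expect_length(grep("^\\s*vertex", txt), 12L)  # 3 per facet before merging
  back <- load_mesh(path)
  # oracle: count of unique coordinate triples
  expect_equal(n_vertices(back),
               nrow(unique(round(tet$vertices, 9))))
  expect_equal(abs(signed_volume(back)), 1 / 6, tolerance = 1e-9)
})

test_that("OBJ files round-trip", {
  cube <- cube_mesh()
  path <- withr::local_tempfile(fileext = ".obj")
  save_mesh(cube, path)
  back <- load_mesh(path)
  expect_equal(n_vertices(back), 8L)
  expect_equal(signed_volume(back), 1, tolerance = 1e-12)
})

test_that("malformed mesh files raise format errors", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 10",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0",
               "3 0 1 2"), path)
  expect_error(load_mesh(path), "declares 10 records")
  expect_error(load_mesh(withr::local_tempfile(fileext = ".ply")), "does not exist")
  path2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 0", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0"), path2)
  expect_error(load_mesh(path2), "empty mesh")
})

test_that("per-vertex scalars travel through PLY and are rejected elsewhere", {
  tet <- tetra_mesh()
  q <- c(0.1, 0.5, 2.5, 7)
  path <- withr::local_tempfile(fileext = ".ply")
  save_mesh(tet, path, per_vertex_scalar = q)
  back <- load_mesh(path)
  expect_equal(sort(attr(back, "quality")), sort(q), tolerance = 1e-12)
  expect_error(save_mesh(tet, path, per_vertex_scalar = q[1:3]),
               "one value per vertex")
  stl <- withr::local_tempfile(fileext = ".stl")
  expect_warning(save_mesh(tet, stl, per_vertex_scalar = q),
                 "cannot carry per-vertex scalars")
})

test_that("vertex normals are area-weighted, unit, and outward", {
  cube <- compute_vertex_normals(cube_symmetric())
  # corner symmetry: all components equal in magnitude, pointing away from centre
  expect_equal(abs(cube$normals[1:8, ]), matrix(1 / sqrt(3), 8, 3),
               tolerance = 1e-12)
  expect_true(all(rowSums(cube$normals * cube$vertices) > 0))

  sph <- compute_vertex_normals(icosphere(3))
  radial <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  ang <- acos(pmin(1, rowSums(sph$normals * radial))) * 180 / pi
  expect_lt(max(ang), 2)  # radial-direction oracle for an analytic sphere
  expect_equal(row_norms_test(sph$normals), rep(1, 642), tolerance = 1e-9)

  plate <- compute_vertex_normals(plate_mesh(5, 10))
  expect_equal(plate$normals, matrix(rep(c(0, 0, 1), each = 36), 36, 3),
               tolerance = 1e-12)
})

test_that("closed meshes have positive volume and outward mean orientation", {
  for (mesh in list(tetra_mesh(), cube_mesh(), icosphere(2, 7))) {
    expect_gt(signed_volume(mesh), 0)
    m <- compute_vertex_normals(mesh)
    ctr <- colMeans(m$vertices)
    expect_gt(mean(rowSums(m$normals * sweep(m$vertices, 2, ctr))), 0)
  }
})

test_that("mirroring is involutive and preserves signed volume", {
  tet <- tetra_mesh()
  m1 <- suppressWarnings(mirror_sagittal(tet))
  expect_equal(signed_volume(m1), 1 / 6, tolerance = 1e-15)  # winding repaired
  m2 <- suppressWarnings(mirror_sagittal(m1))
  expect_identical(m2$vertices, tet$vertices)  # exact negation is involutive
  expect_warning(mirror_sagittal(tet), "global x = 0")
  # mesh symmetric about x = 0: mirror equals original up to reindexing
  cube <- cube_mesh()
  mc <- mirror_sagittal(cube, frame = anatomical_frame())
  expect_equal(max(oracle_nearest_vertex(mc$vertices, cube$vertices)), 0)
  expect_equal(max(oracle_nearest_vertex(cube$vertices, mc$vertices)), 0)
  # mirroring across a frame's sagittal plane is an involution too
  fr <- fit_anatomical_frame(quick_pair(3)$right, "right")
  bone <- quick_pair(3)$right
  back <- mirror_sagittal(mirror_sagittal(bone, fr), fr)
  expect_equal(back$vertices, bone$vertices, tolerance = 1e-12)
})

test_that("cutting clips exactly at the plane and conserves area", {
  cyl <- cylinder_mesh(radius = 10, height = 100, ntheta = 128, nz = 100)
  fr <- anatomical_frame()
  cut <- cut_at_height(cyl, fr, 30)
  # closed-form lateral area oracle
  expect_equal(surface_area(cut$distal_part), 2 * pi * 10 * 30,
               tolerance = 5e-3)
  expect_lte(max(cut$distal_part$vertices[, 3]), 30 + 1e-9)
  # boundary loop lies on the plane
  expect_true(!is.null(cut$boundary_loop))
  expect_lt(max(abs(cut$boundary_loop[, 3] - 30)), 1e-9)
  # boundary vertices marked and on-plane
  b <- cut$distal_part$boundary
  expect_true(length(b) > 0)
  expect_lt(max(abs(cut$distal_part$vertices[b, 3] - 30)), 1e-9)
  # area conservation across both parts, arbitrary oblique plane
  bone <- quick_pair(2)$right
  parts <- bisym:::clip_by_plane(bone, colMeans(bone$vertices),
                                 c(0.3, -0.2, 0.93))
  expect_equal(surface_area(parts$below) + surface_area(parts$above),
               surface_area(bone), tolerance = 1e-6)
})

test_that("cut tie and degenerate-plane rules hold", {
  cyl <- cylinder_mesh(radius = 5, height = 50, ntheta = 32, nz = 10)
  fr <- anatomical_frame()
  # plane above the whole mesh: whole mesh returned, empty loop
  cut <- cut_at_height(cyl, fr, 200)
  expect_equal(n_vertices(cut$distal_part), n_vertices(cyl))
  expect_null(cut$boundary_loop)
  # plane exactly through a ring of vertices (ring spacing 5 mm): the
  # on-plane ring is retained in the distal part
  cut2 <- cut_at_height(cyl, fr, 25)
  expect_equal(sum(abs(cut2$distal_part$vertices[, 3] - 25) <= 1e-9), 32L)
  expect_lte(max(cut2$distal_part$vertices[, 3]), 25 + 1e-9)
  expect_error(cut_at_height(cyl, fr, -5), "positive")
})

test_that("duplicate-vertex merge collapses coincident vertices only", {
  tet <- tetra_mesh()
  v2 <- rbind(tet$vertices, tet$vertices + 1e-9)
  f2 <- rbind(tet$faces, tet$faces + 4L)
  merged <- merge_duplicate_vertices(tri_surface(v2, f2, validate = FALSE))
  expect_equal(n_vertices(merged), 4L)
  far <- merge_duplicate_vertices(tri_surface(rbind(tet$vertices,
                                                    tet$vertices + 0.5),
                                              f2, validate = FALSE))
  expect_equal(n_vertices(far), 8L)
})

test_that("mesh validation rejects broken inputs", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_surface(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(tri_surface(v, rbind(c(1, 2, 2))), "repeated vertex")
  expect_error(tri_surface(rbind(v, c(NA, 0, 0)), rbind(c(1, 2, 3))),
               "non-finite")
  expect_error(tri_surface(v, matrix(integer(0), 0, 3)), "empty mesh")
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(tri_surface(collinear, rbind(c(1, 2, 3))), "area below tolerance")
})
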