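test_that("TriMesh validation enforces the type invariants", {
  expect_error(tri_mesh(diag(3), rbind(c(1, 2, 99))), "out of range")
  expect_error(tri_mesh(diag(3), rbind(c(1, 2, 2))), "repeated")
  # degenerate (collinear) triangles are dropped; all-degenerate errors
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  m <- tri_mesh(V, rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(nrow(m$triangles), 1L)
  expect_error(tri_mesh(V, rbind(c(1, 2, 3))), "degenerate")
})

test_that("round-trip read/write is lossless for all three formats", {
  m <- random_patch(seed = 3)
  for (fmt in c("ply", "vtk", "off")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
    expect_identical(m2$triangles, m$triangles)
    # second round trip through a reread
    f2 <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m2, f2)
    m3 <- read_mesh(f2)
    expect_lt(max(abs(m3$vertices - m$vertices)), 1e-6)
    unlink(c(f, f2))
  }
  # binary little-endian PLY
  f <- tempfile(fileext = ".ply")
  write_mesh(m, f, binary = TRUE)
  m2 <- read_mesh(f)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  unlink(f)
})

test_that("a hand-written tetrahedron PLY parses; bad indices error", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2"), f)
  m <- read_mesh(f)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$triangles), 4L)
  # face index 99 on a 4-vertex mesh
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "3 0 1 99"), f)
  expect_error(read_mesh(f), "out of range")
  unlink(f)
})

test_that("quads are split along the 0-2 diagonal", {
  f <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), f)
  m <- read_mesh(f)
  expect_equal(m$triangles, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  unlink(f)
})

test_that("triangle centres and tangents have their closed forms", {
  ct <- triangle_centres_and_tangents(unit_triangle())
  expect_equal(ct$centres[1, ], c(1 / 3, 1 / 3, 0))
  expect_equal(ct$tangents[1, ], c(0, 0, 0.5))
  # equilateral, side 2, in z = 0: |tau| = area = sqrt(3)
  eq <- tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                 rbind(c(1, 2, 3)))
  expect_equal(sqrt(sum(triangle_centres_and_tangents(eq)$tangents^2)),
               sqrt(3))
  # divergence theorem: area-weighted normals of a closed surface sum to 0
  ico <- icosphere(2)
  expect_lt(sqrt(sum(colSums(
    triangle_centres_and_tangents(ico)$tangents)^2)), 1e-9)
})

test_that("mirroring is an involution, maps points correctly and preserves areas", {
  m <- random_patch(seed = 4)
  mm <- mirror_mesh(mirror_mesh(m, 2.5), 2.5)
  expect_lt(max(abs(mm$vertices - m$vertices)), 1e-12)
  p <- tri_mesh(rbind(c(1, 2, 3), c(2, 2, 3), c(1, 3, 3)), rbind(c(1, 2, 3)))
  expect_equal(mirror_mesh(p, 0)$vertices[1, ], c(-1, 2, 3))
  expect_equal(triangle_areas(mirror_mesh(m, 1)), triangle_areas(m))
  # composed with the varifold metric: double mirror is metrically identical
  expect_lt(varifold_sqdist(m, mirror_mesh(mirror_mesh(m, 1), 1),
                            varifold_config(2)), 1e-9)
})

test_that("cohort CSV round-trips through read_cohort", {
  dir <- tempfile()
  dir.create(dir)
  m <- small_ellipsoid()
  write_mesh(m, file.path(dir, "l.ply"))
  write_mesh(translate_mesh(m, c(1, 0, 0)), file.path(dir, "r.ply"))
  write.csv(data.frame(subject_id = "S1", left_mesh = "l.ply",
                       right_mesh = "r.ply", eyo = -12.5, group = "carrier",
                       sex = "F", site = "site1", family_id = "F01"),
            file.path(dir, "cohort.csv"), row.names = FALSE)
  co <- read_cohort(file.path(dir, "cohort.csv"))
  expect_length(co, 1)
  expect_s3_class(co[[1]], "SubjectRecord")
  expect_equal(co[[1]]$eyo, -12.5)
  expect_equal(nrow(co[[1]]$right_mesh$vertices), nrow(m$vertices))
  expect_error(subject_record("S2", m, m, NA, "carrier", "M", "a", "f"))
  expect_error(subject_record("S2", m, m, 0, "other", "M", "a", "f"))
  unlink(dir, recursive = TRUE)
})
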