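test_that("minimal ASCII STL parses with vertex welding", {
  stl <- c("solid tet")
  tet <- unit_tetrahedron()
  v <- tet$vertices
  for (i in seq_len(nrow(tet$faces))) {
    fv <- v[tet$faces[i, ], , drop = FALSE]
    stl <- c(stl, "  facet normal 0 0 0", "    outer loop",
             sprintf("      vertex %g %g %g", fv[, 1], fv[, 2], fv[, 3]),
             "    endloop", "  endfacet")
  }
  stl <- c(stl, "endsolid tet")
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(stl, path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
})

test_that("minimal OBJ parses; polygons fan-triangulate; strict mode rejects", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "vn 0 0 1", "f 1//1 2//1 3//1"),
             path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  # quad face
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), path)
  expect_equal(nrow(read_mesh(path)$faces), 2L)
  expect_error(read_mesh(path, strict = TRUE), "strict")
})

test_that("binary STL layout: 80-byte header and facet count", {
  tet <- unit_tetrahedron()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, path)
  expect_equal(file.size(path), 80 + 4 + 50 * 4)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  expect_equal(readBin(con, "integer", 1, size = 4, endian = "little"), 4L)
})

test_that("mesh round-trips preserve geometry", {
  set.seed(42)
  soup <- random_soup(40, scale = 30)
  for (fmt in c("stl", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(soup, path)
    back <- read_mesh(path)
    # STL welds vertices; compare per-face corner coordinates
    orig_tris <- soup$vertices[t(soup$faces), ]
    back_tris <- back$vertices[t(back$faces), ]
    tol <- if (fmt == "stl") 1e-4 else 1e-5  # binary STL stores float32
    expect_equal(orig_tris, back_tris, tolerance = tol, ignore_attr = TRUE)
  }
  # ASCII STL round trip too
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(soup, path, ascii = TRUE)
  back <- read_mesh(path)
  expect_equal(soup$vertices[t(soup$faces), ], back$vertices[t(back$faces), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("mesh validation rejects malformed input", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 5))), "out of range")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))), "degenerate")
  expect_error(triangle_mesh(matrix(c(0, 0, NA), 1, 3), rbind(c(1, 1, 1))), ".")
  expect_error(read_mesh(tempfile()), "no such file")
})

test_that("landmark CSV round trip and validation", {
  lm <- landmark_set(paste0("G", 1:6), matrix(rnorm(18), ncol = 3), "image")
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$points, lm$points, tolerance = 1e-12)
  expect_equal(back$frame, "image")
  # duplicate labels rejected
  writeLines(c("label,x,y,z", "G1,0,0,0", "G1,1,1,1"), path)
  expect_error(read_landmarks(path), "duplicate")
  # missing coordinate rejected
  writeLines(c("label,x,y,z", "G1,0,,0"), path)
  expect_error(read_landmarks(path), "missing coordinate")
})

test_that("Slicer markup dialect converts RAS to LPS", {
  lm <- landmark_set(c("LFL", "RFL", "MSL"),
                     rbind(c(1, 2, 3), c(-4, 5, 6), c(0, 0, 1)), "image")
  path <- withr::local_tempfile(fileext = ".fcsv")
  write_landmarks(lm, path, dialect = "slicer")
  back <- read_landmarks(path, dialect = "slicer")
  expect_equal(back$points, lm$points, tolerance = 1e-7)
  # with conversion off, x/y come back sign-flipped (raw RAS values)
  raw <- read_landmarks(path, dialect = "slicer", ras_to_lps = FALSE)
  expect_equal(raw$points[, 1:2], -lm$points[, 1:2], tolerance = 1e-7)
  expect_equal(raw$points[, 3], lm$points[, 3], tolerance = 1e-7)
  # auto-detection by extension/content
  expect_equal(read_landmarks(path)$points, lm$points, tolerance = 1e-7)
})

test_that("parsing is deterministic", {
  set.seed(7)
  soup <- random_soup(20)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(soup, path)
  m1 <- read_mesh(path)
  m2 <- read_mesh(path)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})
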