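# Mesh substrate: STL I/O, integrity, measurement, transform invariances.

test_that("box and single-triangle measurements match closed forms", {
  m <- box_mesh()
  expect_equal(surface_area(m), 6.0)
  expect_equal(enclosed_volume(m), 1.0)
  tri <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)
})

test_that("icosphere area and volume converge to the sphere closed forms", {
  s <- icosphere_mesh(2, 4)
  expect_lt(abs(surface_area(s) - 16 * pi) / (16 * pi), 0.01)
  expect_lt(abs(enclosed_volume(s) - 32 * pi / 3) / (32 * pi / 3), 0.01)
})

test_that("area and volume are rigid-motion invariant and scale correctly", {
  m <- icosphere_mesh(1.5, 2, center = c(0.3, -0.2, 0.7))
  a0 <- surface_area(m)
  v0 <- enclosed_volume(m)
  mt <- rotate_mesh(translate_mesh(m, c(3.2, -1.1, 0.4)), 0.83, "y")
  expect_equal(surface_area(mt), a0, tolerance = 1e-9)
  expect_equal(enclosed_volume(mt), v0, tolerance = 1e-9)
  for (s in c(0.5, 2.3)) {
    ms <- scale_mesh(m, s)
    expect_equal(surface_area(ms), s^2 * a0, tolerance = 1e-9)
    expect_equal(enclosed_volume(ms), s^3 * v0, tolerance = 1e-9)
  }
})

test_that("watertightness check counts open edges and winding faults", {
  m <- box_mesh()
  expect_true(is_watertight(m))
  open_m <- mesh(m$vertices, m$faces[-1, ])   # drop one face
  rep <- mesh_integrity(open_m)
  expect_false(rep$watertight)
  expect_equal(rep$open_edges, 3L)
  err <- tryCatch(enclosed_volume(open_m), error = function(e) e)
  expect_s3_class(err, "mesh_integrity_error")
  expect_match(conditionMessage(err), "3 open edge")
  flipped <- m
  flipped$faces[4, ] <- rev(flipped$faces[4, ])  # inconsistent winding
  expect_false(is_watertight(flipped))
})

test_that("inverted global orientation yields |volume| with a warning", {
  m <- box_mesh()
  m$faces <- m$faces[, c(1, 3, 2)]  # flip all faces consistently
  expect_warning(v <- enclosed_volume(m), "inverted")
  expect_equal(v, 1.0)
})

test_that("binary STL round trip preserves the mesh and the size formula", {
  m <- box_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, path, "binary")
  expect_equal(file.size(path), 84 + 12 * 50)
  m2 <- read_stl(path)
  expect_equal(nrow(m2$vertices), 8L)
  expect_equal(nrow(m2$faces), 12L)
  expect_meshes_equal(m, m2)
  expect_true(is_watertight(m2))
})

test_that("ASCII STL round trip equals the binary route", {
  m <- icosphere_mesh(1.2, 1)
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, pa, "ascii")
  write_stl(m, pb, "binary")
  ma <- read_stl(pa)
  mb <- read_stl(pb)
  expect_meshes_equal(ma, mb, tol = 1e-5)
  expect_equal(surface_area(ma), surface_area(m), tolerance = 1e-5)
  expect_true(is_watertight(ma))
})

test_that("generated tooth survives a binary STL round trip", {
  m <- fast_tooth(3, pitch = 0.35)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, path, "binary")
  m2 <- read_stl(path)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  expect_true(is_watertight(m2))
  expect_equal(enclosed_volume(m2), enclosed_volume(m), tolerance = 1e-4)
})

test_that("malformed STL inputs raise parse errors naming the defect", {
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(box_mesh(), path, "binary")
  raw <- readBin(path, "raw", n = file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw[1:300], trunc_path)  # truncated mid-facet
  err <- tryCatch(read_stl(trunc_path), error = function(e) e)
  expect_s3_class(err, "stl_parse_error")
  expect_match(conditionMessage(err), "byte")
  empty_path <- withr::local_tempfile(fileext = ".stl")
  file.create(empty_path)
  expect_error(read_stl(empty_path), class = "empty_mesh_error")
  expect_error(write_stl(mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         withr::local_tempfile()),
               class = "empty_mesh_error")
})
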