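# Hausdorff distance, signed deviation and Dice against brute force.

test_that("self-comparison is the identity report", {
  m <- icosphere_mesh(1.5, 2)
  expect_equal(directed_hausdorff(m, m, 500), 0, tolerance = 1e-9)
  expect_equal(symmetric_hausdorff(m, m, 500), 0, tolerance = 1e-9)
  expect_equal(signed_deviation_range(m, m, 500), c(0, 0), tolerance = 1e-9)
  rep <- compare_meshes(m, m, pitch = 0.1, n_samples = 500)
  expect_equal(rep$dsc, 1.0)
  expect_equal(rep$hd, 0, tolerance = 1e-9)
  expect_equal(rep$msa_a, rep$msa_b)
  expect_equal(rep$vv_a, rep$vv_b)
})

test_that("translated cube has Hausdorff distance equal to the offset", {
  a <- box_mesh()
  b <- translate_mesh(box_mesh(), c(0.3, 0, 0))
  # closed form: every far-face point of A is exactly 0.3 from B
  expect_equal(directed_hausdorff(a, b, 2000), 0.3, tolerance = 0.01)
  expect_equal(symmetric_hausdorff(a, b, 2000), 0.3, tolerance = 0.01)
})

test_that("scaled cube Hausdorff equals the corner offset 0.05*sqrt(3)", {
  a <- box_mesh()
  b <- scale_mesh(box_mesh(), 1.1)
  # corners of B protrude by 0.05*sqrt(3) from A; A's vertices are sampled
  # so the directed distance B->A attains the corner offset exactly
  expect_equal(symmetric_hausdorff(a, b, 5000), 0.05 * sqrt(3),
               tolerance = 1e-6)
  expect_equal(symmetric_hausdorff(a, b, 5000),
               symmetric_hausdorff(b, a, 5000))
})

test_that("sampled distances agree with a brute-force oracle", {
  a <- icosphere_mesh(1, 1)
  b <- translate_mesh(icosphere_mesh(1, 1), c(0.35, 0.1, -0.2))
  pts <- sample_surface_points(a, 150, seed = 3)
  fast <- crownforge:::cpp_surface_distance(pts, b$vertices, b$faces - 1L)
  slow <- oracle_surface_dist(pts, b)
  # oracle scans barycentric grids, so it upper-bounds the true distance
  # (its own resolution limits agreement to ~ edge/20)
  expect_true(all(fast <= slow + 1e-9))
  expect_lt(max(abs(fast - slow)), 0.02)
  ins_fast <- crownforge:::cpp_points_in_mesh(pts, b$vertices, b$faces - 1L)
  expect_identical(as.vector(ins_fast), as.vector(oracle_inside(pts, b)))
})

test_that("directed Hausdorff is monotone in the sample count (nested)", {
  a <- fast_tooth(4, pitch = 0.4)
  b <- translate_mesh(fast_tooth(5, pitch = 0.4), c(0.1, 0.05, 0))
  vals <- sapply(c(200, 800, 3200), function(n)
    directed_hausdorff(a, b, n, seed = 11))
  expect_true(all(diff(vals) >= 0))
})

test_that("strict containment makes the outer direction dominate", {
  inner <- box_mesh(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8))
  outer <- box_mesh()
  d_io <- directed_hausdorff(inner, outer, 2000)
  d_oi <- directed_hausdorff(outer, inner, 2000)
  expect_gt(d_oi, d_io)
  expect_equal(symmetric_hausdorff(inner, outer, 2000), d_oi)
})

test_that("signed deviation resolves shrunken and bulged fixtures", {
  ref <- box_mesh()
  shrunk <- box_mesh(rep(0.02, 3), rep(0.98, 3))
  sd1 <- signed_deviation_range(shrunk, ref, 3000)
  expect_equal(sd1[1], -0.02, tolerance = 0.002)
  expect_equal(sd1[2], -0.02, tolerance = 0.002)
  bulged <- box_mesh(c(0, 0, 0), c(1, 1, 1.1))  # top face pushed out 0.1
  sd2 <- signed_deviation_range(bulged, ref, 3000)
  expect_equal(sd2[2], 0.1, tolerance = 0.003)
})

test_that("Dice equals the closed form on constructed and random grids", {
  base <- array(FALSE, c(4, 4, 4))
  a <- base; a[1:2, , ] <- TRUE   # slab x in {0,1}: 32 voxels
  b <- base; b[2:3, , ] <- TRUE   # slab x in {1,2}: 32 voxels
  ga <- voxel_grid(a, c(0, 0, 0), 1)
  gb <- voxel_grid(b, c(0, 0, 0), 1)
  expect_equal(dice_coefficient(ga, gb), 2 * 16 / 64)
  expect_equal(dice_coefficient(ga, gb), dice_coefficient(gb, ga))
  expect_equal(dice_coefficient(ga, ga), 1.0)
  disjoint <- base; disjoint[4, , ] <- TRUE
  expect_equal(dice_coefficient(ga, voxel_grid(disjoint, c(0, 0, 0), 1)), 0)
  set.seed(42)
  for (i in 1:20) {
    d <- sample(3:16, 3, replace = TRUE)
    oa <- array(runif(prod(d)) < 0.4, d)
    ob <- array(runif(prod(d)) < 0.4, d)
    if (sum(oa) + sum(ob) == 0) next
    got <- dice_coefficient(voxel_grid(oa, c(0, 0, 0), 0.5),
                            voxel_grid(ob, c(0, 0, 0), 0.5))
    expect_equal(got, 2 * sum(oa & ob) / (sum(oa) + sum(ob)))
  }
})

test_that("Dice validates frames and emptiness", {
  a <- voxel_grid(array(TRUE, c(2, 2, 2)), c(0, 0, 0), 1)
  b <- voxel_grid(array(TRUE, c(2, 2, 2)), c(0.5, 0, 0), 1)
  expect_error(dice_coefficient(a, b), class = "frame_mismatch_error")
  e <- voxel_grid(array(FALSE, c(2, 2, 2)), c(0, 0, 0), 1)
  expect_error(dice_coefficient(e, e), class = "undefined_input_error")
})

test_that("report invariant hd >= max|signed deviation| - pitch holds", {
  set.seed(7)
  for (i in 1:6) {
    a <- icosphere_mesh(runif(1, 0.8, 1.3), 1, center = runif(3, -0.1, 0.1))
    b <- icosphere_mesh(runif(1, 0.8, 1.3), 1, center = runif(3, -0.1, 0.1))
    rep <- compare_meshes(a, b, pitch = 0.1, n_samples = 800, seed = i)
    expect_gte(rep$hd, max(abs(c(rep$signed_dev_min, rep$signed_dev_max))) -
                 rep$pitch_used)
    expect_gte(rep$hd, 0)
    expect_lte(rep$signed_dev_min, rep$signed_dev_max)
    expect_true(rep$dsc >= 0 && rep$dsc <= 1)
  }
})
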