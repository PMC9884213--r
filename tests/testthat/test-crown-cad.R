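# CAD synthesis: Boolean identities, conservation, fit checks and the
# cross-method consistency of the two design routes.

make_cube_fixture <- function(pitch = 0.1) {
  tmpl <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  cavity <- box_mesh(c(3, 3, 8), c(7, 7, 10.5))  # 4x4x2 mm cavity, open top
  fr <- crownforge:::grid_frame(pitch, list(lo = rep(-0.5, 3),
                                            hi = rep(10.5, 3)))
  ft <- crownforge:::mesh_sdf_grid(tmpl, fr$origin, fr$shape, pitch)
  fc <- crownforge:::mesh_sdf_grid(cavity, fr$origin, fr$shape, pitch)
  prep <- crownforge:::contour_field_grid(pmin(ft, -fc), fr$origin, pitch)
  list(template = tmpl, prep = prep)
}

test_that("Boolean design reproduces the enumerated cavity volume", {
  fx <- make_cube_fixture()
  des <- design_prosthesis_boolean(fx$prep, fx$template, "inlay",
                                   cad_config(pitch = 0.1, smooth_iters = 0))
  expect_true(is_watertight(des$prosthesis))
  expect_equal(enclosed_volume(des$prosthesis), 32, tolerance = 0.02)
  # penetration bounded by 2 voxels equivalent
  expect_lte(des$fit$penetration_volume, 2 * 0.1^3 + 1e-9)
  expect_gte(des$fit$restored_dice, 0.99)
})

test_that("Boolean identity: prosthesis union preparation restores template", {
  fx <- make_cube_fixture()
  des <- design_prosthesis_boolean(fx$prep, fx$template, "inlay",
                                   cad_config(pitch = 0.1, smooth_iters = 0))
  pitch <- 0.1
  b <- shared_bounds(list(fx$template, fx$prep, des$prosthesis), pitch)
  gt <- voxelize(fx$template, pitch, b)
  gp <- voxelize(fx$prep, pitch, b)
  gd <- voxelize(des$prosthesis, pitch, b)
  restored <- voxel_grid(gp$occupancy | gd$occupancy, gt$origin, pitch)
  expect_gte(dice_coefficient(restored, gt), 0.99)
  # conservation within 2%
  vol_err <- abs(enclosed_volume(des$prosthesis) + enclosed_volume(fx$prep) -
                   enclosed_volume(fx$template))
  expect_lt(vol_err / enclosed_volume(fx$template), 0.02)
})

test_that("designing against an identical template is an empty design", {
  fx <- make_cube_fixture()
  expect_error(design_prosthesis_boolean(fx$template, fx$template, "inlay",
                                         cad_config(pitch = 0.2)),
               class = "empty_design_error")
})

test_that("design is idempotent under a fixed configuration", {
  fx <- make_cube_fixture(pitch = 0.2)
  d1 <- design_prosthesis_boolean(fx$prep, fx$template, "inlay",
                                  cad_config(pitch = 0.2))
  d2 <- design_prosthesis_boolean(fx$prep, fx$template, "inlay",
                                  cad_config(pitch = 0.2))
  expect_identical(d1$prosthesis$vertices, d2$prosthesis$vertices)
})

test_that("surface reconstruction conserves cavity volume on tooth anatomy", {
  tooth <- fast_tooth(2, pitch = 0.18)
  spec <- preparation_spec("inlay")
  prep <- apply_inlay_preparation(tooth, spec)
  cavity <- preparation_cavity_solid(tooth, spec)
  cfg <- cad_config(pitch = 0.12)
  sr <- design_inlay_surface_reconstruction(prep, tooth, cfg)
  expect_true(is_watertight(sr$prosthesis))
  expect_equal(enclosed_volume(sr$prosthesis), enclosed_volume(cavity),
               tolerance = 0.08 * enclosed_volume(cavity))
  # cross-method consistency with the Boolean route
  bo <- design_prosthesis_boolean(prep, tooth, "inlay", cfg)
  b <- shared_bounds(list(sr$prosthesis, bo$prosthesis), 0.1)
  d <- dice_coefficient(voxelize(sr$prosthesis, 0.1, b),
                        voxelize(bo$prosthesis, 0.1, b))
  expect_gte(d, 0.95)
  # workflow outputs differ but stay close (both workflows usable)
  expect_gt(symmetric_hausdorff(sr$prosthesis, bo$prosthesis, 2000), 0)
  expect_gte(d, 0.90)
})

test_that("surface reconstruction without a cavity fails cleanly", {
  tooth <- fast_tooth(3, pitch = 0.25)
  expect_error(design_inlay_surface_reconstruction(tooth, NULL,
                                                   cad_config(pitch = 0.2)),
               class = "no_cavity_error")
})

test_that("morphological closing caps the cavity when no reference exists", {
  tooth <- fast_tooth(4, pitch = 0.2)
  spec <- preparation_spec("inlay")
  prep <- apply_inlay_preparation(tooth, spec)
  cavity <- preparation_cavity_solid(tooth, spec)
  sr <- design_inlay_surface_reconstruction(prep, NULL,
                                            cad_config(pitch = 0.15))
  expect_true(is_watertight(sr$prosthesis))
  # the closing-based cap recovers most of the cavity volume
  expect_gt(enclosed_volume(sr$prosthesis), 0.5 * enclosed_volume(cavity))
  expect_lt(enclosed_volume(sr$prosthesis), 1.5 * enclosed_volume(cavity))
})

test_that("fit check flags a displaced prosthesis", {
  fx <- make_cube_fixture(pitch = 0.15)
  des <- design_prosthesis_boolean(fx$prep, fx$template, "inlay",
                                   cad_config(pitch = 0.15, smooth_iters = 0))
  good <- check_fit(des$prosthesis, fx$prep, fx$template, pitch = 0.15)
  expect_lte(good$penetration_volume, 2 * 0.15^3 + 1e-9)
  moved <- translate_mesh(des$prosthesis, c(0.5, 0, 0))
  bad <- check_fit(moved, fx$prep, fx$template, pitch = 0.15)
  expect_gt(bad$penetration_volume, 0)
  expect_gt(bad$margin_max_gap, good$margin_max_gap)
  expect_error(check_fit(mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         fx$prep, fx$template),
               class = "empty_mesh_error")
})

test_that("prosthesis floor never undercuts the cavity floor", {
  tooth <- fast_tooth(5, pitch = 0.2)
  spec <- preparation_spec("onlay")
  prep <- apply_onlay_preparation(tooth, spec)
  des <- design_prosthesis_boolean(prep, tooth, "onlay",
                                   cad_config(pitch = 0.15))
  geo <- attr(tooth, "tooth_geometry")
  floor_z <- geo$z_fossa - spec$pulpal_depth - spec$box_depth
  expect_gte(mesh_bounds(des$prosthesis)$lo[3], floor_z - 0.15 - 0.05)
})
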