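# Procedural anatomy: determinism, volume calibration, preparation
# semantics, scan simulation, oversampling and the design matrix.

test_that("tooth generation is deterministic and volume-calibrated", {
  m1 <- generate_intact_tooth(tooth_params(seed = 5))
  m2 <- generate_intact_tooth(tooth_params(seed = 5))
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  for (s in 1:6) {
    m <- fast_tooth(s, pitch = 0.3)
    expect_true(is_watertight(m))
    v <- enclosed_volume(m)
    expect_gte(v, 250)
    expect_lte(v, 450)
  }
})

test_that("inlay preparation removes material and conserves volume", {
  tooth <- fast_tooth(1)
  spec <- preparation_spec("inlay")
  prep <- apply_inlay_preparation(tooth, spec)
  expect_true(is_watertight(prep))
  expect_lt(enclosed_volume(prep), enclosed_volume(tooth))
  cavity <- preparation_cavity_solid(tooth, spec)
  expect_true(is_watertight(cavity))
  expect_lt(abs(enclosed_volume(prep) + enclosed_volume(cavity) -
                  enclosed_volume(tooth)), 0.01 * enclosed_volume(tooth))
})

test_that("zero-depth cavity is the identity preparation", {
  tooth <- fast_tooth(2)
  spec <- preparation_spec("inlay", pulpal_depth = 0, box_depth = 0)
  prep <- apply_inlay_preparation(tooth, spec)
  expect_identical(prep$vertices, tooth$vertices)
})

test_that("onlay adds a planar cusp reduction on top of the inlay cavity", {
  tooth <- fast_tooth(3)
  si <- preparation_spec("inlay")
  so <- preparation_spec("onlay", cusp_reduction = 1.5)
  prep_i <- apply_inlay_preparation(tooth, si)
  prep_o <- apply_onlay_preparation(tooth, so)
  expect_lt(enclosed_volume(prep_o), enclosed_volume(prep_i))
  pitch <- attr(tooth, "tooth_params")$mesh_pitch
  expect_equal(mesh_bounds(tooth)$hi[3] - mesh_bounds(prep_o)$hi[3], 1.5,
               tolerance = 2 * pitch)
  # zero reduction degenerates to the inlay preparation
  s0 <- preparation_spec("onlay", cusp_reduction = 0)
  prep_0 <- apply_onlay_preparation(tooth, s0)
  expect_equal(enclosed_volume(prep_0), enclosed_volume(prep_i),
               tolerance = 1e-9)
})

test_that("zero divergence gives constant cavity cross-sections", {
  tooth <- fast_tooth(4)
  geo <- attr(tooth, "tooth_geometry")
  spec <- preparation_spec("inlay", divergence_deg = 0)
  cav <- crownforge:::cavity_field_closure(spec, geo)
  # slice the unbounded cavity field over a fixed window at several heights
  xs <- seq(-geo$L / 2, geo$L / 2, by = 0.05)
  ys <- seq(-geo$W / 2, geo$W / 2, by = 0.05)
  z_floor <- geo$z_fossa - spec$pulpal_depth
  areas <- sapply(z_floor + c(0.6, 0.9, 1.2), function(z) {
    pts <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)), z)
    sum(cav(pts) > 0)
  })
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  # with divergence the proximal-box sections widen pulpo-occlusally
  spec_d <- preparation_spec("inlay", divergence_deg = 8)
  cav_d <- crownforge:::cavity_field_closure(spec_d, geo)
  areas_d <- sapply(z_floor - c(1.2, 0.3), function(z) {
    pts <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)), z)
    sum(cav_d(pts) > 0)
  })
  expect_gt(areas_d[2], areas_d[1])
})

test_that("preparations that breach the crown are rejected", {
  tooth <- fast_tooth(5)
  expect_error(apply_inlay_preparation(
    tooth, preparation_spec("inlay", pulpal_depth = 4, box_depth = 3)),
    class = "anatomy_error")
  expect_error(apply_inlay_preparation(
    tooth, preparation_spec("inlay", isthmus_width = 7)),
    class = "anatomy_error")
})

test_that("oversampling yields monotone variants with exact counts", {
  spec <- preparation_spec("inlay")
  specs <- oversample_preparation(spec, k = 5)
  expect_length(specs, 5)
  expect_equal(vapply(specs, `[[`, integer(1), "variant_index"), 0:4)
  depths <- vapply(specs, `[[`, numeric(1), "pulpal_depth")
  widths <- vapply(specs, `[[`, numeric(1), "isthmus_width")
  expect_true(all(diff(depths) > 0))
  expect_true(all(diff(widths) > 0))
  single <- oversample_preparation(spec, k = 1)
  expect_equal(single[[1]], spec)
  # 6 base specimens x 5 variants = 30
  expect_equal(6 * length(specs), 30)
  geo <- attr(fast_tooth(1), "tooth_geometry")
  expect_error(oversample_preparation(
    preparation_spec("inlay", isthmus_width = 5), k = 8, increment = 0.15,
    geo = geo), class = "anatomy_error")
})

test_that("scan simulation is deterministic and near-identity when noiseless", {
  prep <- apply_inlay_preparation(fast_tooth(1), preparation_spec("inlay"))
  quiet <- scanner_profile("desktop", jitter_sd = 0,
                           smoothing_iterations = 0,
                           target_triangles = 30000)
  s1 <- simulate_scan(prep, quiet, seed = 9)
  s2 <- simulate_scan(prep, quiet, seed = 9)
  expect_identical(s1$vertices, s2$vertices)
  expect_true(is_watertight(s1))
  b <- shared_bounds(list(prep, s1), 0.15)
  d <- dice_coefficient(voxelize(prep, 0.15, b), voxelize(s1, 0.15, b))
  expect_gte(d, 0.99)
  # profile invariant: intraoral carries the higher triangle budget
  pr <- default_scanner_profiles()
  expect_gt(pr$intraoral$target_triangles, pr$desktop$target_triangles)
})

test_that("study design matrix has the exact factorial structure", {
  study <- build_study_dataset(fast_study_config(), seed = 3)
  expect_length(study$preparations, 30)
  expect_equal(nrow(study$design), 120)
  expect_equal(sum(study$design$kind == "inlay"), 60)
  expect_equal(sum(study$design$kind == "onlay"), 60)
  expect_equal(sort(unique(study$design$workflow)), c(1L, 2L))
  expect_equal(sort(unique(study$design$operator)), c(1L, 2L))
  expect_equal(nrow(unique(study$design[, c("prep_id", "workflow",
                                            "operator")])), 120)
  for (m in study$preparations[c(1, 15, 30)]) expect_true(is_watertight(m))
  # determinism of the full manifest
  study2 <- build_study_dataset(fast_study_config(), seed = 3)
  expect_identical(study$design, study2$design)
  expect_identical(study$preparations[[7]]$vertices,
                   study2$preparations[[7]]$vertices)
})
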