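# Prosthesis synthesis.  Two CAD principles are implemented on voxel grids:
#
#  * Boolean subtraction: prosthesis = template AND NOT preparation,
#    computed by min/max CSG on narrow-band signed-distance samples (the
#    voxel-occupancy Boolean with sub-voxel surface recovery at
#    re-extraction), largest connected component, then smoothing.
#  * Surface reconstruction (inlay): the cavity is capped by the reference
#    occlusal surface (or bridged by morphological closing when no
#    reference exists) and the inlay is the capped solid minus the
#    preparation; "wrap" steps are emulated by a final morphological
#    closing of configurable radius before re-extraction.
#
# Exact B-rep Booleans are out of scope by design: voxel CSG is robust on
# scan-like noisy meshes and directly verifiable against enumeration
# oracles.

#' CAD configuration
#'
#' @param pitch voxel pitch of the CAD grid (mm); 0.1 mm resolves typical
#'   margin tolerances on crown-sized geometry.
#' @param wrap_radius morphological-closing radius (mm) emulating the final
#'   "wrap"/autofix cleanup.
#' @param closing_radius capping radius (mm) used by surface reconstruction
#'   when no intact reference is available; must exceed half the cavity
#'   opening width to bridge it.
#' @param smooth_iters Taubin smoothing iterations on the extracted
#'   prosthesis (emulates manual sculpt/smooth steps).
#' @param margin_offset signed offset (mm) added to the preparation field
#'   before subtraction; operator personas use fractions of a voxel to model
#'   margin placement variability.
#' @param workflow,operator labels carried into the design metadata.
#' @return A `cad_config` list.
#' @export
cad_config <- function(pitch = 0.1, wrap_radius = 0.25, closing_radius = 1.8,
                       smooth_iters = 2L, margin_offset = 0,
                       workflow = 1L, operator = 1L) {
  stopifnot(pitch > 0, wrap_radius >= 0, closing_radius > 0)
  structure(list(pitch = pitch, wrap_radius = wrap_radius,
                 closing_radius = closing_radius,
                 smooth_iters = as.integer(smooth_iters),
                 margin_offset = margin_offset,
                 workflow = as.integer(workflow),
                 operator = as.integer(operator)),
            class = "cad_config")
}

# morphological closing of a logical array with a Euclidean ball (voxels)
binary_closing <- function(occ, radius_vox) {
  if (radius_vox <= 0) return(occ)
  d <- dim(occ)
  dil_sq <- cpp_edt_sq(as.logical(occ), d)
  dil <- array(dil_sq <= radius_vox^2 + 1e-9, d)
  ero_sq <- cpp_edt_sq(as.logical(!dil), d)
  array(dil & ero_sq > radius_vox^2 + 1e-9, d)
}

# contour a CSG field after suppressing all but the largest component
extract_design_mesh <- function(field, origin, pitch, smooth_iters) {
  occ <- field > 0
  if (!any(occ))
    stop_crownforge("Boolean result is empty (preparation equals template?)",
                    "empty_design_error")
  comp <- largest_component(occ)
  field[occ & !comp] <- -1e-6
  m <- contour_field_grid(field, origin, pitch, iso = 0)
  if (smooth_iters > 0)
    m$vertices <- cpp_taubin_smooth(m$vertices, m$faces - 1L,
                                    as.integer(smooth_iters), 0.5, -0.53)
  m
}

#' Design a prosthesis by Boolean subtraction
#'
#' Prosthesis occupancy = template AND NOT preparation on a shared grid,
#' largest connected component, surface-extracted and smoothed.  This is the
#' workflow used for onlays (crown template superimposed on the preparation)
#' and for inlays in the subtraction-based workflow.
#'
#' @param prep watertight preparation mesh, co-registered with `template`.
#' @param template watertight template solid covering the region of interest
#'   (for onlays: the intact crown form).
#' @param kind `"inlay"` or `"onlay"` label for the design.
#' @param config a [cad_config()].
#' @return A `prosthesis_design` list: `prosthesis` (mesh), `kind`,
#'   `workflow`, `operator`, `fit` (a fit report, see [check_fit()]).
#' @export
design_prosthesis_boolean <- function(prep, template,
                                      kind = c("inlay", "onlay"),
                                      config = cad_config()) {
  kind <- match.arg(kind)
  assert_watertight(prep, "preparation")
  assert_watertight(template, "template")
  pitch <- config$pitch
  bounds <- shared_bounds(list(prep, template), pitch, pad = 2L)
  fr <- grid_frame(pitch, bounds)
  fp <- solid_field(prep, fr$origin, fr$shape, pitch) + config$margin_offset
  ft <- solid_field(template, fr$origin, fr$shape, pitch)
  m <- extract_design_mesh(pmin(ft, -fp), fr$origin, pitch,
                           config$smooth_iters)
  m$provenance <- sprintf("boolean %s design (wf %d, op %d)", kind,
                          config$workflow, config$operator)
  fit <- check_fit(m, prep, template, pitch)
  structure(list(prosthesis = m, kind = kind, workflow = config$workflow,
                 operator = config$operator, fit = fit),
            class = "prosthesis_design")
}

#' Design an inlay by surface reconstruction
#'
#' The cavity opening is capped by the intact reference's occlusal surface
#' (when available) or bridged by morphological closing of the preparation,
#' and the inlay is the capped solid minus the preparation.  A final
#' closing of radius `config$wrap_radius` emulates the wrap/autofix cleanup.
#'
#' @param prep watertight preparation mesh with a detectable occlusal cavity.
#' @param intact_reference optional watertight intact-tooth mesh.
#' @param config a [cad_config()].
#' @return A `prosthesis_design` (see [design_prosthesis_boolean()]).
#' @export
design_inlay_surface_reconstruction <- function(prep, intact_reference = NULL,
                                                config = cad_config()) {
  assert_watertight(prep, "preparation")
  pitch <- config$pitch
  meshes <- list(prep)
  if (!is.null(intact_reference)) {
    assert_watertight(intact_reference, "intact reference")
    meshes <- c(meshes, list(intact_reference))
  }
  bounds <- shared_bounds(meshes, pitch,
                          pad = 2L + ceiling(config$closing_radius / pitch))
  fr <- grid_frame(pitch, bounds)
  fp <- solid_field(prep, fr$origin, fr$shape, pitch) + config$margin_offset
  occ_prep <- fp > 0
  if (!is.null(intact_reference)) {
    capped <- solid_field(intact_reference, fr$origin, fr$shape, pitch) > 0
  } else {
    capped <- binary_closing(occ_prep, config$closing_radius / pitch)
  }
  inlay_occ <- capped & !occ_prep
  if (!any(inlay_occ))
    stop_crownforge("no cavity found on the preparation", "no_cavity_error")
  inlay_occ <- largest_component(inlay_occ)
  if (sum(inlay_occ) * pitch^3 < 1)
    stop_crownforge("no cavity found (candidate cap below 1 mm^3)",
                    "no_cavity_error")
  if (config$wrap_radius > 0)
    inlay_occ <- binary_closing(inlay_occ, config$wrap_radius / pitch)
  field <- array(ifelse(inlay_occ, pitch / 2, -pitch / 2), fr$shape)
  m <- extract_design_mesh(field, fr$origin, pitch,
                           max(config$smooth_iters, 1L))
  m$provenance <- sprintf("surface-reconstruction inlay (wf %d, op %d)",
                          config$workflow, config$operator)
  ref <- intact_reference
  fit <- if (!is.null(ref)) check_fit(m, prep, ref, pitch) else NULL
  structure(list(prosthesis = m, kind = "inlay", workflow = config$workflow,
                 operator = config$operator, fit = fit),
            class = "prosthesis_design")
}

#' Check the fit of a prosthesis on its preparation
#'
#' Computes on a shared grid: the penetration volume (prosthesis
#' intersecting remaining tooth material), the restored Dice coefficient
#' (prosthesis plus preparation against the intact reference), and the
#' maximum margin gap (largest distance from any cavity-wall point of the
#' preparation to the prosthesis surface; cavity-wall points are preparation
#' surface points lying inside the intact reference).
#'
#' @param prosthesis,prep,intact_reference watertight meshes in one frame.
#' @param pitch grid pitch (mm).
#' @param n_samples surface samples for the margin-gap estimate.
#' @return A one-row `data.frame`: `penetration_volume` (mm^3),
#'   `restored_dice`, `margin_max_gap` (mm).
#' @export
check_fit <- function(prosthesis, prep, intact_reference, pitch = 0.1,
                      n_samples = 4000) {
  if (n_faces(prosthesis) == 0)
    stop_crownforge("empty prosthesis", "empty_mesh_error")
  assert_watertight(prosthesis, "prosthesis")
  bounds <- shared_bounds(list(prosthesis, prep, intact_reference), pitch)
  gpro <- voxelize(prosthesis, pitch, bounds)
  gprep <- voxelize(prep, pitch, bounds)
  gref <- voxelize(intact_reference, pitch, bounds)
  penetration <- sum(gpro$occupancy & gprep$occupancy) * pitch^3
  restored <- voxel_grid(gpro$occupancy | gprep$occupancy, gpro$origin, pitch)
  rdice <- dice_coefficient(restored, gref)
  pts <- sample_surface_points(prep, n_samples, seed = 7L)
  inside <- cpp_points_in_mesh(pts, intact_reference$vertices,
                               intact_reference$faces - 1L)
  d_ref <- cpp_surface_distance(pts, intact_reference$vertices,
                                intact_reference$faces - 1L)
  wall <- inside & d_ref > 2 * pitch
  gap <- if (any(wall)) {
    max(cpp_surface_distance(pts[wall, , drop = FALSE],
                             prosthesis$vertices, prosthesis$faces - 1L))
  } else NA_real_
  data.frame(penetration_volume = penetration, restored_dice = rdice,
             margin_max_gap = gap)
}
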