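# Phase-3 data preparation: slicing solids into axial 2D segments, stacking
# them into fixed-shape 3D matrices, nearest-neighbour resampling, labelling
# and the stratified 2:1 train/validation split.

#' Slice a mesh into a stack of axial binary cross-sections
#'
#' `n_slices` evenly spaced z planes over the mesh bounds, each rasterized
#' at `in_plane_resolution` x `in_plane_resolution` via the same
#' center-inside test as [voxelize()] (anisotropic sampling of one parity
#' structure, so stack and voxelization agree up to the boundary band).
#' Slices are stacked gingival to occlusal (z ascending, 0-based).
#'
#' @param m a watertight `crown_mesh`.
#' @param n_slices number of z planes (>= 2).
#' @param in_plane_resolution pixels per slice edge.
#' @return A logical array of dim `(res, res, n_slices)`.
#' @export
slice_mesh_to_stack <- function(m, n_slices = 32L, in_plane_resolution = 32L) {
  if (n_faces(m) == 0)
    stop_crownforge("empty mesh", "empty_mesh_error")
  stopifnot(n_slices >= 2, in_plane_resolution >= 2)
  assert_watertight(m)
  b <- mesh_bounds(m)
  span <- b$hi - b$lo
  res <- as.integer(in_plane_resolution)
  xs <- b$lo[1] + (seq_len(res) - 0.5) * span[1] / res
  ys <- b$lo[2] + (seq_len(res) - 0.5) * span[2] / res
  zs <- b$lo[3] + (seq_len(n_slices) - 0.5) * span[3] / n_slices
  occ <- cpp_voxelize(m$vertices, m$faces - 1L, xs, ys, zs)
  array(occ, c(res, res, as.integer(n_slices)))
}

#' Nearest-neighbour resampling of a volume
#'
#' @param volume 3D array (logical or numeric).
#' @param target_shape integer length-3 target dimensions.
#' @return Array of dim `target_shape`; the occupied fraction is preserved
#'   to within ~10% for non-pathological volumes.
#' @export
resample_volume <- function(volume, target_shape) {
  stopifnot(length(dim(volume)) == 3)
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0))
    stop_crownforge("target shape must be positive", "shape_error")
  d <- dim(volume)
  if (identical(d, target_shape)) return(volume)
  ix <- pmin(d[1], floor((seq_len(target_shape[1]) - 0.5) * d[1] /
                           target_shape[1]) + 1)
  iy <- pmin(d[2], floor((seq_len(target_shape[2]) - 0.5) * d[2] /
                           target_shape[2]) + 1)
  iz <- pmin(d[3], floor((seq_len(target_shape[3]) - 0.5) * d[3] /
                           target_shape[3]) + 1)
  volume[ix, iy, iz, drop = FALSE]
}

#' Assemble the labelled volume dataset and its 2:1 split
#'
#' One `VolumeSample` per preparation (or prosthesis) in the study design:
#' the mesh is sliced to the configured input shape and labelled
#' inlay/onlay.  Samples are split 2:1 into training and validation,
#' stratified by class, with a seeded shuffle.
#'
#' @param study a `study_design` from [build_study_dataset()], or a named
#'   list of meshes plus a `labels` vector.
#' @param source `"prep"` to use preparation meshes, `"prosthesis"` to use
#'   designed prosthesis meshes (requires a `prostheses` list on `study`).
#' @param shape cubic input edge (default 32; the classifier requires a
#'   power-of-two-divisible shape).
#' @param seed shuffle seed.
#' @param labels optional explicit label vector (used with a plain mesh list).
#' @return List with `volumes` (list of logical arrays), `labels` (factor
#'   inlay/onlay), `ids`, and `split` (list `train`, `validation` of indices,
#'   `ratio = c(2, 1)`, `stratified = TRUE`).
#' @export
assemble_dataset <- function(study, source = c("prep", "prosthesis"),
                             shape = 32L, seed = 1L, labels = NULL) {
  source <- match.arg(source)
  if (inherits(study, "study_design")) {
    if (source == "prep") {
      meshes <- study$preparations
      labels <- study$prep_table$kind[match(names(meshes),
                                            study$prep_table$prep_id)]
    } else {
      if (is.null(study$prostheses))
        stop_crownforge(
          "study has no designed prostheses; run the design phase first",
          "missing_input_error")
      meshes <- study$prostheses
      labels <- study$prosthesis_kinds
    }
  } else {
    meshes <- study
    if (is.null(labels) || length(labels) != length(meshes))
      stop_crownforge("labels must accompany a plain mesh list",
                      "missing_input_error")
  }
  missing <- vapply(meshes, is.null, logical(1))
  if (any(missing))
    stop_crownforge(paste("missing meshes:",
                          paste(names(meshes)[missing], collapse = ", ")),
                    "missing_input_error")
  shape <- as.integer(shape)
  volumes <- lapply(meshes, slice_mesh_to_stack, n_slices = shape,
                    in_plane_resolution = shape)
  labels <- factor(labels, levels = c("inlay", "onlay"))
  split <- stratified_split(labels, ratio = c(2, 1), seed = seed)
  list(volumes = volumes, labels = labels,
       ids = names(meshes) %||% as.character(seq_along(meshes)),
       split = split)
}

#' Stratified 2:1 train/validation split
#'
#' @param labels factor of class labels.
#' @param ratio train:validation ratio (default `c(2, 1)`).
#' @param seed shuffle seed.
#' @return List `train`, `validation` (integer indices), `ratio`,
#'   `stratified = TRUE`.
#' @export
stratified_split <- function(labels, ratio = c(2, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  train <- integer(0)
  val <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      n_train <- round(length(idx) * ratio[1] / sum(ratio))
      train <- c(train, idx[seq_len(n_train)])
      val <- c(val, idx[-seq_len(n_train)])
    }
    train <- train[sample.int(length(train))]
    val <- val[sample.int(length(val))]
  })
  list(train = train, validation = val, ratio = ratio, stratified = TRUE)
}
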