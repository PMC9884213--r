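# Triangle meshes: construction, integrity, STL I/O, measurement.
#
# A `crown_mesh` is a list with `vertices` (n x 3 numeric, mm), `faces`
# (m x 3 integer, 1-based) and `provenance` (free text).  A mesh may carry an
# analytic implicit-field closure in attr "field" (positive inside), used by
# the anatomy simulator and the CAD module for sub-voxel accurate remeshing.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param provenance free-text tag (scanner profile, workflow, operator).
#' @return An object of class `crown_mesh`.
#' @export
mesh <- function(vertices, faces, provenance = "") {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop_crownforge("face indices out of range", "mesh_integrity_error")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop_crownforge("faces with repeated vertices", "mesh_integrity_error")
  }
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)),
            class = "crown_mesh")
}

#' @export
print.crown_mesh <- function(x, ...) {
  cat(sprintf("<crown_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

n_faces <- function(m) nrow(m$faces)

#' Axis-aligned bounding box of a mesh
#'
#' @param m a `crown_mesh`.
#' @return list with `lo` and `hi`, numeric length-3 vectors (mm).
#' @export
mesh_bounds <- function(m) {
  list(lo = apply(m$vertices, 2, min), hi = apply(m$vertices, 2, max))
}

#' Retrieve the analytic implicit field attached to a mesh, if any
#'
#' Meshes produced by the anatomy simulator carry a vectorized closure
#' `f(xyz)` returning positive values inside the solid; scan simulation and
#' CAD use it for sub-voxel accurate resampling.
#'
#' @param m a `crown_mesh`.
#' @return A function or `NULL`.
#' @export
mesh_field <- function(m) attr(m, "field", exact = TRUE)

set_mesh_field <- function(m, f) {
  attr(m, "field") <- f
  m
}

# ---- integrity -------------------------------------------------------------

#' Edge-based mesh integrity report
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces wind consistently (each directed edge
#' occurs exactly once).
#'
#' @param m a `crown_mesh`.
#' @return list with `watertight`, `open_edges` (count of undirected edges not
#'   shared by exactly 2 faces) and `inconsistent_edges` (count of repeated
#'   directed edges).
#' @export
mesh_integrity <- function(m) {
  f <- m$faces
  if (nrow(f) == 0)
    return(list(watertight = FALSE, open_edges = 0L, inconsistent_edges = 0L))
  nv <- nrow(m$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  dir_key <- (as.numeric(a) - 1) * nv + as.numeric(b)
  und_key <- (as.numeric(pmin(a, b)) - 1) * nv + as.numeric(pmax(a, b))
  inconsistent <- sum(duplicated(dir_key))
  tab <- table_counts(und_key)
  open_edges <- sum(tab != 2L)
  list(watertight = open_edges == 0L && inconsistent == 0L,
       open_edges = as.integer(open_edges),
       inconsistent_edges = as.integer(inconsistent))
}

# run-length count of equal values after sorting (fast small-footprint table)
table_counts <- function(keys) {
  s <- sort(keys)
  r <- rle(s)
  r$lengths
}

#' Test whether a mesh is watertight
#' @param m a `crown_mesh`.
#' @return logical flag.
#' @export
is_watertight <- function(m) mesh_integrity(m)$watertight

assert_watertight <- function(m, what = "mesh") {
  rep <- mesh_integrity(m)
  if (!rep$watertight)
    stop_crownforge(sprintf(
      "%s is not watertight: %d open edge(s), %d inconsistent edge(s)",
      what, rep$open_edges, rep$inconsistent_edges), "mesh_integrity_error")
  invisible(TRUE)
}

# ---- measurement -----------------------------------------------------------

#' Mesh surface area (MSA)
#'
#' Sum of triangle areas; degenerate triangles contribute zero.  Invariant
#' under rigid motion.
#'
#' @param m a `crown_mesh`.
#' @return Area in mm^2.
#' @export
surface_area <- function(m) {
  if (n_faces(m) == 0)
    stop_crownforge("empty mesh", "empty_mesh_error")
  v <- m$vertices
  f <- m$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume (VV) of a watertight mesh
#'
#' Signed tetrahedron (divergence theorem) sum.  If the global orientation is
#' inverted the absolute value is returned with a warning, since scanners
#' emit either winding.
#'
#' @param m a watertight, consistently wound `crown_mesh`.
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(m) {
  assert_watertight(m)
  v <- m$vertices
  f <- m$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
             a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
             a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  if (vol < 0) {
    warning("mesh has inverted global orientation; returning |volume|")
    vol <- -vol
  }
  vol
}

# ---- transforms ------------------------------------------------------------

#' Rigid and scaling transforms
#'
#' Utilities used throughout the test-suite invariants (rigid invariance of
#' area/volume, scaling laws) and by fixture construction.
#'
#' @param m a `crown_mesh`.
#' @param offset numeric length-3 translation (mm).
#' @return The transformed mesh (any attached implicit field is dropped).
#' @export
translate_mesh <- function(m, offset) {
  m$vertices <- sweep(m$vertices, 2, offset, "+")
  attr(m, "field") <- NULL
  m
}

#' @rdname translate_mesh
#' @param angle rotation angle in radians.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @export
rotate_mesh <- function(m, angle, axis = "z") {
  cs <- cos(angle); sn <- sin(angle)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3),
    y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3),
    z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3))
  m$vertices <- m$vertices %*% t(R)
  attr(m, "field") <- NULL
  m
}

#' @rdname translate_mesh
#' @param s scale factor; applied about `center`.
#' @param center point to scale about (default mesh centroid of bounds).
#' @export
scale_mesh <- function(m, s, center = NULL) {
  if (is.null(center)) {
    b <- mesh_bounds(m)
    center <- (b$lo + b$hi) / 2
  }
  m$vertices <- sweep(sweep(m$vertices, 2, center, "-") * s, 2, center, "+")
  attr(m, "field") <- NULL
  m
}

# area-weighted per-vertex normals (for jitter along normals)
vertex_normals <- function(m) {
  v <- m$vertices
  f <- m$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], f[, k])
      n[as.integer(rownames(acc)), c] <- n[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# ---- STL I/O ---------------------------------------------------------------

#' Read an STL file (ASCII or binary, auto-detected)
#'
#' Duplicate vertices are merged within a tolerance of 1e-6 mm, since STL
#' stores facets independently and downstream topology checks need shared
#' vertices.
#'
#' @param path file path.
#' @param merge_tol vertex merge tolerance in mm.
#' @return A `crown_mesh`.
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path))
    stop_crownforge(sprintf("no such file: %s", path), "stl_parse_error")
  size <- file.size(path)
  if (size == 0)
    stop_crownforge(sprintf("empty STL file: %s", path), "empty_mesh_error")
  raw <- readBin(path, "raw", n = size)
  binary <- FALSE
  if (size >= 84) {
    count <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    if (count >= 0 && size == 84 + 50 * as.double(count)) binary <- TRUE
  }
  if (!binary && size >= 84 && !is_ascii_stl(raw)) {
    # binary header but wrong length: report where parsing fails
    count <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    stop_crownforge(sprintf(
      "malformed binary STL %s: header declares %d facets (%d bytes) but file has %d bytes; truncated at byte %d",
      path, count, 84 + 50 * as.double(count), size, size), "stl_parse_error")
  }
  tris <- if (binary) parse_stl_binary(raw, path) else parse_stl_ascii(raw, path)
  if (nrow(tris) == 0)
    stop_crownforge(sprintf("STL file %s contains no facets", path),
                    "empty_mesh_error")
  nf <- nrow(tris) / 3
  merged <- cpp_merge_vertices(tris, matrix(seq_len(nrow(tris)) - 1L,
                                            ncol = 3, byrow = TRUE), merge_tol)
  m <- mesh(merged$vertices, merged$faces, provenance = basename(path))
  drop_degenerate_faces(m)
}

is_ascii_stl <- function(raw) {
  head_raw <- raw[seq_len(min(length(raw), 512))]
  if (any(head_raw == as.raw(0))) return(FALSE)  # binary payload
  head_txt <- tryCatch(rawToChar(head_raw), error = function(e) "")
  grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
}

parse_stl_binary <- function(raw, path) {
  if (length(raw) < 84)
    stop_crownforge(sprintf(
      "truncated binary STL %s: %d bytes, header needs 84 (failed at byte %d)",
      path, length(raw), length(raw)), "stl_parse_error")
  count <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  base <- 84 + 50 * (seq_len(count) - 1)
  idx <- rep(base, each = 36L) + rep(12L + 1:36, times = count)
  vals <- readBin(raw[idx], "numeric", size = 4, n = 9L * count,
                  endian = "little")
  vm <- matrix(vals, ncol = 3, byrow = TRUE)
  vm
}

parse_stl_ascii <- function(raw, path) {
  txt <- rawToChar(raw)
  lines <- strsplit(txt, "\r?\n")[[1]]
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0) return(matrix(numeric(0), ncol = 3))
  if (length(vlines) %% 3 != 0)
    stop_crownforge(sprintf(
      "malformed ASCII STL %s: %d vertex lines (not a multiple of 3)",
      path, length(vlines)), "stl_parse_error")
  nums <- suppressWarnings(vapply(strsplit(trimws(vlines), "\\s+"),
    function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(nums))
    stop_crownforge(sprintf("malformed ASCII STL %s: non-numeric vertex", path),
                    "stl_parse_error")
  t(nums)
}

drop_degenerate_faces <- function(m) {
  f <- m$faces
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  if (!all(keep)) m$faces <- f[keep, , drop = FALSE]
  m
}

#' Write a mesh to STL
#'
#' @param m a non-empty `crown_mesh`.
#' @param path output path.
#' @param dialect `"binary"` (80-byte header, uint32 facet count, 50-byte
#'   facets, little-endian) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(m, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (n_faces(m) == 0)
    stop_crownforge("cannot write an empty mesh", "empty_mesh_error")
  v <- m$vertices
  f <- m$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "crownforge binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- t(cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
    facets <- matrix(writeBin(as.numeric(block), raw(), size = 4,
                              endian = "little"), nrow = 48)
    out <- rbind(facets, matrix(as.raw(0), nrow = 2, ncol = nrow(f)))
    writeBin(as.vector(out), con)
  } else {
    vv <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3])
    txt <- character(7 * nrow(f) + 2)
    txt[1] <- "solid crownforge"
    for (i in seq_len(nrow(f))) {
      o <- 1 + (i - 1) * 7
      txt[o + 1] <- sprintf("  facet normal %.9g %.9g %.9g",
                            nrm[i, 1], nrm[i, 2], nrm[i, 3])
      txt[o + 2] <- "    outer loop"
      txt[o + 3] <- vv(v[f[i, 1], ])
      txt[o + 4] <- vv(v[f[i, 2], ])
      txt[o + 5] <- vv(v[f[i, 3], ])
      txt[o + 6] <- "    endloop"
      txt[o + 7] <- "  endfacet"
    }
    txt[length(txt)] <- "endsolid crownforge"
    writeLines(txt, path)
  }
  invisible(path)
}

# canonical axis-aligned cuboid fixture
#' Axis-aligned box mesh
#'
#' 12-triangle cuboid used widely in tests and as a CAD block template.
#'
#' @param lo,hi opposite corners (length-3, mm).
#' @return A watertight `crown_mesh`.
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  # corner index: x + 2y + 4z (1-based), outward-wound faces
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo
    c(5, 6, 8), c(5, 8, 7),   # z = hi
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(3, 7, 8), c(3, 8, 4),   # y = hi
    c(1, 5, 7), c(1, 7, 3),   # x = lo
    c(2, 4, 8), c(2, 8, 6))   # x = hi
  mesh(corners, f, provenance = "box")
}

#' Icosphere mesh
#'
#' Subdivided icosahedron; a smooth-sphere fixture for closed-form area and
#' volume checks.
#'
#' @param radius radius in mm.
#' @param subdivisions number of 4-to-1 subdivision rounds.
#' @param center center point.
#' @return A watertight `crown_mesh`.
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ekey <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- ekey[[k]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(v)
      ekey[[k]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  mesh(v, f, provenance = "icosphere")
}
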