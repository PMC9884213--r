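# Shared fixtures and independent oracles, built in code at test time.

# brute-force point-in-mesh oracle: pure-R ray parity along +z, vectorized
# over faces for one query point (independent of the C++ parity kernel)
oracle_inside <- function(pts, m) {
  v <- m$vertices
  f <- m$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  apply(pts, 1, function(p) {
    qx <- p[1] + 4.1e-7
    qy <- p[2] + 2.9e-7
    d1x <- b[, 1] - a[, 1]; d1y <- b[, 2] - a[, 2]
    d2x <- c3[, 1] - a[, 1]; d2y <- c3[, 2] - a[, 2]
    det <- d1x * d2y - d1y * d2x
    ok <- abs(det) > 1e-14
    px <- qx - a[, 1]; py <- qy - a[, 2]
    u <- (px * d2y - py * d2x) / det
    w <- (d1x * py - d1y * px) / det
    hit <- ok & u > 0 & w > 0 & (u + w) < 1
    zhit <- a[, 3] + u * (b[, 3] - a[, 3]) + w * (c3[, 3] - a[, 3])
    sum(hit & zhit > p[3], na.rm = TRUE) %% 2 == 1
  })
}

# brute-force point-to-triangle-soup distance oracle (pure R, per point)
oracle_surface_dist <- function(pts, m) {
  v <- m$vertices
  f <- m$faces
  tri_dist <- function(p, a, b, c3) {
    # dense barycentric scan: adequate oracle accuracy for coarse fixtures
    s <- seq(0, 1, length.out = 21)
    g <- expand.grid(u = s, w = s)
    g <- g[g$u + g$w <= 1, ]
    q <- outer(1 - g$u - g$w, a) + outer(g$u, b) + outer(g$w, c3)
    min(sqrt(rowSums(sweep(q, 2, p)^2)))
  }
  apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(i)
      tri_dist(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), numeric(1)))
  })
}

# small, fast tooth configuration for CAD/dataset tests
fast_tooth <- function(seed = 1, pitch = 0.22) {
  generate_intact_tooth(tooth_params(seed = seed, mesh_pitch = pitch))
}

# quick study config for structural (count) tests
fast_study_config <- function() study_config(prep_mesh_pitch = 0.3)

expect_meshes_equal <- function(a, b, tol = 1e-5) {
  expect_equal(nrow(a$vertices), nrow(b$vertices))
  expect_equal(nrow(a$faces), nrow(b$faces))
  # compare vertex sets irrespective of ordering
  key <- function(v) order(round(v[, 1] / tol), round(v[, 2] / tol),
                           round(v[, 3] / tol))
  expect_equal(a$vertices[key(a$vertices), ], b$vertices[key(b$vertices), ],
               tolerance = tol)
}
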