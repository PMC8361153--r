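# Fixtures are built in code; the synthetic face is cached per test run.

.fixture_env <- new.env(parent = emptyenv())

test_face <- function() {
  if (is.null(.fixture_env$face)) {
    .fixture_env$face <- generate_face(face_params(seed = 42))
  }
  .fixture_env$face
}

# regular grid patch in the xy-plane with an optional height function
grid_patch_mesh <- function(nx = 10, ny = 10, spacing = 1,
                            z_fun = function(x, y) rep(0, length(x))) {
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)
  v <- cbind(gx, gy, z_fun(gx, gy))
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  f <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
             cbind(v00, v00 + nx + 1L, v00 + nx))
  surface_mesh(v, f, mesh_id = "grid-patch")
}

# closed unit cube, 12 triangles, outward winding
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),      # z = 0 (normal -z)
    c(5, 6, 8), c(5, 8, 7),      # z = 1 (+z)
    c(1, 2, 6), c(1, 6, 5),      # y = 0 (-y)
    c(3, 7, 8), c(3, 8, 4),      # y = 1 (+y)
    c(1, 5, 7), c(1, 7, 3),      # x = 0 (-x)
    c(2, 4, 8), c(2, 8, 6)       # x = 1 (+x)
  )
  surface_mesh(v, f, mesh_id = "unit-cube")
}

# Independent closest-point oracle: exhaustive loop over all triangles,
# per-triangle distance by plane projection + edge-segment clamping (a
# different formulation than the package's region-based search).
oracle_point_triangle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sum(n^2)
  if (nn < 1e-300) {  # degenerate triangle: best over the three segments
    return(min(oracle_point_segment(p, a, b), oracle_point_segment(p, b, c),
               oracle_point_segment(p, a, c)))
  }
  q <- p - sum((p - a) * n) / nn * n  # projection onto the plane
  # barycentric coordinates of q
  v0 <- b - a
  v1 <- c - a
  v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  bv <- (d11 * d20 - d01 * d21) / den
  bw <- (d00 * d21 - d01 * d20) / den
  if (bv >= 0 && bw >= 0 && bv + bw <= 1) {
    return(sqrt(sum((p - q)^2)))
  }
  min(oracle_point_segment(p, a, b), oracle_point_segment(p, b, c),
      oracle_point_segment(p, a, c))
}

oracle_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - a - t * ab)^2))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

oracle_closest_dist <- function(p, mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  min(vapply(seq_len(nrow(f)), function(t) {
    oracle_point_triangle(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
  }, 0))
}

# rank-sum Kruskal-Wallis oracle (no-ties formula)
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ni <- lengths(groups)
  12 / (n * (n + 1)) * sum(rs^2 / ni) - 3 * (n + 1)
}

# transformed copies of a landmark set
transform_landmarks <- function(landmarks, tf) {
  out <- landmark_set(landmarks$name,
                      apply_transform(tf, as.matrix(landmarks[, c("x", "y", "z")])))
  attr(out, "vertex_index") <- attr(landmarks, "vertex_index")
  out
}
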