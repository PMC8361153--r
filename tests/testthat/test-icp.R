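test_that("closest-point search matches the exhaustive triangle oracle", {
  set.seed(3)
  bumpy <- grid_patch_mesh(11, 11, spacing = 2,
                           z_fun = function(x, y) sin(x / 3) * cos(y / 4))
  expect_gte(nrow(bumpy$faces), 200)
  q <- cbind(runif(50, -2, 22), runif(50, -2, 22), runif(50, -4, 4))
  cs <- closest_on_surface(q, bumpy)
  for (i in seq_len(50)) {
    expect_lt(abs(cs$dist[i] - oracle_closest_dist(q[i, ], bumpy)), 1e-10)
  }
})

test_that("correspondences find the foot point and reject overhangs", {
  patch <- grid_patch_mesh(8, 8, spacing = 2)  # flat, z = 0
  above <- matrix(c(7.3, 6.1, 1), 1)
  co <- correspondences(above, patch, exclude_overhangs = TRUE)
  expect_equal(co$closest[1, ], c(7.3, 6.1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(abs(co$normal[1, 3]), 1, tolerance = 1e-12)

  off_edge <- matrix(c(-5, 6, 0.5), 1)   # beyond the open border
  expect_error(correspondences(off_edge, patch, exclude_overhangs = TRUE),
               "no overlap")
  kept <- correspondences(off_edge, patch, exclude_overhangs = FALSE)
  expect_equal(nrow(kept$source), 1)

  both <- rbind(above, off_edge)
  co2 <- correspondences(both, patch, exclude_overhangs = TRUE)
  expect_equal(co2$kept, 1L)
})

test_that("the point-to-plane step solves exactly and handles degeneracy", {
  # zero residual: identity
  set.seed(4)
  s <- cbind(runif(20), runif(20), runif(20))
  n <- matrix(rnorm(60), 20)
  n <- n / sqrt(rowSums(n^2))
  co <- list(source = s, closest = s, normal = n)
  tf <- solve_point_to_plane_step(co)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)

  # known pure translation with true foot points: exact corrective recovery
  offset <- c(0, 0, 0.5)
  sphere_pts <- matrix(rnorm(300), ncol = 3)
  sphere_pts <- 40 * sphere_pts / sqrt(rowSums(sphere_pts^2))
  normals <- sphere_pts / 40
  co2 <- list(source = sweep(sphere_pts, 2, offset, "+"),
              closest = sphere_pts, normal = normals)
  # radial normals make rotation unobservable (s x n = 0): rank-deficient,
  # resolved by pseudoinverse with a warning; translation is still exact
  expect_warning(tf2 <- solve_point_to_plane_step(co2), "rank-deficient")
  expect_lt(max(abs(tf2$translation - c(0, 0, -0.5))), 1e-6)
  expect_lt(max(abs(tf2$rotation - diag(3))), 1e-6)

  # all normals parallel: lateral offset unobservable, solved along z only
  flat_s <- cbind(runif(20, 0, 10) + 3, runif(20, 0, 10), 0.7)
  flat_c <- cbind(flat_s[, 1] - 3, flat_s[, 2], 0)
  flat_n <- matrix(rep(c(0, 0, 1), each = 20), ncol = 3)
  expect_warning(
    tf3 <- solve_point_to_plane_step(
      list(source = flat_s, closest = flat_c, normal = flat_n)),
    "parallel"
  )
  expect_equal(tf3$translation[1:2], c(0, 0))
  expect_equal(tf3$translation[3], -0.7, tolerance = 1e-9)
  expect_true(attr(tf3, "degenerate"))
})

test_that("ICP is exact on noise-free problems", {
  face <- test_face()
  mask <- build_reference_area(face$mesh, face$landmarks, "area4")

  # source == target: identity
  res0 <- run_icp(face$mesh, mask, face$mesh)
  expect_lt(max(abs(res0$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(res0$transform$translation)), 1e-9)
  expect_lte(res0$runs_used, 3)

  # known rigid displacement: composed deviation below 1e-3 mm
  tf_true <- rigid_transform(rotation_about_axis(c(0, 1, 0), 5 * pi / 180),
                             c(2, -1, 3))
  moved <- apply_transform(tf_true, face$mesh)
  lm_moved <- transform_landmarks(face$landmarks, tf_true)
  mask_m <- build_reference_area(moved, lm_moved, "area4")
  res <- run_icp(moved, mask_m, face$mesh)
  comp <- compose_transforms(res$transform, tf_true)
  pts <- face$mesh$vertices[mask$indices, , drop = FALSE]
  dev <- apply_transform(comp, pts) - pts
  expect_lt(max(sqrt(rowSums(dev^2))), 1e-3)
  expect_lt(res$per_run_residual[res$runs_used], 1e-6)
  expect_true(res$converged)
})

test_that("per-run residuals never increase and are finite", {
  face <- test_face()
  s <- apply_growth(face$mesh, face$landmarks,
                    growth_params(lower_face_protrusion = 2,
                                  noise_sigma = 0.1,
                                  misalignment = rigid_transform(
                                    rotation_about_axis(c(1, 0, 1), 0.06),
                                    c(4, 2, -3)),
                                  seed = 8))
  res <- superimpose_subject(s, "area1")
  expect_true(all(is.finite(res$per_run_residual)))
  expect_true(all(diff(res$per_run_residual) <= 1e-9))
})

test_that("ICP is equivariant under a joint rigid motion", {
  face <- test_face()
  tf_true <- rigid_transform(rotation_about_axis(c(1, 2, 0), 0.05),
                             c(1, -2, 2))
  moved <- apply_transform(tf_true, face$mesh)
  lm_moved <- transform_landmarks(face$landmarks, tf_true)
  mask_m <- build_reference_area(moved, lm_moved, "area4")
  base <- run_icp(moved, mask_m, face$mesh)

  g <- rigid_transform(rotation_about_axis(c(0, 0, 1), 0.3), c(15, -8, 4))
  src_g <- apply_transform(g, moved)
  tgt_g <- apply_transform(g, face$mesh)
  mask_g <- region_mask(mask_m$indices, mask_m$label, mesh = src_g)
  res_g <- run_icp(src_g, mask_g, tgt_g)
  conj <- compose_transforms(compose_transforms(g, base$transform),
                             invert_transform(g))
  expect_lt(max(abs(res_g$transform$rotation - conj$rotation)), 1e-6)
  expect_lt(max(abs(res_g$transform$translation - conj$translation)), 1e-6)
})

test_that("registration error grows monotonically with noise level", {
  face <- test_face()
  mis <- rigid_transform(rotation_about_axis(c(1, 2, 3), 4 * pi / 180),
                         c(3, -2, 4))
  err <- vapply(c(0, 0.05, 0.1, 0.2), function(sg) {
    d <- vapply(1:3, function(sd) {
      s <- apply_growth(face$mesh, face$landmarks,
                        growth_params(misalignment = mis, noise_sigma = sg,
                                      seed = sd))
      r <- superimpose_subject(s, "area4")
      method_gold_disagreement(s, r$transform)$mean_displacement_mm
    }, 0)
    mean(d)
  }, 0)
  expect_lt(err[1], 1e-6)
  expect_true(all(diff(err) > 0))
})

test_that("transform files round-trip at full precision", {
  tf <- rigid_transform(rotation_about_axis(c(0.3, -1, 2), 0.7),
                        c(1.25, -3.5, 0.125))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(tf, path, comment = "settings: point-to-plane, 50 iter")
  back <- read_transform(path)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-15)
  expect_equal(back$translation, tf$translation, tolerance = 1e-15)
  # composition/inversion identities
  prod <- compose_transforms(tf, invert_transform(tf))
  expect_lt(max(abs(prod$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(prod$translation)), 1e-12)
})
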