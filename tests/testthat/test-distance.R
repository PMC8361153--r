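test_that("the signed distance map is exact, signed, and rigidly invariant", {
  face <- test_face()
  mesh <- face$mesh

  # self-comparison: identically zero
  self_map <- signed_distance_map(mesh, mesh)
  expect_equal(self_map$distances, rep(0, nrow(mesh$vertices)))

  # comparison offset +1 mm along vertex normals of a near-flat patch
  patch <- grid_patch_mesh(10, 10, spacing = 2,
                           z_fun = function(x, y) 0.02 * x)
  moved <- surface_mesh(patch$vertices + patch$vertex_normals, patch$faces)
  map1 <- signed_distance_map(patch, moved)
  interior <- setdiff(seq_len(nrow(patch$vertices)),
                      patch$boundary_vertices)
  expect_equal(map1$distances[interior],
               rep(1, length(interior)), tolerance = 1e-6)

  # |signed| equals the exhaustive unsigned oracle on a random pair
  set.seed(9)
  a <- grid_patch_mesh(7, 7, spacing = 2,
                       z_fun = function(x, y) sin(x / 2))
  b_v <- grid_patch_mesh(7, 7, spacing = 2,
                         z_fun = function(x, y) cos(y / 3))$vertices
  b <- surface_mesh(b_v + matrix(runif(nrow(b_v) * 3, -0.3, 0.3), ncol = 3),
                    a$faces)
  map2 <- signed_distance_map(a, b)
  for (i in seq(1, nrow(a$vertices), by = 5)) {
    expect_lt(abs(abs(map2$distances[i]) -
                    oracle_closest_dist(a$vertices[i, ], b)), 1e-10)
  }

  # joint rigid motion leaves the map unchanged
  g <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.4), c(5, 6, -7))
  map3 <- signed_distance_map(apply_transform(g, a), apply_transform(g, b))
  expect_equal(map3$distances, map2$distances, tolerance = 1e-9)
})

test_that("patch MAD is the mean absolute distance", {
  face <- test_face()
  map <- signed_distance_map(face$mesh, face$mesh)
  patch <- build_measurement_patch(face$mesh, face$landmarks, "meas_N")
  expect_equal(patch_mad(map, patch), 0)

  # contract on signs: {+1, -1, +1, -1} -> 1.0
  fake <- map
  fake$distances[patch$indices] <- rep(c(1, -1), 50)
  expect_equal(patch_mad(fake, patch), 1)

  # closed form: k/100 for k = 1..100 -> 0.505
  fake$distances[patch$indices] <- seq_along(patch$indices) / 100
  expect_equal(patch_mad(fake, patch), 0.505)

  # monotone under pointwise |d| increase
  bigger <- fake
  bigger$distances[patch$indices] <- fake$distances[patch$indices] * 2
  expect_gt(patch_mad(bigger, patch), patch_mad(fake, patch))
})

test_that("T1-vs-T1 placement differences behave like rigid offsets", {
  face <- test_face()
  s <- apply_growth(face$mesh, face$landmarks,
                    growth_params(noise_sigma = 0, seed = 2))
  gold <- t1_gold_placement(s)
  patches <- build_all_patches(gold, s$landmarks_t0)

  same <- t1_method_difference(gold, gold, patches)
  expect_equal(same$report$mad_mm, rep(0, 7))
  expect_equal(same$sum_mm, 0)

  # +0.5 mm pure z on an anterior-facing patch reads ~0.5
  shift <- rigid_transform(diag(3), c(0, 0, 0.5))
  shifted <- apply_transform(shift, gold)
  diff <- t1_method_difference(gold, shifted, patches)
  pog <- diff$report$mad_mm[diff$report$patch == "meas_Pog"]
  expect_equal(pog, 0.5, tolerance = 0.03)

  # vertex-count mismatch is an error
  half <- submesh(gold, seq(1, nrow(gold$vertices), by = 2))$mesh
  expect_error(t1_method_difference(gold, half, patches), "vertex counts")
})

test_that("reference congruence is near zero for noise-free recovery", {
  face <- test_face()
  s <- apply_growth(face$mesh, face$landmarks,
                    growth_params(lower_face_protrusion = 2, noise_sigma = 0,
                                  misalignment = rigid_transform(
                                    rotation_about_axis(c(0, 1, 0), 0.05),
                                    c(2, -1, 3)),
                                  seed = 3))
  res <- superimpose_subject(s, "area4")
  mask_t0 <- build_reference_area(s$t0_mesh, s$landmarks_t0, "area4")
  cong <- reference_congruence(s$t0_mesh,
                               apply_transform(res$transform, s$t1_mesh),
                               mask_t0)
  expect_lt(cong, 1e-3)

  # t1 == t0 exactly
  expect_equal(reference_congruence(s$t0_mesh, s$t0_mesh, mask_t0), 0)
})

test_that("reproducibility differences are signed and label-checked", {
  r1 <- structure(data.frame(patch = PATCH_LABELS,
                             mad_mm = c(1, 2, 3, 4, 5, 6, 7),
                             n_vertices = 100),
                  class = c("mad_report", "data.frame"))
  r2 <- r1
  expect_equal(reproducibility_difference(r1, r2)$difference_mm, rep(0, 7))
  r2$mad_mm <- r1$mad_mm + c(0.5, -0.5, 0, 0, 0, 0, 0)
  d <- reproducibility_difference(r1, r2)$difference_mm
  expect_equal(d[1:2], c(-0.5, 0.5))
  r3 <- r1
  r3$patch[1] <- "meas_X"
  expect_error(reproducibility_difference(r1, r3), "labels differ")
})

test_that("colour-coded maps clamp at the scale and centre at white", {
  face <- test_face()
  map <- signed_distance_map(face$mesh, face$mesh)
  path <- withr::local_tempfile(fileext = ".ply")
  export_colormap(map, face$mesh, path, scale = c(-2, 2))
  back <- read_mesh(path)
  cols <- attr(back, "vertex_colors")
  expect_true(all(cols == 255))  # zero distance -> white midpoint

  expect_equal(diverging_colors(2, c(-2, 2)), diverging_colors(4, c(-2, 2)))
  expect_equal(diverging_colors(-2, c(-2, 2)), diverging_colors(-9, c(-2, 2)))
  expect_false(isTRUE(all.equal(diverging_colors(2, c(-2, 2)),
                                diverging_colors(-2, c(-2, 2)))))
  expect_error(export_colormap(map, face$mesh, path, scale = c(2, 2)),
               "min < max")
})
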