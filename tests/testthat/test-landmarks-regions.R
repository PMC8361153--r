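test_that("landmark tables read, and errors are informative", {
  face <- test_face()
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(face$landmarks, path)
  lm <- read_landmarks(path)
  expect_s3_class(lm, "landmark_set")
  expect_equal(nrow(lm), 16)
  expect_equal(landmark_point(lm, "pronasale"),
               landmark_point(face$landmarks, "pronasale"), tolerance = 1e-9)

  # tab-separated, no header
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- as.data.frame(face$landmarks)
  writeLines(sprintf("%s\t%.6f\t%.6f\t%.6f", df$name, df$x, df$y, df$z), path2)
  expect_equal(nrow(read_landmarks(path2)), 16)

  # missing required name
  df_miss <- df[df$name != "soft_pogonion", ]
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z",
               sprintf("%s,%g,%g,%g", df_miss$name, df_miss$x, df_miss$y,
                       df_miss$z)), path3)
  expect_error(read_landmarks(path3), "soft_pogonion")

  # duplicated landmark
  df_dup <- rbind(df, df[df$name == "glabella", ])
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z",
               sprintf("%s,%g,%g,%g", df_dup$name, df_dup$x, df_dup$y,
                       df_dup$z)), path4)
  expect_error(read_landmarks(path4), "glabella")

  # malformed row names its line
  path5 <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(path)
  lines[5] <- "broken_row,1,2"
  writeLines(lines, path5)
  expect_error(read_landmarks(path5), "line 5")
})

test_that("cropping is idempotent and respects the posterior cut", {
  face <- test_face()
  cropped <- crop_to_face(face$mesh, face$landmarks)
  fr <- face_frame(face$landmarks)
  p <- to_face_frame(cropped$vertices, fr)
  expect_true(all(p[, 3] >= default_crop_bounds()["zmin"] - 1e-9))
  again <- crop_to_face(cropped, face$landmarks)
  expect_identical(again$vertices, cropped$vertices)
  expect_identical(again$faces, cropped$faces)
  # inconsistent landmarks (face frame far off the mesh) must be caught
  far <- landmark_set(face$landmarks$name,
                      landmark_coords(face$landmarks) + 500)
  expect_error(crop_to_face(face$mesh, far), "95%")
})

test_that("reference areas honour their defining geometry", {
  face <- test_face()
  fr <- face_frame(face$landmarks)
  p <- to_face_frame(face$mesh$vertices, fr)
  pn <- to_face_frame(matrix(landmark_point(face$landmarks, "pronasale"), 1),
                      fr)

  a4 <- build_reference_area(face$mesh, face$landmarks, "area4")
  a5 <- build_reference_area(face$mesh, face$landmarks, "area5")
  cfg <- default_region_config()
  in_fh <- p[, 1] >= cfg$area4_forehead$xlim[1] &
    p[, 1] <= cfg$area4_forehead$xlim[2] &
    p[, 2] >= cfg$area4_forehead$ylim[1] &
    p[, 2] <= cfg$area4_forehead$ylim[2]
  # area5 is exactly area4 minus the forehead rectangle
  expect_setequal(a5$indices, setdiff(a4$indices, which(in_fh)))
  expect_true(length(a5$indices) < length(a4$indices))
  # both area-4 components are populated
  expect_gt(length(intersect(a4$indices, which(in_fh))), 0)
  expect_gt(length(setdiff(a4$indices, which(in_fh))), 0)

  a1 <- build_reference_area(face$mesh, face$landmarks, "area1")
  d_pn <- sqrt(rowSums(sweep(p[a1$indices, , drop = FALSE], 2, pn[1, ])^2))
  expect_true(all(d_pn > cfg$nose_tip_radius))

  a3 <- build_reference_area(face$mesh, face$landmarks, "area3")
  expect_true(all(p[a3$indices, 2] >= cfg$area3_ymin))
  d_pn3 <- sqrt(rowSums(sweep(p[a3$indices, , drop = FALSE], 2, pn[1, ])^2))
  expect_true(all(d_pn3 > cfg$nose_tip_radius))

  # area2 stays clear of the mouth exclusion
  a2 <- build_reference_area(face$mesh, face$landmarks, "area2")
  mouth <- (to_face_frame(matrix(landmark_point(face$landmarks, "cheilion_R"), 1), fr) +
            to_face_frame(matrix(landmark_point(face$landmarks, "cheilion_L"), 1), fr)) / 2
  q <- sweep(p[a2$indices, , drop = FALSE], 2, mouth[1, ])
  inside_mouth <- (q[, 1] / cfg$mouth_semiaxes[1])^2 +
    (q[, 2] / cfg$mouth_semiaxes[2])^2 +
    (q[, 3] / cfg$mouth_semiaxes[3])^2 <= 1
  expect_false(any(inside_mouth))
})

test_that("measurement patches match an exhaustive nearest-100 sort", {
  face <- test_face()
  patch <- build_measurement_patch(face$mesh, face$landmarks, "meas_Pog")
  expect_length(patch$indices, 100)
  seed <- landmark_point(face$landmarks, "soft_pogonion")
  d <- sqrt(colSums((t(face$mesh$vertices) - seed)^2))
  expect_setequal(patch$indices, order(d, seq_along(d))[1:100])

  expect_error(
    build_measurement_patch(grid_patch_mesh(5, 5), face$landmarks, "meas_N"),
    "fewer than"
  )
})

test_that("patches are pairwise disjoint and rigidly invariant", {
  face <- test_face()
  patches <- build_all_patches(face$mesh, face$landmarks)
  idx <- unlist(lapply(patches, `[[`, "indices"))
  expect_false(any(duplicated(idx)))

  tf <- rigid_transform(rotation_about_axis(c(1, -1, 2), 0.4), c(10, -4, 7))
  mesh_t <- apply_transform(tf, face$mesh)
  lm_t <- transform_landmarks(face$landmarks, tf)
  for (lab in c("meas_N", "meas_GoL")) {
    expect_setequal(
      build_measurement_patch(mesh_t, lm_t, lab)$indices,
      patches[[lab]]$indices
    )
  }
  for (lab in c("area1", "area4")) {
    expect_setequal(
      build_reference_area(mesh_t, lm_t, lab)$indices,
      build_reference_area(face$mesh, face$landmarks, lab)$indices
    )
  }
})

test_that("mask transfer maps to the same geometry", {
  face <- test_face()
  patch <- build_measurement_patch(face$mesh, face$landmarks, "meas_N")

  # identical target: identical index set
  same <- transfer_mask(patch, face$mesh, face$mesh)
  expect_setequal(same$indices, patch$indices)

  # permuted target: maps to the same 3D points
  set.seed(1)
  perm <- sample(nrow(face$mesh$vertices))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  permuted <- surface_mesh(face$mesh$vertices[perm, ],
                           matrix(inv[face$mesh$faces], ncol = 3),
                           mesh_id = "permuted")
  moved <- transfer_mask(patch, face$mesh, permuted)
  expect_setequal(perm[moved$indices], patch$indices)

  # decimated target: mapped vertices stay near the source patch
  keep <- seq(1, nrow(face$mesh$vertices), by = 2)
  deci <- submesh(face$mesh, keep)$mesh
  mapped <- transfer_mask(patch, face$mesh, deci)
  src_pts <- face$mesh$vertices[patch$indices, , drop = FALSE]
  ctr <- colMeans(src_pts)
  r <- max(sqrt(rowSums(sweep(src_pts, 2, ctr)^2)))
  edge <- 2 * sqrt(mean(face$mesh$face_areas))
  d <- sqrt(rowSums(sweep(deci$vertices[mapped$indices, , drop = FALSE], 2, ctr)^2))
  expect_true(all(d <= r + edge))
  expect_equal(mapped$orig_size, 100)
})

test_that("mask files store 0-based indices and round-trip", {
  face <- test_face()
  patch <- build_measurement_patch(face$mesh, face$landmarks, "meas_A")
  path <- withr::local_tempfile(fileext = ".txt")
  write_mask(patch, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# meas_A")
  expect_equal(as.integer(lines[2:101]), patch$indices - 1L)
  back <- read_mask(path, face$mesh)
  expect_setequal(back$indices, patch$indices)
  expect_equal(back$label, "meas_A")
})
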