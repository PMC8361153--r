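#' Parameters of the synthetic face generator
#'
#' The synthetic face is a smooth parametric height field over an elliptical
#' facial domain in the anatomical face frame (origin at soft nasion, +y up,
#' +z anterior, mm): a broad dome plus Gaussian-bump features (brow ridge,
#' nasal ridge and tip, orbital depressions, cheeks, lips, chin). Landmarks
#' are placed analytically from the generating functions and snapped to mesh
#' vertices, so they lie exactly on the surface and displacement fields have
#' closed forms.
#'
#' @param nose_height nasal tip bump amplitude (mm).
#' @param brow_ridge brow ridge amplitude (mm).
#' @param chin_prominence chin bump amplitude (mm).
#' @param cheek_fullness cheek bump amplitude (mm).
#' @param resolution target vertex count (>= 2000 so 100-vertex patches stay
#'   local).
#' @param seed integer seed recorded with the face (generation itself is
#'   deterministic and analytic).
#' @return object of class `face_params`.
#' @export
face_params <- function(nose_height = 8, brow_ridge = 2.5,
                        chin_prominence = 5, cheek_fullness = 4,
                        resolution = 3000, seed = 1L) {
  if (resolution < 2000) stop("resolution must be at least 2000 vertices")
  structure(list(nose_height = nose_height, brow_ridge = brow_ridge,
                 chin_prominence = chin_prominence,
                 cheek_fullness = cheek_fullness,
                 resolution = as.integer(resolution), seed = as.integer(seed)),
            class = "face_params")
}

# analytic (x, y) positions of the 16 landmarks in the generator frame
synthetic_landmark_layout <- function() {
  rbind(
    glabella = c(0, 22), soft_nasion = c(0, 0), pronasale = c(0, -12),
    subnasale = c(0, -17), orbitale_R = c(22, -8), orbitale_L = c(-22, -8),
    exocanthion_R = c(35, 2), exocanthion_L = c(-35, 2),
    cheilion_R = c(21, -40), cheilion_L = c(-21, -40),
    soft_A_point = c(0, -28), soft_pogonion = c(0, -70),
    zygion_R = c(55, -12), zygion_L = c(-55, -12),
    gonion_R = c(45, -55), gonion_L = c(-45, -55)
  )
}

# facial domain: ellipse in (x, y), centre (0, -18), semi-axes (78, 72) mm
FACE_DOMAIN <- list(center = c(0, -18), semi = c(78, 72))

# height field (z as a function of x, y), before shifting nasion to z = 0
face_height_raw <- function(x, y, p) {
  g2 <- function(cx, cy, wx, wy) {
    exp(-(((x - cx) / wx)^2 + ((y - cy) / wy)^2))
  }
  u <- 1 - (x / 95)^2 - ((y + 18) / 150)^2
  z <- 50 * sqrt(pmax(u, 0))
  z <- z + p$brow_ridge * g2(0, 20, 30, 7)
  z <- z + 0.6 * p$nose_height * g2(0, -9, 6, 8)          # nasal ridge
  z <- z + p$nose_height * g2(0, -12, 7, 7)               # nasal tip
  z <- z - 3 * (g2(23, 2, 11, 7) + g2(-23, 2, 11, 7))     # orbits
  z <- z + p$cheek_fullness * (g2(40, -35, 18, 16) + g2(-40, -35, 18, 16))
  z <- z + 2 * g2(0, -40, 24, 6)                          # lips
  z <- z + p$chin_prominence * g2(0, -80, 20, 20)         # chin
  z
}

face_height <- function(x, y, p) {
  face_height_raw(x, y, p) - face_height_raw(0, 0, p)
}

#' Generate a synthetic facial surface with landmarks
#'
#' Builds an open, smooth, face-like triangulated height-field mesh (boundary
#' at the domain edge) with identifiable forehead, nasal bridge and tip,
#' orbits, cheeks, lips and chin, and places the 16 required soft-tissue
#' landmarks analytically (snapped to mesh vertices; the pronasale is snapped
#' to the locally highest vertex of the nose tip so it is a true local
#' anterior maximum). Deterministic given the parameters.
#'
#' @param params a [face_params()].
#' @return list with `mesh` (a [surface_mesh()]) and `landmarks` (a
#'   [landmark_set()] carrying a `vertex_index` attribute mapping each
#'   landmark to its mesh vertex).
#' @export
generate_face <- function(params = face_params()) {
  stopifnot(inherits(params, "face_params"))
  dom <- FACE_DOMAIN
  spacing <- sqrt(pi * dom$semi[1] * dom$semi[2] / params$resolution)
  xs <- seq(-dom$semi[1], dom$semi[1], by = spacing)
  ys <- seq(dom$center[2] - dom$semi[2], dom$center[2] + dom$semi[2],
            by = spacing)
  nx <- length(xs)
  ny <- length(ys)
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)
  inside <- (gx / dom$semi[1])^2 + ((gy - dom$center[2]) / dom$semi[2])^2 <= 1
  vid <- integer(nx * ny)
  vid[inside] <- seq_len(sum(inside))
  vx <- gx[inside]
  vy <- gy[inside]
  vz <- face_height(vx, vy, params)

  # two triangles per grid cell, kept only when all corners are in-domain;
  # winding chosen so normals point anteriorly (+z)
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  ok <- inside[v00] & inside[v10] & inside[v01] & inside[v11]
  faces <- rbind(
    cbind(vid[v00[ok]], vid[v10[ok]], vid[v11[ok]]),
    cbind(vid[v00[ok]], vid[v11[ok]], vid[v01[ok]])
  )
  mesh <- surface_mesh(cbind(vx, vy, vz), faces,
                       mesh_id = paste0("synthetic-face-", params$seed))

  layout <- synthetic_landmark_layout()
  idx <- integer(nrow(layout))
  for (k in seq_len(nrow(layout))) {
    d2 <- (vx - layout[k, 1])^2 + (vy - layout[k, 2])^2
    if (rownames(layout)[k] == "pronasale") {
      cand <- which(d2 <= 8^2)
      idx[k] <- cand[which.max(vz[cand])]
    } else {
      idx[k] <- which.min(d2)
    }
  }
  landmarks <- landmark_set(rownames(layout), mesh$vertices[idx, , drop = FALSE])
  attr(landmarks, "vertex_index") <- idx
  list(mesh = mesh, landmarks = landmarks)
}

#' Growth and acquisition parameters for a synthetic subject pair
#'
#' Describes the T0 -> T1 change imposed on a generated face: a global
#' anterior drift of the whole face, a lower-face protrusion whose smooth
#' weight rises below the subnasale (zero over the mid-face reference
#' region), nasal growth decaying radially from the pronasale, a signed
#' adiposity change weighted on the cheeks, scanner-like acquisition noise
#' along vertex normals (a smooth Gaussian random field with ~6 mm
#' correlation length and per-vertex marginal SD `noise_sigma`), and an
#' arbitrary rigid misalignment between the two acquisitions.
#'
#' @param global_forward_drift mm of whole-face anterior translation.
#' @param lower_face_protrusion mm of anterior displacement at full weight.
#' @param nasal_growth mm of anterior displacement at the pronasale.
#' @param adiposity_change mm (signed) along vertex normals at the cheeks.
#' @param noise_sigma per-vertex Gaussian noise SD along normals (mm).
#' @param misalignment a [rigid_transform()]: the pose difference between the
#'   two scans.
#' @param seed integer seed for the noise draws.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(global_forward_drift = 0,
                          lower_face_protrusion = 0,
                          nasal_growth = 0,
                          adiposity_change = 0,
                          noise_sigma = 0.05,
                          misalignment = rigid_transform(),
                          seed = 1L) {
  stopifnot(inherits(misalignment, "rigid_transform"), noise_sigma >= 0)
  structure(list(global_forward_drift = global_forward_drift,
                 lower_face_protrusion = lower_face_protrusion,
                 nasal_growth = nasal_growth,
                 adiposity_change = adiposity_change,
                 noise_sigma = noise_sigma,
                 misalignment = misalignment,
                 seed = as.integer(seed)),
            class = "growth_params")
}

# Scanner-like acquisition noise: a stationary Gaussian random field over the
# facial plane with squared-exponential covariance (correlation length
# `corr_length` mm) and per-vertex marginal SD `sigma`, realized by random
# Fourier features. Surface-scan noise is band-limited — smooth at the
# millimetre scale — so white per-vertex noise at mesh-edge spacing would
# emulate facet-scale roughness no real acquisition produces (and whose
# spurious closest-point attraction is a discretization artifact, not a
# property of the imaging chain).
acquisition_noise <- function(p_ff, sigma, corr_length = 6, n_features = 96) {
  if (sigma <= 0) return(numeric(nrow(p_ff)))
  omega <- matrix(stats::rnorm(2 * n_features, sd = 1 / corr_length),
                  ncol = 2)
  phase <- stats::runif(n_features, 0, 2 * pi)
  proj <- p_ff[, 1:2, drop = FALSE] %*% t(omega)
  as.numeric(sigma * sqrt(2 / n_features) *
               cos(sweep(proj, 2, phase, "+")) %*% rep(1, n_features))
}

# smoothstep: 0 below 0, 1 above 1, 3t^2 - 2t^3 in between
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  3 * t^2 - 2 * t^3
}

# spatial weight fields of the growth model, all in [0, 1].
# The lower-face weight starts 10 mm below the subnasale and saturates 25 mm
# further down, so it is ~0 over the mid-face (area 4 stand-in) and exactly 1
# over the pogonion patch.
growth_weights <- function(p_ff, lf) {
  onset <- lf["subnasale", 2] - 10
  w_lower <- smoothstep((onset - p_ff[, 2]) / 25)
  dpn <- sqrt(rowSums(sweep(p_ff, 2, lf["pronasale", ])^2))
  w_nasal <- exp(-(dpn / 12)^2)
  cheek <- function(sgn) {
    exp(-(((p_ff[, 1] - sgn * 42) / 14)^2 + ((p_ff[, 2] + 38) / 12)^2))
  }
  w_cheek <- pmin(cheek(1) + cheek(-1), 1)
  cbind(lower = w_lower, nasal = w_nasal, cheek = w_cheek)
}

#' Apply growth, noise and misalignment to a generated face
#'
#' Produces a ground-truth longitudinal subject: the T1 mesh is the T0
#' geometry plus the growth displacement field plus normal-direction noise,
#' relocated by the rigid misalignment; the T0 mesh receives independent
#' noise of the same sigma. Landmarks follow their vertices. The recorded
#' `true_transform` (the inverse misalignment, mapping T1 back into the T0
#' stable frame) is the synthetic analog of a gold-standard cranial-base
#' registration, and `true_displacement_field` is the imposed growth in that
#' frame.
#'
#' @param mesh,landmarks output of [generate_face()].
#' @param growth a [growth_params()].
#' @param face_parameters the [face_params()] used (recorded).
#' @param subject_id optional identifier.
#' @return object of class `synthetic_subject`: list with `t0_mesh`,
#'   `t1_mesh`, `landmarks_t0`, `landmarks_t1`, `true_transform`,
#'   `true_displacement_field`, `growth`, `face_parameters`, `subject_id`.
#' @export
apply_growth <- function(mesh, landmarks, growth,
                         face_parameters = NULL, subject_id = "subject") {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(growth, "growth_params"))
  fr <- face_frame(landmarks)
  p_ff <- to_face_frame(mesh$vertices, fr)
  lf <- to_face_frame(landmark_coords(landmarks), fr)
  rownames(lf) <- landmarks$name
  w <- growth_weights(p_ff, lf)

  z_world <- fr$axes[, "z"]  # anterior direction in world coordinates
  anterior_mm <- growth$global_forward_drift +
    growth$lower_face_protrusion * w[, "lower"] +
    growth$nasal_growth * w[, "nasal"]
  disp <- outer(anterior_mm, z_world) +
    growth$adiposity_change * w[, "cheek"] * mesh$vertex_normals

  set.seed(growth$seed)
  noise0 <- acquisition_noise(p_ff, growth$noise_sigma)
  noise1 <- acquisition_noise(p_ff, growth$noise_sigma)

  v_t0 <- mesh$vertices + noise0 * mesh$vertex_normals
  v_t1_stable <- mesh$vertices + disp + noise1 * mesh$vertex_normals
  v_t1 <- apply_transform(growth$misalignment, v_t1_stable)

  t0_mesh <- surface_mesh(v_t0, mesh$faces,
                          mesh_id = paste0(subject_id, "-t0"))
  t1_mesh <- surface_mesh(v_t1, mesh$faces,
                          mesh_id = paste0(subject_id, "-t1"))
  idx <- attr(landmarks, "vertex_index")
  if (is.null(idx)) {
    idx <- cpp_nearest_vertex(landmark_coords(landmarks), mesh$vertices)$index + 1L
  }
  lm_t0 <- landmark_set(landmarks$name, v_t0[idx, , drop = FALSE])
  attr(lm_t0, "vertex_index") <- idx
  lm_t1 <- landmark_set(landmarks$name, v_t1[idx, , drop = FALSE])
  attr(lm_t1, "vertex_index") <- idx

  structure(list(
    t0_mesh = t0_mesh, t1_mesh = t1_mesh,
    landmarks_t0 = lm_t0, landmarks_t1 = lm_t1,
    true_transform = invert_transform(growth$misalignment),
    true_displacement_field = disp,
    growth = growth, face_parameters = face_parameters,
    subject_id = subject_id
  ), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("synthetic_subject", x$subject_id, "-", nrow(x$t0_mesh$vertices),
      "vertices; protrusion", x$growth$lower_face_protrusion,
      "mm, drift", x$growth$global_forward_drift, "mm\n")
  invisible(x)
}

runif1 <- function(lim) stats::runif(1, lim[1], lim[2])

# draw a random rigid misalignment: rotation of 2-6 degrees about a random
# axis, translation uniform in [-5, 5] mm per component
draw_misalignment <- function() {
  axis <- stats::rnorm(3)
  angle <- stats::runif(1, 2, 6) * pi / 180
  rigid_transform(rotation_about_axis(axis, angle), stats::runif(3, -5, 5))
}

# per-scenario parameter ranges; see the methods vignette for rationale
draw_scenario_growth <- function(scenario, seed) {
  pro <- runif1(c(1, 3))
  switch(scenario,
    stable = growth_params(
      global_forward_drift = 0, lower_face_protrusion = pro,
      nasal_growth = 0, adiposity_change = runif1(c(-0.5, 0.5)),
      noise_sigma = 0.05, misalignment = draw_misalignment(), seed = seed
    ),
    retrusion = growth_params(
      global_forward_drift = runif1(c(0.5, 1.5)), lower_face_protrusion = pro,
      nasal_growth = 0, adiposity_change = runif1(c(-0.5, 0.5)),
      noise_sigma = 0.05, misalignment = draw_misalignment(), seed = seed
    ),
    rotation = growth_params(
      global_forward_drift = 0, lower_face_protrusion = pro,
      nasal_growth = runif1(c(1.5, 3)), adiposity_change = 0,
      noise_sigma = 0.05, misalignment = draw_misalignment(), seed = seed
    ),
    contaminated = growth_params(
      global_forward_drift = runif1(c(0, 1)), lower_face_protrusion = pro,
      nasal_growth = runif1(c(1, 2)), adiposity_change = runif1(c(-1, 1)),
      noise_sigma = 0.05, misalignment = draw_misalignment(), seed = seed
    ),
    stop("unknown scenario: ", scenario)
  )
}

#' Generate a cohort of synthetic longitudinal subjects
#'
#' Draws per-subject face shapes and growth parameters under a named
#' scenario, with independent per-subject seeds derived from the master seed,
#' and records every draw in a manifest.
#'
#' Scenarios: `"stable"` (growth confined to the lower face, mid-face
#' reference region undisturbed), `"retrusion"` (stable plus a global
#' anterior drift of the whole face), `"rotation"` (nasal growth without any
#' forehead change), `"contaminated"` (drift, nasal growth and adiposity all
#' active).
#'
#' @param n_subjects number of subjects.
#' @param scenario scenario name (see Details).
#' @param seed master seed.
#' @param resolution target mesh vertex count per face.
#' @return list with `subjects` (list of [apply_growth()] results) and
#'   `manifest` (data frame of drawn parameters).
#' @export
generate_cohort <- function(n_subjects,
                            scenario = c("stable", "retrusion", "rotation",
                                         "contaminated"),
                            seed = 1L, resolution = 3000) {
  scenario <- match.arg(scenario)
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(sub_seeds[i])
    fp <- face_params(
      nose_height = runif1(c(6, 10)), brow_ridge = runif1(c(1.5, 3.5)),
      chin_prominence = runif1(c(4, 6)), cheek_fullness = runif1(c(3, 5)),
      resolution = resolution, seed = sub_seeds[i]
    )
    gp <- draw_scenario_growth(scenario, seed = sub_seeds[i])
    face <- generate_face(fp)
    subjects[[i]] <- apply_growth(face$mesh, face$landmarks, gp,
                                  face_parameters = fp,
                                  subject_id = sprintf("S%02d", i))
    rows[[i]] <- data.frame(
      subject = sprintf("S%02d", i), scenario = scenario,
      seed = sub_seeds[i], nose_height = fp$nose_height,
      brow_ridge = fp$brow_ridge, chin_prominence = fp$chin_prominence,
      cheek_fullness = fp$cheek_fullness,
      global_forward_drift = gp$global_forward_drift,
      lower_face_protrusion = gp$lower_face_protrusion,
      nasal_growth = gp$nasal_growth,
      adiposity_change = gp$adiposity_change,
      noise_sigma = gp$noise_sigma,
      misalign_angle_deg = rotation_angle_deg(gp$misalignment$rotation),
      misalign_trans_mm = sqrt(sum(gp$misalignment$translation^2))
    )
  }
  list(subjects = subjects, manifest = do.call(rbind, rows))
}
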