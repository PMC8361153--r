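#' Labels of superimposition reference areas and measurement patches
#' @export
AREA_LABELS <- c("area1", "area2", "area3", "area4", "area5")

#' @rdname AREA_LABELS
#' @export
PATCH_LABELS <- c("meas_N", "meas_A", "meas_Pog", "meas_ZygR", "meas_ZygL",
                  "meas_GoR", "meas_GoL")

# seed landmark for each 100-vertex measurement patch
PATCH_SEEDS <- c(
  meas_N = "soft_nasion", meas_A = "soft_A_point", meas_Pog = "soft_pogonion",
  meas_ZygR = "zygion_R", meas_ZygL = "zygion_L",
  meas_GoR = "gonion_R", meas_GoL = "gonion_L"
)

#' Construct a region mask
#'
#' A set of vertex indices on a specific mesh: either a superimposition
#' reference area (`area1`..`area5`) or a 100-vertex measurement patch.
#'
#' @param indices integer vertex indices (1-based, unique).
#' @param label one of [AREA_LABELS] or [PATCH_LABELS].
#' @param mesh the [surface_mesh()] the indices refer to (for validation),
#'   or an integer vertex count.
#' @param orig_size original selection size before any duplicate collapse
#'   (recorded by [transfer_mask()]).
#' @return object of class `region_mask`.
#' @export
region_mask <- function(indices, label, mesh = NULL, orig_size = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) stop("empty region mask for label ", label)
  if (!label %in% c(AREA_LABELS, PATCH_LABELS)) {
    stop("unknown mask label: ", label)
  }
  mesh_id <- NA_character_
  if (!is.null(mesh)) {
    nv <- if (inherits(mesh, "surface_mesh")) nrow(mesh$vertices) else mesh
    if (min(indices) < 1L || max(indices) > nv) {
      stop("mask indices out of range for mesh with ", nv, " vertices")
    }
    if (inherits(mesh, "surface_mesh")) mesh_id <- mesh$mesh_id
  }
  structure(list(indices = indices, label = label, mesh_id = mesh_id,
                 orig_size = orig_size %||% length(indices)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask:", x$label, "-", length(x$indices), "vertices on mesh",
      x$mesh_id, "\n")
  invisible(x)
}

#' Default geometric constants of the reference-area definitions
#'
#' All primitives live in the anatomical face frame (mm, origin at soft
#' nasion; see [face_frame()]). The areas are defined anatomically in the
#' source methodology; these constants parameterize that anatomy so the
#' selection is fully reproducible and tunable in one place.
#'
#' @return nested list of constants; see the methods vignette for the
#'   rationale of each value.
#' @export
default_region_config <- function() {
  list(
    # exclusion primitives
    eye_medial_offset = 11,     # eye centre: exocanthion shifted medially (mm)
    eye_posterior_offset = 2,   # ... and posteriorly (mm)
    eye_semiaxes = c(22, 14, 15),
    mouth_semiaxes = c(30, 18, 15),
    nose_tip_radius = 10,
    # area 2: forehead/glabella box + nasal-base box around soft nasion
    area2_forehead = list(xmax = 30, ylim = c(5, 45), zmin = -5),
    area2_nasal = list(xmax = 12, ylim = c(-8, 8)),
    # area 3: upper half of the face (lower bound just above subnasale)
    area3_ymin = -15,
    # area 4: small forehead rectangle + mid-nose strip + infraorbital patches
    area4_forehead = list(xlim = c(-15, 15), ylim = c(18, 38)),
    area4_nose_strip = list(xlim = c(-10, 10), ylim = c(-25, 0)),
    area4_orbit_radius = 12,
    patch_size = 100
  )
}

in_ellipsoid <- function(p, center, semi) {
  ((p[, 1] - center[1]) / semi[1])^2 +
    ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2 <= 1
}

in_sphere <- function(p, center, radius) {
  (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
    (p[, 3] - center[3])^2 <= radius^2
}

# exclusion selector: eyes (two ellipsoids), mouth (ellipsoid), nose tip
# (sphere); p and landmark coordinates in the face frame
region_exclusions <- function(p, lf, cfg) {
  eye <- function(side) {
    ex <- lf[paste0("exocanthion_", side), ]
    ctr <- ex + c(-sign(ex[1]) * cfg$eye_medial_offset, 0,
                  -cfg$eye_posterior_offset)
    in_ellipsoid(p, ctr, cfg$eye_semiaxes)
  }
  mouth_ctr <- (lf["cheilion_R", ] + lf["cheilion_L", ]) / 2
  list(
    eyes = eye("R") | eye("L"),
    mouth = in_ellipsoid(p, mouth_ctr, cfg$mouth_semiaxes),
    nose_tip = in_sphere(p, lf["pronasale", ], cfg$nose_tip_radius)
  )
}

# face-frame coordinates of mesh vertices and landmarks
frame_coords <- function(mesh, landmarks) {
  fr <- face_frame(landmarks)
  lf <- to_face_frame(landmark_coords(landmarks), fr)
  rownames(lf) <- landmarks$name
  list(p = to_face_frame(mesh$vertices, fr), lf = lf)
}

area_selector <- function(p, lf, label, cfg) {
  excl <- region_exclusions(p, lf, cfg)
  switch(label,
    area1 = !(excl$eyes | excl$mouth | excl$nose_tip),
    area2 = {
      fh <- abs(p[, 1]) <= cfg$area2_forehead$xmax &
        p[, 2] >= cfg$area2_forehead$ylim[1] &
        p[, 2] <= cfg$area2_forehead$ylim[2] &
        p[, 3] >= cfg$area2_forehead$zmin
      nb <- abs(p[, 1] - lf["soft_nasion", 1]) <= cfg$area2_nasal$xmax &
        p[, 2] >= lf["soft_nasion", 2] + cfg$area2_nasal$ylim[1] &
        p[, 2] <= lf["soft_nasion", 2] + cfg$area2_nasal$ylim[2]
      fh | nb
    },
    area3 = p[, 2] >= cfg$area3_ymin & !(excl$eyes | excl$nose_tip),
    area4 = area4_components(p, lf, cfg, excl)$all,
    area5 = {
      cmp <- area4_components(p, lf, cfg, excl)
      cmp$all & !cmp$forehead
    },
    stop("unknown area label: ", label)
  )
}

area4_components <- function(p, lf, cfg, excl) {
  fh <- p[, 1] >= cfg$area4_forehead$xlim[1] &
    p[, 1] <= cfg$area4_forehead$xlim[2] &
    p[, 2] >= cfg$area4_forehead$ylim[1] &
    p[, 2] <= cfg$area4_forehead$ylim[2]
  strip <- p[, 1] >= cfg$area4_nose_strip$xlim[1] &
    p[, 1] <= cfg$area4_nose_strip$xlim[2] &
    p[, 2] >= cfg$area4_nose_strip$ylim[1] &
    p[, 2] <= cfg$area4_nose_strip$ylim[2] &
    !excl$nose_tip
  orb <- in_sphere(p, lf["orbitale_R", ], cfg$area4_orbit_radius) |
    in_sphere(p, lf["orbitale_L", ], cfg$area4_orbit_radius)
  list(forehead = fh, nasal = strip | orb, all = fh | strip | orb)
}

#' Build a superimposition reference area
#'
#' Selects the mesh vertices belonging to one of the five candidate
#' superimposition reference areas: (1) the whole facial surface excluding
#' eyes, mouth and nose tip; (2) forehead/glabella plus the nasal base;
#' (3) the upper half of the face excluding eyes and nose tip; (4) a small
#' forehead rectangle plus the mid-nose and infraorbital region; (5) the same
#' as area 4 without the forehead rectangle. All geometry is evaluated in the
#' anatomical face frame with the constants of [default_region_config()].
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()] on this mesh.
#' @param label one of [AREA_LABELS].
#' @param config region constants, see [default_region_config()].
#' @return a [region_mask()].
#' @export
build_reference_area <- function(mesh, landmarks, label,
                                 config = default_region_config()) {
  label <- match.arg(label, AREA_LABELS)
  fc <- frame_coords(mesh, landmarks)
  sel <- area_selector(fc$p, fc$lf, label, config)
  if (!any(sel)) stop("reference area selection is empty for ", label)
  region_mask(which(sel), label, mesh = mesh)
}

#' Build a 100-vertex measurement patch
#'
#' Exactly the `patch_size` (default 100) mesh vertices nearest (Euclidean)
#' to the patch's seed landmark (soft nasion, soft A-point, soft pogonion,
#' zygion R/L, gonion R/L); distance ties are broken by lower vertex index.
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()] on this mesh.
#' @param label one of [PATCH_LABELS].
#' @param config region constants (for `patch_size`).
#' @return a [region_mask()].
#' @export
build_measurement_patch <- function(mesh, landmarks, label,
                                    config = default_region_config()) {
  label <- match.arg(label, PATCH_LABELS)
  n <- config$patch_size
  if (nrow(mesh$vertices) < n) {
    stop("mesh has fewer than ", n, " vertices")
  }
  seed <- landmark_point(landmarks, PATCH_SEEDS[[label]])
  d <- sqrt(colSums((t(mesh$vertices) - seed)^2))
  idx <- order(d, seq_along(d))[seq_len(n)]
  region_mask(idx, label, mesh = mesh)
}

#' Build all seven measurement patches
#' @inheritParams build_measurement_patch
#' @return named list of [region_mask()] objects, one per [PATCH_LABELS].
#' @export
build_all_patches <- function(mesh, landmarks,
                              config = default_region_config()) {
  stats::setNames(
    lapply(PATCH_LABELS, build_measurement_patch, mesh = mesh,
           landmarks = landmarks, config = config),
    PATCH_LABELS
  )
}

#' Transfer a mask to another mesh by nearest vertices
#'
#' Each source-mask vertex maps to its nearest vertex on the target mesh
#' (both meshes must already be in a common frame, e.g. after
#' superimposition). Duplicate targets collapse; the original selection size
#' is recorded in `orig_size`.
#'
#' @param mask a [region_mask()] on `source_mesh`.
#' @param source_mesh,target_mesh [surface_mesh()] objects.
#' @return a [region_mask()] on `target_mesh` with the same label.
#' @export
transfer_mask <- function(mask, source_mesh, target_mesh) {
  pts <- source_mesh$vertices[mask$indices, , drop = FALSE]
  nn <- cpp_nearest_vertex(pts, target_mesh$vertices)
  region_mask(nn$index + 1L, mask$label, mesh = target_mesh,
              orig_size = length(mask$indices))
}

#' Write a region mask (one 0-based index per line)
#'
#' Header line: `# <label> <mesh_id> <count>`. Indices are stored 0-based.
#'
#' @param mask a [region_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  writeLines(c(
    paste("#", mask$label, mask$mesh_id, length(mask$indices)),
    as.character(mask$indices - 1L)
  ), path)
  invisible(path)
}

#' Read a region mask written by [write_mask()]
#' @param path file path.
#' @param mesh optional [surface_mesh()] for index validation.
#' @return a [region_mask()].
#' @export
read_mask <- function(path, mesh = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#", lines[1])) {
    stop("mask file must start with a '# label mesh_id count' header")
  }
  hdr <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "\\s+")[[1]]
  idx <- as.integer(lines[-1][nzchar(trimws(lines[-1]))])
  if (anyNA(idx)) stop("non-integer mask index in ", path)
  region_mask(idx + 1L, hdr[1], mesh = mesh)
}
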