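#' Required soft-tissue landmark names
#'
#' The 16 facial soft-tissue landmarks every [landmark_set()] must carry:
#' midline points (glabella, soft nasion, pronasale, subnasale, soft A-point,
#' soft pogonion) and bilateral points (orbitale, exocanthion, cheilion,
#' zygion, gonion).
#'
#' @export
REQUIRED_LANDMARKS <- c(
  "glabella", "soft_nasion", "pronasale", "subnasale",
  "orbitale_R", "orbitale_L", "exocanthion_R", "exocanthion_L",
  "cheilion_R", "cheilion_L", "soft_A_point", "soft_pogonion",
  "zygion_R", "zygion_L", "gonion_R", "gonion_L"
)

#' Construct a landmark set
#'
#' Named 3D points (mm) on a facial surface. All 16 [REQUIRED_LANDMARKS] must
#' be present exactly once; extra names are preserved.
#'
#' @param names character vector of landmark names.
#' @param coords n x 3 numeric matrix of coordinates (mm).
#' @return object of class `landmark_set`: data frame with columns
#'   `name`, `x`, `y`, `z`.
#' @export
landmark_set <- function(names, coords) {
  coords <- as.matrix(coords)
  stopifnot(length(names) == nrow(coords), ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("landmark coordinates must be finite")
  dup <- unique(names[duplicated(names)])
  if (length(dup)) {
    stop("duplicated landmark name(s): ", paste(dup, collapse = ", "))
  }
  missing <- setdiff(REQUIRED_LANDMARKS, names)
  if (length(missing)) {
    stop("missing required landmark(s): ", paste(missing, collapse = ", "))
  }
  structure(
    data.frame(name = as.character(names), x = coords[, 1], y = coords[, 2],
               z = coords[, 3], stringsAsFactors = FALSE),
    class = c("landmark_set", "data.frame")
  )
}

#' Get one landmark's coordinates
#' @param landmarks a [landmark_set()].
#' @param name landmark name.
#' @return numeric length-3 vector.
#' @export
landmark_point <- function(landmarks, name) {
  i <- match(name, landmarks$name)
  if (is.na(i)) stop("no landmark named ", name)
  as.numeric(landmarks[i, c("x", "y", "z")])
}

landmark_coords <- function(landmarks) {
  as.matrix(landmarks[, c("x", "y", "z")])
}

#' Read a landmark table
#'
#' Plain text, one row per landmark: `name, x, y, z` in mm, comma- or
#' tab-separated, optional header row.
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) stop("empty landmark file: ", path)
  sep <- if (grepl("\t", lines[keep[1]])) "\t" else ","
  rows <- strsplit(trimws(lines[keep]), sep)
  parse_row <- function(r) suppressWarnings(as.numeric(trimws(r[2:4])))
  first_vals <- parse_row(rows[[1]])
  if (anyNA(first_vals)) keep <- keep[-1]  # header row
  if (!length(keep)) stop("no landmark rows in ", path)
  rows <- strsplit(trimws(lines[keep]), sep)
  nm <- character(length(rows))
  co <- matrix(NA_real_, length(rows), 3)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < 4L) {
      stop("malformed landmark row at line ", keep[i], " of ", path)
    }
    vals <- parse_row(r)
    if (anyNA(vals)) {
      stop("malformed landmark row at line ", keep[i], " of ", path)
    }
    nm[i] <- trimws(r[1])
    co[i, ] <- vals
  }
  landmark_set(nm, co)
}

#' Write a landmark table (CSV: name,x,y,z)
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Check that landmarks lie on (near) a mesh surface
#' @param landmarks a [landmark_set()].
#' @param mesh a [surface_mesh()].
#' @param max_dist maximum allowed point-to-surface distance (mm).
#' @return `TRUE` invisibly, or an error naming offending landmarks.
#' @export
validate_landmarks_on_mesh <- function(landmarks, mesh, max_dist = 2) {
  d <- closest_on_surface(landmark_coords(landmarks), mesh)$dist
  off <- d > max_dist
  if (any(off)) {
    stop("landmark(s) further than ", max_dist, " mm from the surface: ",
         paste(landmarks$name[off], collapse = ", "))
  }
  invisible(TRUE)
}

#' Anatomical face-aligned coordinate frame
#'
#' A reproducible frame in which the reference-area and crop geometry is
#' expressed: origin at soft nasion; +x from the left toward the right
#' exocanthion (subject's right); +y from soft pogonion toward glabella (up),
#' orthogonalized against x; +z anterior, completing a right-handed frame.
#'
#' @param landmarks a [landmark_set()].
#' @return list with `origin` (length 3) and `axes` (3 x 3 matrix whose
#'   columns are the unit x, y, z axes in world coordinates).
#' @export
face_frame <- function(landmarks) {
  origin <- landmark_point(landmarks, "soft_nasion")
  ex_r <- landmark_point(landmarks, "exocanthion_R")
  ex_l <- landmark_point(landmarks, "exocanthion_L")
  gl <- landmark_point(landmarks, "glabella")
  pog <- landmark_point(landmarks, "soft_pogonion")
  xa <- ex_r - ex_l
  xa <- xa / sqrt(sum(xa^2))
  ya <- gl - pog
  ya <- ya - sum(ya * xa) * xa
  ya <- ya / sqrt(sum(ya^2))
  za <- c(xa[2] * ya[3] - xa[3] * ya[2],
          xa[3] * ya[1] - xa[1] * ya[3],
          xa[1] * ya[2] - xa[2] * ya[1])
  list(origin = origin, axes = cbind(x = xa, y = ya, z = za))
}

#' Express points in a face frame
#' @param points n x 3 matrix of world coordinates.
#' @param frame result of [face_frame()].
#' @return n x 3 matrix of face-frame coordinates.
#' @export
to_face_frame <- function(points, frame) {
  points <- as.matrix(points)
  sweep(points, 2, frame$origin) %*% frame$axes
}

#' Default face crop bounds (mm, face frame)
#'
#' Spans forehead to below the chin and ear to ear, with a posterior cut-off
#' 20 mm behind the nasion plane.
#' @return named numeric vector `xmin, xmax, ymin, ymax, zmin`.
#' @export
default_crop_bounds <- function() {
  c(xmin = -75, xmax = 75, ymin = -90, ymax = 45, zmin = -20)
}

#' Crop a mesh to the facial region of interest
#'
#' Retains vertices inside a face-frame-aligned bounding region (forehead to
#' below the chin, ear to ear, in front of a posterior cut plane); faces with
#' any removed vertex are removed. Idempotent: cropping an already-cropped
#' mesh leaves it unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()] on this mesh.
#' @param bounds crop box in the face frame, see [default_crop_bounds()].
#' @return the cropped [surface_mesh()].
#' @export
crop_to_face <- function(mesh, landmarks, bounds = default_crop_bounds()) {
  fr <- face_frame(landmarks)
  p <- to_face_frame(mesh$vertices, fr)
  keep <- p[, 1] >= bounds["xmin"] & p[, 1] <= bounds["xmax"] &
    p[, 2] >= bounds["ymin"] & p[, 2] <= bounds["ymax"] &
    p[, 3] >= bounds["zmin"]
  if (mean(!keep) > 0.95) {
    stop("crop removes more than 95% of vertices; ",
         "landmarks are inconsistent with the mesh")
  }
  if (all(keep)) return(mesh)
  submesh(mesh, keep)$mesh
}
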