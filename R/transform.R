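#' Rigid transform (rotation + translation)
#'
#' Maps points by `x -> R x + t`. The rotation is validated to be orthonormal
#' with determinant +1; no scale or shear is ever represented (serial scans of
#' one subject, calibrated millimetres).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) stop("rotation is not orthonormal (deviation ", err, ")")
  if (err > 1e-9) rotation <- nearest_rotation(rotation)
  if (det(rotation) < 0) stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4g deg, translation (%.4g, %.4g, %.4g) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Project a near-rotation matrix to the nearest rotation (polar/SVD)
#' @param m 3 x 3 matrix.
#' @return 3 x 3 rotation matrix.
#' @export
nearest_rotation <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$u[, 3] <- -s$u[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

#' Rotation about an axis (Rodrigues' formula)
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Apply a rigid transform
#' @param transform a [rigid_transform()].
#' @param x an n x 3 point matrix or a [surface_mesh()].
#' @return object of the same kind, transformed.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    v <- x$vertices %*% t(transform$rotation)
    v <- sweep(v, 2, transform$translation, "+")
    return(surface_mesh(v, x$faces, mesh_id = x$mesh_id))
  }
  x <- as.matrix(x)
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose rigid transforms: `compose_transforms(a, b)` applies `b` first
#' @param a,b [rigid_transform()] objects.
#' @return the composite `a %*% b` as a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Convert a rigid transform to a 4 x 4 homogeneous matrix
#' @param transform a [rigid_transform()].
#' @return 4 x 4 numeric matrix.
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Build a rigid transform from a 4 x 4 homogeneous matrix
#' @param m 4 x 4 matrix.
#' @return a [rigid_transform()].
#' @export
transform_from_matrix <- function(m) {
  stopifnot(all(dim(m) == c(4, 4)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write a rigid transform as a plain-text 4 x 4 homogeneous matrix
#'
#' Row-major, full precision, with `#`-prefixed comment header lines carrying
#' a settings fingerprint.
#'
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @param comment optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path, comment = NULL) {
  m <- transform_matrix(transform)
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  hdr <- if (length(comment)) paste("#", comment) else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a rigid transform written by [write_transform()]
#' @param path file path.
#' @return a [rigid_transform()].
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4L) stop("transform file must have 4 matrix rows")
  m <- t(vapply(strsplit(trimws(lines), "\\s+"),
                function(t) as.numeric(t), numeric(4)))
  transform_from_matrix(m)
}
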