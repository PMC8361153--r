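#' Signed point-to-surface distance map
#'
#' For each vertex of the reference mesh, the exact closest distance to the
#' comparison surface, signed positive where the comparison surface lies
#' along the reference vertex's outward normal (so anterior movement of the
#' face reads positive on an anterior-facing reference), negative on the
#' opposite side, and zero for vertices exactly on the comparison surface.
#'
#' @param reference [surface_mesh()] at whose vertices distances are
#'   evaluated.
#' @param comparison [surface_mesh()] measured against.
#' @return object of class `distance_map`: list with `distances` (signed,
#'   mm, one per reference vertex), `reference_mesh_id`, `closest` (n x 3).
#' @export
signed_distance_map <- function(reference, comparison) {
  stopifnot(inherits(reference, "surface_mesh"),
            inherits(comparison, "surface_mesh"))
  if (nrow(comparison$faces) < 1L) stop("comparison mesh is empty")
  cs <- closest_on_surface(reference$vertices, comparison)
  dirdot <- rowSums((cs$point - reference$vertices) *
                      reference$vertex_normals)
  sgn <- sign(dirdot)
  sgn[cs$dist == 0] <- 0
  # exactly lateral contacts (dot == 0 at non-zero distance) count positive
  sgn[sgn == 0 & cs$dist > 0] <- 1
  structure(list(distances = sgn * cs$dist,
                 reference_mesh_id = reference$mesh_id,
                 closest = cs$point),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("distance_map on", x$reference_mesh_id, "-", length(x$distances),
      "vertices, median |d| =", signif(stats::median(abs(x$distances)), 4),
      "mm\n")
  invisible(x)
}

#' Mean absolute distance over a patch
#'
#' Arithmetic mean of the unsigned distances at the patch vertices (MAD, mm).
#'
#' @param map a [signed_distance_map()].
#' @param patch a [region_mask()] on the map's reference mesh.
#' @return MAD in mm.
#' @export
patch_mad <- function(map, patch) {
  stopifnot(inherits(map, "distance_map"), inherits(patch, "region_mask"))
  if (!length(patch$indices)) stop("empty patch")
  if (max(patch$indices) > length(map$distances)) {
    stop("patch indices exceed the distance map length")
  }
  mean(abs(map$distances[patch$indices]))
}

#' Per-patch MAD report
#'
#' @param map a [signed_distance_map()].
#' @param patches named list of [region_mask()] patches.
#' @return data frame of class `mad_report` with columns `patch`, `mad_mm`,
#'   `n_vertices`, plus an `overall` attribute: the pooled MAD across all
#'   patch vertices.
#' @export
mad_report <- function(map, patches) {
  rows <- data.frame(
    patch = vapply(patches, `[[`, "", "label"),
    mad_mm = vapply(patches, function(p) patch_mad(map, p), 0),
    n_vertices = vapply(patches, function(p) length(p$indices), 0L),
    row.names = NULL
  )
  pooled <- mean(abs(map$distances[unlist(lapply(patches, `[[`, "indices"))]))
  structure(rows, overall_mad = pooled, class = c("mad_report", "data.frame"))
}

#' Difference between two placements of the same T1 model
#'
#' Compares a method's T1 placement against the gold-standard T1 placement of
#' the same surface model (both are the same mesh under two transforms; a
#' differing vertex count is an error). The gold-standard placement is the
#' reference of the signed map, and MADs are reported per measurement patch
#' together with their sum (the per-subject "sum of differences").
#'
#' @param t1_gold [surface_mesh()]: T1 under the gold-standard transform.
#' @param t1_method [surface_mesh()]: the same T1 under the method transform.
#' @param patches named list of seven [region_mask()] patches on `t1_gold`.
#' @return list with `map` (the [signed_distance_map()]), `report`
#'   (a [mad_report()]) and `sum_mm` (sum of the seven patch MADs).
#' @export
t1_method_difference <- function(t1_gold, t1_method, patches) {
  if (nrow(t1_gold$vertices) != nrow(t1_method$vertices)) {
    stop("t1_gold and t1_method must be the same model (vertex counts differ)")
  }
  map <- signed_distance_map(t1_gold, t1_method)
  rep_ <- mad_report(map, patches)
  list(map = map, report = rep_, sum_mm = sum(rep_$mad_mm))
}

#' Surface congruence on the reference area
#'
#' MAD between the superimposed serial surfaces restricted to the reference
#' area itself — how well the two surfaces actually meet on the region the
#' registration used.
#'
#' @param t0 fixed [surface_mesh()].
#' @param t1_superimposed [surface_mesh()] already relocated into the T0
#'   frame.
#' @param reference_mask [region_mask()] on `t0`.
#' @return MAD in mm.
#' @export
reference_congruence <- function(t0, t1_superimposed, reference_mask) {
  patch_mad(signed_distance_map(t0, t1_superimposed), reference_mask)
}

#' Reproducibility differences between two repeated runs
#'
#' Signed per-patch differences (run 1 minus run 2) of MAD values obtained
#' from two independent superimposition runs of the same subject and method.
#'
#' @param mad_run1,mad_run2 [mad_report()] data frames with matching patches.
#' @return data frame with columns `patch`, `mad_run1`, `mad_run2`,
#'   `difference_mm` (signed).
#' @export
reproducibility_difference <- function(mad_run1, mad_run2) {
  if (!setequal(mad_run1$patch, mad_run2$patch)) {
    stop("patch labels differ between the two runs")
  }
  m2 <- mad_run2[match(mad_run1$patch, mad_run2$patch), ]
  data.frame(patch = mad_run1$patch,
             mad_run1 = mad_run1$mad_mm,
             mad_run2 = m2$mad_mm,
             difference_mm = mad_run1$mad_mm - m2$mad_mm)
}

#' Export a colour-coded distance map as a coloured PLY
#'
#' Vertices are coloured by a symmetric diverging ramp (blue = negative /
#' posterior, white = zero, red = positive / anterior), clamped at the given
#' scale; the scale is recorded in the PLY header comment.
#'
#' @param map a [signed_distance_map()].
#' @param mesh the reference [surface_mesh()] the map was evaluated on.
#' @param path output PLY path.
#' @param scale length-2 numeric `(min, max)` in mm, `min < max`.
#' @return `path`, invisibly.
#' @export
export_colormap <- function(map, mesh, path, scale = c(-2, 2)) {
  if (scale[1] >= scale[2]) stop("scale must satisfy min < max")
  if (length(map$distances) != nrow(mesh$vertices)) {
    stop("map length does not match the mesh vertex count")
  }
  colors <- diverging_colors(map$distances, scale)
  write_mesh(mesh, path, format = "ply", vertex_colors = colors,
             header_comment = sprintf("distance scale %g %g mm",
                                      scale[1], scale[2]))
  invisible(path)
}

#' Map signed distances to diverging RGB colours
#' @param d signed distances (mm).
#' @param scale length-2 clamp range (mm).
#' @return n x 3 matrix of RGB values in 0-255.
#' @export
diverging_colors <- function(d, scale = c(-2, 2)) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  u <- (pmin(pmax(d, scale[1]), scale[2]) - scale[1]) / (scale[2] - scale[1])
  ramp(u)
}
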