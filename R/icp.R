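#' ICP settings
#'
#' Settings of the region-constrained rigid superimposition: point-to-plane
#' metric, exact nearest-neighbour (point-to-surface) correspondence search,
#' every masked vertex participating (100% overlap, 100% sampling), overhang
#' exclusion (correspondences whose closest target point lies on a boundary
#' edge/vertex are discarded), up to 50 inner iterations, and an outer
#' repeat-until-minimum loop that re-runs the whole inner loop from the
#' current pose until the mean absolute point-to-point distance stops
#' improving.
#'
#' @param overlap_fraction,sampling_fraction in (0, 1]; 1 means every masked
#'   source vertex participates and no correspondence trimming is applied.
#' @param metric only `"point_to_plane"` is provided.
#' @param exact_nn must remain `TRUE`: exact closest-point search.
#' @param exclude_overhangs discard boundary-contact correspondences.
#' @param max_iterations inner-loop cap.
#' @param inner_tolerance inner stop: RMS point-to-plane improvement (mm).
#' @param outer_max_runs outer-loop cap.
#' @param outer_tolerance outer stop: mean absolute point-to-point distance
#'   improvement (mm).
#' @return object of class `icp_settings`.
#' @export
icp_settings <- function(overlap_fraction = 1, sampling_fraction = 1,
                         metric = "point_to_plane", exact_nn = TRUE,
                         exclude_overhangs = TRUE, max_iterations = 50,
                         inner_tolerance = 1e-6, outer_max_runs = 10,
                         outer_tolerance = 1e-4) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1,
            sampling_fraction > 0, sampling_fraction <= 1,
            max_iterations >= 1, outer_max_runs >= 1,
            identical(metric, "point_to_plane"), isTRUE(exact_nn))
  structure(list(overlap_fraction = overlap_fraction,
                 sampling_fraction = sampling_fraction, metric = metric,
                 exact_nn = exact_nn, exclude_overhangs = exclude_overhangs,
                 max_iterations = as.integer(max_iterations),
                 inner_tolerance = inner_tolerance,
                 outer_max_runs = as.integer(outer_max_runs),
                 outer_tolerance = outer_tolerance),
            class = "icp_settings")
}

#' Exact point-to-surface correspondences
#'
#' For each source point, the exactly closest point on the target surface
#' (vertex, edge or face interior) with the normal of the supporting face
#' (averaged at edges/vertices). With `exclude_overhangs`, correspondences
#' whose closest point lies on a boundary edge or boundary vertex of the
#' target are discarded.
#'
#' @param source_points n x 3 matrix (mm).
#' @param target a [surface_mesh()] with at least one face.
#' @param exclude_overhangs logical.
#' @return list with `source`, `closest`, `normal` (all n_kept x 3), `dist`
#'   and `kept` (indices into the input rows).
#' @export
correspondences <- function(source_points, target, exclude_overhangs = TRUE) {
  if (nrow(target$faces) < 1L) stop("target mesh has no faces")
  cs <- closest_on_surface(source_points, target)
  keep <- if (exclude_overhangs) !cs$on_boundary else
    rep(TRUE, nrow(source_points))
  if (!any(keep)) stop("no overlap under overhang exclusion")
  list(source = as.matrix(source_points)[keep, , drop = FALSE],
       closest = cs$point[keep, , drop = FALSE],
       normal = cs$normal[keep, , drop = FALSE],
       dist = cs$dist[keep],
       kept = which(keep))
}

#' One point-to-plane least-squares step
#'
#' Finds the rigid transform minimizing the sum of squared point-to-plane
#' residuals `n . (R s + t - c)` under small-angle linearization, solved in
#' closed form from the 6 x 6 normal equations; the rotation is recovered as
#' the exact exponential (Rodrigues) of the solved rotation vector, so the
#' result is exactly rigid. If the normal system is rank-deficient because
#' all normals are (nearly) parallel — a plane, which allows in-plane sliding
#' — the translation is solved only along the common normal, the in-plane
#' components are set to zero and a warning is issued; other rank
#' deficiencies are resolved by a pseudoinverse with a warning.
#'
#' @param corr a correspondence set from [correspondences()] (fields
#'   `source`, `closest`, `normal`).
#' @return a [rigid_transform()] with attribute `degenerate` flagging the
#'   rank-deficient case.
#' @export
solve_point_to_plane_step <- function(corr) {
  s <- corr$source
  c_ <- corr$closest
  n <- corr$normal
  if (nrow(s) < 6L) stop("need at least 6 correspondences")
  cx <- cbind(s[, 2] * n[, 3] - s[, 3] * n[, 2],
              s[, 3] * n[, 1] - s[, 1] * n[, 3],
              s[, 1] * n[, 2] - s[, 2] * n[, 1])
  A <- cbind(cx, n)
  b <- rowSums(n * (s - c_))
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  ev <- eigen(AtA, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- FALSE
  if (min(ev) < 1e-10 * max(ev)) {
    degenerate <- TRUE
    nsv <- svd(n, nu = 0)$d
    if (nsv[2] < 1e-6 * nsv[1]) {
      # all normals parallel: only the offset along the common normal is
      # observable; translate along it, leave rotation and in-plane motion at
      # identity/zero
      warning("degenerate point-to-plane system: all normals parallel; ",
              "solving translation along the normal only")
      nbar <- colMeans(n)
      nbar <- nbar / sqrt(sum(nbar^2))
      t_ <- -mean(b) * nbar
      out <- rigid_transform(diag(3), t_)
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    warning("rank-deficient point-to-plane system; using pseudoinverse")
    sv <- svd(AtA)
    inv <- sv$v %*% diag(ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)) %*%
      t(sv$u)
    x <- as.numeric(inv %*% (-Atb))
  } else {
    x <- as.numeric(solve(AtA, -Atb))
  }
  omega <- x[1:3]
  ang <- sqrt(sum(omega^2))
  rot <- if (ang < 1e-300) diag(3) else rotation_about_axis(omega, ang)
  out <- rigid_transform(rot, x[4:6])
  attr(out, "degenerate") <- degenerate
  out
}

ptp_rms <- function(corr) {
  sqrt(mean(rowSums(corr$normal * (corr$source - corr$closest))^2))
}

#' Region-constrained point-to-plane ICP superimposition
#'
#' Rigidly superimposes the (moving) source mesh onto the (fixed) target
#' mesh, restricting correspondences to the masked source vertices. The inner
#' loop alternates exact correspondence search and closed-form point-to-plane
#' steps, stopping when the RMS point-to-plane residual stops improving (or
#' would increase: then the previous pose is kept). The whole inner loop is
#' then re-run from the current pose (the outer "repeat until a minimum
#' distance" loop) until the mean absolute point-to-point distance improves
#' by less than `outer_tolerance`.
#'
#' @param source the moving [surface_mesh()] (T1).
#' @param source_mask a [region_mask()] on `source` (the reference area).
#' @param target the fixed [surface_mesh()] (T0).
#' @param settings an [icp_settings()].
#' @return object of class `superimposition_result`: list with `transform`
#'   (a [rigid_transform()] mapping source into the target frame),
#'   `runs_used`, `per_run_residual` (mean absolute point-to-plane residual
#'   per outer run, non-increasing), `per_run_distance` (mean absolute
#'   point-to-point distance per outer run), `converged`, and
#'   `inner_iterations` per run.
#' @export
run_icp <- function(source, source_mask, target, settings = icp_settings()) {
  stopifnot(inherits(source, "surface_mesh"),
            inherits(target, "surface_mesh"),
            inherits(source_mask, "region_mask"))
  base_pts <- source$vertices[source_mask$indices, , drop = FALSE]
  transform <- rigid_transform()
  per_run_residual <- numeric(0)
  per_run_distance <- numeric(0)
  inner_iterations <- integer(0)
  prev_dist <- Inf
  converged <- FALSE

  for (run in seq_len(settings$outer_max_runs)) {
    inner <- run_icp_inner(base_pts, target, transform, settings)
    transform <- inner$transform
    if (!is.finite(inner$rms)) {
      stop("non-finite ICP residual at outer run ", run,
           " (inner iteration ", inner$iterations, ")")
    }
    mad_now <- inner$mean_abs_ptp
    res_now <- inner$mean_abs_plane
    if (length(per_run_residual) &&
        res_now > per_run_residual[length(per_run_residual)] + 1e-9) {
      # an outer re-run must not worsen the fit: keep the previous pose
      transform <- inner$start_transform
      converged <- TRUE
      break
    }
    per_run_residual <- c(per_run_residual, res_now)
    per_run_distance <- c(per_run_distance, mad_now)
    inner_iterations <- c(inner_iterations, inner$iterations)
    if (prev_dist - mad_now < settings$outer_tolerance) {
      converged <- TRUE
      prev_dist <- mad_now
      break
    }
    prev_dist <- mad_now
  }
  structure(list(transform = transform, runs_used = length(per_run_residual),
                 per_run_residual = per_run_residual,
                 per_run_distance = per_run_distance,
                 inner_iterations = inner_iterations,
                 converged = converged, settings = settings),
            class = "superimposition_result")
}

run_icp_inner <- function(base_pts, target, transform, settings) {
  start_transform <- transform
  pts <- apply_transform(transform, base_pts)
  corr <- correspondences(pts, target, settings$exclude_overhangs)
  rms <- ptp_rms(corr)
  it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    step <- suppressWarnings(solve_point_to_plane_step(corr))
    cand_transform <- compose_transforms(step, transform)
    cand_pts <- apply_transform(cand_transform, base_pts)
    cand_corr <- correspondences(cand_pts, target, settings$exclude_overhangs)
    cand_rms <- ptp_rms(cand_corr)
    if (!is.finite(cand_rms)) break
    if (cand_rms > rms + 1e-9) break  # keep previous pose
    improved <- rms - cand_rms
    transform <- cand_transform
    pts <- cand_pts
    corr <- cand_corr
    rms <- cand_rms
    if (improved < settings$inner_tolerance) break
  }
  list(transform = transform, start_transform = start_transform,
       rms = rms, iterations = it,
       mean_abs_plane = mean(abs(rowSums(corr$normal *
                                           (corr$source - corr$closest)))),
       mean_abs_ptp = mean(corr$dist))
}

#' @export
print.superimposition_result <- function(x, ...) {
  cat("superimposition_result:", x$runs_used, "outer run(s),",
      sum(x$inner_iterations), "inner iterations, final residual",
      signif(x$per_run_residual[length(x$per_run_residual)], 4), "mm,",
      if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}
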