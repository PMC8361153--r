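#' Superimpose one subject's T1 onto T0 on a chosen reference area
#'
#' Builds the reference-area mask on the (moving) T1 mesh from the T1
#' landmarks and runs the point-to-plane ICP against the fixed T0 mesh.
#'
#' @param subject a `synthetic_subject` (or any list with `t0_mesh`,
#'   `t1_mesh`, `landmarks_t1`).
#' @param area one of [AREA_LABELS].
#' @param settings an [icp_settings()].
#' @param config region constants.
#' @return the [run_icp()] result, with the mask attached as attribute
#'   `mask`.
#' @export
superimpose_subject <- function(subject, area, settings = icp_settings(),
                                config = default_region_config()) {
  mask <- build_reference_area(subject$t1_mesh, subject$landmarks_t1, area,
                               config)
  res <- run_icp(subject$t1_mesh, mask, subject$t0_mesh, settings)
  attr(res, "mask") <- mask
  res
}

#' T1 mesh under the gold-standard (ground-truth) transform
#' @param subject a `synthetic_subject`.
#' @return a [surface_mesh()].
#' @export
t1_gold_placement <- function(subject) {
  apply_transform(subject$true_transform, subject$t1_mesh)
}

#' Disagreement between a method's placement and the gold placement
#'
#' Measures how far a recovered superimposition transform places the T1
#' surface from its gold-standard placement: the mean vertex displacement
#' between the two placements (mm), the mean signed anterior (z) component of
#' that displacement in the T0 face frame (negative = the method places T1
#' posterior to gold), and the rotation angle of the residual transform.
#'
#' @param subject a `synthetic_subject`.
#' @param method_transform a [rigid_transform()] mapping T1 into the T0
#'   frame.
#' @return list with `mean_displacement_mm`, `max_displacement_mm`,
#'   `mean_signed_z_mm`, `rotation_error_deg`.
#' @export
method_gold_disagreement <- function(subject, method_transform) {
  xg <- apply_transform(subject$true_transform, subject$t1_mesh$vertices)
  xm <- apply_transform(method_transform, subject$t1_mesh$vertices)
  d <- xm - xg
  mag <- sqrt(rowSums(d^2))
  z_ax <- face_frame(subject$landmarks_t0)$axes[, "z"]
  resid <- compose_transforms(method_transform,
                              invert_transform(subject$true_transform))
  list(mean_displacement_mm = mean(mag),
       max_displacement_mm = max(mag),
       mean_signed_z_mm = mean(d %*% z_ax),
       rotation_error_deg = rotation_angle_deg(resid$rotation))
}

#' Superimpose and score every subject of a cohort on chosen areas
#'
#' Runs the region-constrained ICP per subject and reference area and scores
#' each result against the subject's ground-truth transform.
#'
#' @param cohort result of [generate_cohort()] (or a bare list of subjects).
#' @param areas character vector of [AREA_LABELS].
#' @param settings an [icp_settings()].
#' @param config region constants.
#' @return data frame with one row per (subject, area): disagreement
#'   metrics, outer runs used and final residual; the fitted transforms are
#'   attached as attribute `transforms` (a named nested list).
#' @export
evaluate_cohort <- function(cohort, areas = c("area1", "area4"),
                            settings = icp_settings(),
                            config = default_region_config()) {
  subjects <- cohort$subjects %||% cohort
  rows <- list()
  transforms <- list()
  for (s in subjects) {
    transforms[[s$subject_id]] <- list()
    for (a in areas) {
      res <- superimpose_subject(s, a, settings, config)
      dis <- method_gold_disagreement(s, res$transform)
      transforms[[s$subject_id]][[a]] <- res$transform
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$subject_id, area = a,
        mean_displacement_mm = dis$mean_displacement_mm,
        max_displacement_mm = dis$max_displacement_mm,
        mean_signed_z_mm = dis$mean_signed_z_mm,
        rotation_error_deg = dis$rotation_error_deg,
        runs_used = res$runs_used,
        final_residual_mm = res$per_run_residual[res$runs_used]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "transforms") <- transforms
  out
}

#' T0-T1 change per measurement patch for one superimposed subject
#'
#' Relocates T1 by the given transform, evaluates the signed distance map at
#' the T0 vertices (T0 is the fixed reference) and summarizes MAD at the
#' seven measurement patches built from the T0 landmarks.
#'
#' @param subject a `synthetic_subject`.
#' @param transform [rigid_transform()] mapping T1 into the T0 frame.
#' @param patches optional pre-built patches on T0 (built if `NULL`).
#' @return list with `map`, `report` (a [mad_report()]).
#' @export
subject_change_report <- function(subject, transform, patches = NULL) {
  if (is.null(patches)) {
    patches <- build_all_patches(subject$t0_mesh, subject$landmarks_t0)
  }
  t1s <- apply_transform(transform, subject$t1_mesh)
  map <- signed_distance_map(subject$t0_mesh, t1s)
  list(map = map, report = mad_report(map, patches))
}

#' One independent reproducibility run
#'
#' Emulates an operator re-doing the workflow: landmarks are re-picked with
#' Gaussian jitter (default 0.5 mm SD), the reference area and measurement
#' patches are re-selected from the jittered landmarks, the ICP is re-run,
#' and the per-patch T0-T1 MADs are recomputed.
#'
#' @param subject a `synthetic_subject`.
#' @param area reference-area label.
#' @param landmark_jitter_sd SD of the landmark re-picking jitter (mm).
#' @param seed seed for the jitter.
#' @param settings an [icp_settings()].
#' @return the [mad_report()] of the run.
#' @export
reproducibility_run <- function(subject, area, landmark_jitter_sd = 0.5,
                                seed = 1L, settings = icp_settings()) {
  set.seed(seed)
  jitter_lm <- function(lms) {
    co <- landmark_coords(lms) +
      matrix(stats::rnorm(3 * nrow(lms), sd = landmark_jitter_sd),
             ncol = 3)
    landmark_set(lms$name, co)
  }
  lm1 <- jitter_lm(subject$landmarks_t1)
  lm0 <- jitter_lm(subject$landmarks_t0)
  mask <- build_reference_area(subject$t1_mesh, lm1, area)
  res <- run_icp(subject$t1_mesh, mask, subject$t0_mesh, settings)
  patches <- build_all_patches(subject$t0_mesh, lm0)
  subject_change_report(subject, res$transform, patches)$report
}

#' Run the full simulated study
#'
#' Orchestrates the whole workflow on a simulated cohort: generate subjects,
#' superimpose each on the requested reference areas, write per-subject
#' transforms and per-patch MAD tables, score methods against the
#' ground-truth gold standard (per-patch sums of T1 placement differences),
#' run the nonparametric statistics over methods, and (optionally) a second
#' reproducibility pass. All outputs are deterministic given the
#' configuration and seed.
#'
#' @param config list with elements `n_subjects`, `scenario`, `areas`,
#'   `seed`, `outdir`, and optionally `resolution`, `settings` (an
#'   [icp_settings()]), `colormap_scale`, `reproducibility` (logical),
#'   `export_maps` (logical, default `FALSE`).
#' @return list with `scores` (cohort evaluation data frame), `mad_long`
#'   (per subject/method/patch MAD rows), `t1_differences` (per-patch sums of
#'   method-vs-gold MADs per area), `stats` (omnibus + post hoc rows),
#'   `reproducibility` (or `NULL`), and `manifest`.
#' @export
run_study <- function(config) {
  required <- c("n_subjects", "scenario", "areas", "seed", "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("run_study config lacks: ", paste(missing, collapse = ", "))
  }
  settings <- config$settings %||% icp_settings()
  resolution <- config$resolution %||% 3000
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "study_log.txt")
  log_lines <- c(
    sprintf("scenario=%s n=%d seed=%d resolution=%d areas=%s",
            config$scenario, config$n_subjects, config$seed, resolution,
            paste(config$areas, collapse = ",")),
    sprintf("icp: max_iterations=%d inner_tol=%g outer_max_runs=%d outer_tol=%g",
            settings$max_iterations, settings$inner_tolerance,
            settings$outer_max_runs, settings$outer_tolerance)
  )

  cohort <- generate_cohort(config$n_subjects, config$scenario,
                            seed = config$seed, resolution = resolution)
  utils::write.csv(cohort$manifest,
                   file.path(config$outdir, "cohort_manifest.csv"),
                   row.names = FALSE)

  scores <- evaluate_cohort(cohort, config$areas, settings)
  transforms <- attr(scores, "transforms")
  utils::write.csv(scores, file.path(config$outdir, "method_scores.csv"),
                   row.names = FALSE)

  mad_rows <- list()
  t1diff_rows <- list()
  for (s in cohort$subjects) {
    patches_t0 <- build_all_patches(s$t0_mesh, s$landmarks_t0)
    gold <- t1_gold_placement(s)
    patches_gold <- lapply(patches_t0, transfer_mask,
                           source_mesh = s$t0_mesh, target_mesh = gold)
    gold_rep <- subject_change_report(s, s$true_transform, patches_t0)$report
    mad_rows[[length(mad_rows) + 1L]] <- data.frame(
      subject = s$subject_id, method = "gold", patch = gold_rep$patch,
      mad_mm = gold_rep$mad_mm, n_vertices = gold_rep$n_vertices
    )
    for (a in config$areas) {
      tf <- transforms[[s$subject_id]][[a]]
      write_transform(
        tf, file.path(config$outdir,
                      sprintf("%s_%s_transform.txt", s$subject_id, a)),
        comment = sprintf("subject=%s area=%s point-to-plane ICP",
                          s$subject_id, a)
      )
      rep_a <- subject_change_report(s, tf, patches_t0)$report
      mad_rows[[length(mad_rows) + 1L]] <- data.frame(
        subject = s$subject_id, method = a, patch = rep_a$patch,
        mad_mm = rep_a$mad_mm, n_vertices = rep_a$n_vertices
      )
      t1m <- apply_transform(tf, s$t1_mesh)
      td <- t1_method_difference(gold, t1m, patches_gold)
      t1diff_rows[[length(t1diff_rows) + 1L]] <- data.frame(
        subject = s$subject_id, method = a, patch = td$report$patch,
        mad_mm = td$report$mad_mm
      )
      if (isTRUE(config$export_maps)) {
        map <- subject_change_report(s, tf, patches_t0)$map
        export_colormap(map, s$t0_mesh,
                        file.path(config$outdir,
                                  sprintf("%s_%s_map.ply", s$subject_id, a)),
                        scale = config$colormap_scale %||% c(-2, 2))
      }
    }
  }
  mad_long <- do.call(rbind, mad_rows)
  utils::write.csv(mad_long, file.path(config$outdir, "mad_report.csv"),
                   row.names = FALSE)

  t1diff <- do.call(rbind, t1diff_rows)
  sums <- stats::aggregate(mad_mm ~ method + patch, t1diff, sum)
  wide <- stats::reshape(sums, idvar = "method", timevar = "patch",
                         direction = "wide")
  names(wide) <- sub("^mad_mm\\.", "", names(wide))
  wide$Total <- rowSums(wide[, -1, drop = FALSE])
  utils::write.csv(wide, file.path(config$outdir, "t1_difference_sums.csv"),
                  row.names = FALSE)

  # nonparametric comparison of methods, overall and per patch
  mad_groups <- split(mad_long$mad_mm, mad_long$method)
  kw <- kruskal_wallis(mad_groups)
  dunn <- if (kw$p_value < 0.05) dunn_bonferroni(mad_groups) else NULL
  stats_rows <- write_stats_report(
    kw, dunn,
    csv_path = file.path(config$outdir, "stats_overall.csv"),
    txt_path = file.path(config$outdir, "stats_overall.txt"),
    title = "T0-T1 change by method, all patches pooled"
  )

  repro <- NULL
  if (isTRUE(config$reproducibility)) {
    rrows <- list()
    for (s in cohort$subjects) {
      for (a in config$areas) {
        r1 <- reproducibility_run(s, a, seed = config$seed * 2L + 1L)
        r2 <- reproducibility_run(s, a, seed = config$seed * 2L + 2L)
        d <- reproducibility_difference(r1, r2)
        d$subject <- s$subject_id
        d$area <- a
        rrows[[length(rrows) + 1L]] <- d
      }
    }
    repro <- do.call(rbind, rrows)
    utils::write.csv(repro,
                     file.path(config$outdir, "reproducibility.csv"),
                     row.names = FALSE)
  }

  writeLines(c(log_lines, sprintf("R version: %s", R.version.string)), logf)
  list(scores = scores, mad_long = mad_long, t1_differences = wide,
       stats = stats_rows, reproducibility = repro,
       manifest = cohort$manifest)
}
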