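#' Configuration of an end-to-end propagation run
#'
#' @param algorithm "demons" or "sfbr".
#' @param demons_schedule a \code{demons_schedule} (demons runs).
#' @param sfbr_params an \code{sfbr_params} (sfbr runs).
#' @param histogram_bins,histogram_match_points intensity-matching
#'   parameters applied before demons.
#' @param do_rigid run the rigid pre-registration stage (disable when the
#'   inputs are already aligned on a common grid).
#' @param mesh_smooth Taubin smoothing passes applied to extracted ROI
#'   surfaces on the SFBR path (removes the voxel staircase before
#'   warping; see \code{extract_mesh}).
#' @param seed integer seed recorded with the run.
#' @param output_dir optional directory for artifacts (reports, DVF or TPS,
#'   propagated masks, logs); NULL keeps everything in memory.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(algorithm = c("demons", "sfbr"),
                       demons_schedule = adaptreg::demons_schedule(),
                       sfbr_params = adaptreg::sfbr_params(),
                       histogram_bins = 64, histogram_match_points = 7,
                       do_rigid = TRUE, mesh_smooth = 5, seed = 1,
                       output_dir = NULL) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, demons_schedule = demons_schedule,
                 sfbr_params = sfbr_params, mesh_smooth = mesh_smooth,
                 histogram_bins = histogram_bins,
                 histogram_match_points = histogram_match_points,
                 do_rigid = do_rigid, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON config path; recognized fields override the defaults
#'   of \code{run_config}.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(algorithm = j$algorithm %||% "demons",
                    histogram_bins = j$histogram_bins %||% 64,
                    histogram_match_points = j$histogram_match_points %||% 7,
                    do_rigid = j$do_rigid %||% TRUE,
                    seed = j$seed %||% 1,
                    output_dir = j$output_dir)
  if (!is.null(j$demons_levels))
    cfg$demons_schedule <- demons_schedule(
      levels = lapply(seq_len(nrow(j$demons_levels)), function(i)
        as.numeric(j$demons_levels[i, ])),
      stop_tolerance_percent = j$stop_tolerance_percent %||% 1.5,
      stop_window_iterations = j$stop_window_iterations %||% 5)
  if (!is.null(j$reliability_threshold) || !is.null(j$search_radius_mm))
    cfg$sfbr_params <- sfbr_params(
      reliability_threshold = j$reliability_threshold %||% 0.80,
      search_radius_mm = j$search_radius_mm %||% 15)
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run one case end to end
#'
#' Mirrors the clinical ROI-propagation workflow: rigid cross-correlation
#' pre-registration of the planning scan onto the per-treatment scan, then
#' either the demons path (histogram match, multi-resolution demons, mask
#' pull-back per ROI) or the SFBR path (feature detection and matching,
#' thin-plate-spline fit, ROI surface mesh warp and rasterization). When
#' expert masks on the per-treatment image are supplied, a per-ROI metric
#' report (Dice, MSHD, COM shift) is produced.
#'
#' @param planning planning \code{image_volume}.
#' @param planning_masks named list of \code{binary_mask}s on the planning
#'   grid.
#' @param per_treatment per-treatment \code{image_volume} (the target).
#' @param expert_masks optional named list of expert \code{binary_mask}s on
#'   the per-treatment grid (names matched to \code{planning_masks}).
#' @param config a \code{run_config}.
#' @param verbose print stage progress.
#' @return list with \code{propagated} (named list of masks on the target
#'   grid), \code{metrics} (data.frame or NULL), \code{rigid},
#'   \code{registration} (the \code{registration_result} or the
#'   \code{sfbr_register} output), \code{timings_s} (per-stage seconds,
#'   informational only).
#' @export
run_case <- function(planning, planning_masks, per_treatment,
                     expert_masks = NULL, config = run_config(),
                     verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  rigid <- if (config$do_rigid)
    stage("rigid_register", rigid_register(per_treatment, planning))
  else rigid_transform(center = c(0, 0, 0))
  planning_al <- stage("rigid_resample",
                       apply_rigid(planning, rigid, per_treatment))
  masks_al <- lapply(planning_masks, function(m) {
    v <- apply_rigid(image_volume(m$data * 1, m$spacing, m$origin), rigid,
                     per_treatment, nearest = TRUE)
    binary_mask(v$data > 0.5, v$spacing, v$origin, m$label)
  })
  timings["rigid"] <- tic() - t0
  propagated <- list()
  registration <- NULL
  t0 <- tic()
  if (config$algorithm == "demons") {
    moving <- stage("histogram_match",
                    histogram_match(planning_al, per_treatment,
                                    config$histogram_bins,
                                    config$histogram_match_points))
    registration <- stage("demons_register",
                          demons_register(per_treatment, moving,
                                          config$demons_schedule,
                                          verbose = verbose))
    timings["dir"] <- tic() - t0
    t0 <- tic()
    propagated <- lapply(masks_al, propagate_mask,
                         dvf = registration$dvf)
  } else {
    registration <- stage("sfbr_register",
                          sfbr_register(planning_al, per_treatment,
                                        config$sfbr_params))
    timings["dir"] <- tic() - t0
    t0 <- tic()
    propagated <- lapply(masks_al, function(m) stage(m$label, {
      mesh <- extract_mesh(m, smooth_iterations = config$mesh_smooth)
      rasterize_mesh(warp_mesh(mesh, registration$transform),
                     per_treatment)
    }))
  }
  timings["propagate"] <- tic() - t0
  metrics <- NULL
  if (!is.null(expert_masks)) {
    common <- intersect(names(propagated), names(expert_masks))
    metrics <- do.call(rbind, lapply(common, function(lb) {
      r <- metric_report(propagated[[lb]], expert_masks[[lb]])
      r$algorithm <- config$algorithm
      r
    }))
  }
  out <- list(propagated = propagated, metrics = metrics, rigid = rigid,
              registration = registration, timings_s = timings)
  if (!is.null(config$output_dir))
    write_case_artifacts(out, config)
  out
}

write_case_artifacts <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  write_rigid_json(result$rigid, file.path(od, "rigid.json"))
  if (!is.null(result$metrics))
    utils::write.csv(result$metrics, file.path(od, "metrics.csv"),
                     row.names = FALSE)
  for (lb in names(result$propagated))
    write_mask_nifti(result$propagated[[lb]],
                     file.path(od, paste0("propagated_", lb, ".nii")))
  if (config$algorithm == "demons") {
    write_dvf_nifti(result$registration$dvf, file.path(od, "dvf"))
    write_msd_trace(result$registration, file.path(od, "msd_trace.csv"))
  } else {
    write_tps_json(result$registration$transform,
                   file.path(od, "tps.json"))
    write_correspondences_csv(result$registration$correspondences,
                              file.path(od, "correspondences.csv"))
  }
  log <- c(sprintf("[INFO] algorithm %s seed %d", config$algorithm,
                   config$seed),
           sprintf("[INFO] stage %s: %.2f s", names(result$timings_s),
                   result$timings_s))
  writeLines(log, file.path(od, "run.log"))
  invisible(od)
}

#' Aggregate per-case metric reports into study tables
#'
#' Per organ, algorithm and metric: mean, standard error and range
#' (single-case groups get an NA standard error); one-way ANOVA between
#' the two algorithms per organ and metric; expert-score summaries and the
#' point-biserial correlation of each metric against the dichotomized
#' scores (1-2 vs 3) when a score table is supplied.
#'
#' @param case_metrics data.frame of per-case rows (columns patient,
#'   roi_label, algorithm, dice, mshd_mm, com_mag_mm at least).
#' @param scores optional score data.frame (patient, roi_label, algorithm,
#'   score).
#' @param metrics metric columns to summarize.
#' @return list with \code{summary} (data.frame), \code{anova}
#'   (data.frame), \code{score_summary}, \code{point_biserial}.
#' @export
aggregate_study <- function(case_metrics, scores = NULL,
                            metrics = c("dice", "mshd_mm", "com_mag_mm")) {
  if (is.null(case_metrics) || nrow(case_metrics) == 0)
    stop("no case metrics supplied")
  metrics <- intersect(metrics, names(case_metrics))
  key <- interaction(case_metrics$roi_label, case_metrics$algorithm,
                     drop = TRUE)
  rows <- list()
  for (k in levels(key)) {
    sub <- case_metrics[key == k, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]][is.finite(sub[[m]])]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        roi_label = sub$roi_label[1], algorithm = sub$algorithm[1],
        metric = m, n = length(v), mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        min = min(v), max = max(v))
    }
  }
  summary_df <- do.call(rbind, rows)
  an <- list()
  for (lb in unique(case_metrics$roi_label)) {
    for (m in metrics) {
      groups <- lapply(split(case_metrics[case_metrics$roi_label == lb, m],
                             case_metrics$algorithm[
                               case_metrics$roi_label == lb]),
                       function(v) v[is.finite(v)])
      groups <- groups[vapply(groups, length, integer(1)) >= 2]
      if (length(groups) < 2) next
      a <- one_way_anova(groups)
      an[[length(an) + 1L]] <- data.frame(
        roi_label = lb, metric = m, F = a$F, p = a$p,
        df1 = a$df[1], df2 = a$df[2],
        significant = a$p < 0.05)
    }
  }
  anova_df <- if (length(an)) do.call(rbind, an) else NULL
  ss <- pb <- NULL
  if (!is.null(scores)) {
    check_scores(scores$score)
    ss <- list(overall = score_summary(scores$score))
    for (alg in unique(scores$algorithm))
      ss[[alg]] <- score_summary(scores$score[scores$algorithm == alg])
    joined <- merge(case_metrics, scores,
                    by = c("patient", "roi_label", "algorithm"))
    if (nrow(joined)) {
      g <- dichotomize_scores(joined$score)
      pb <- do.call(rbind, lapply(metrics, function(m) {
        v <- joined[[m]]
        okv <- is.finite(v)
        if (length(unique(g[okv])) < 2 || stats::sd(v[okv]) == 0)
          return(data.frame(metric = m, r_pb = NA_real_, p = NA_real_,
                            n = sum(okv)))
        r <- point_biserial(g[okv], v[okv])
        data.frame(metric = m, r_pb = r$r_pb, p = r$p, n = sum(okv))
      }))
    }
  }
  list(summary = summary_df, anova = anova_df, score_summary = ss,
       point_biserial = pb)
}
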