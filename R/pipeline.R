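# End-to-end bilateral-symmetry pipeline:
# mirror -> rigid superposition -> 50 mm cut + re-superposition -> 30 mm cut
# + re-superposition -> nonrigid correspondence on the most distal 25 mm ->
# articular ROI -> distance statistics and heatmaps.

#' Pipeline configuration
#'
#' @param cut1_height_mm first cut height above the most distal point of the
#'   medial malleolus (mm).
#' @param cut2_height_mm second cut height (mm); the resulting plafond models.
#' @param correspondence_height_mm correspondences are established on the
#'   most distal this-many mm of the plafond.
#' @param roi_angle_deg articulating-surface selection half-angle (degrees).
#' @param heatmap_cap_mm distances above this render at the cap colour
#'   (dark red).
#' @param whisker_percentiles boxplot whisker percentiles.
#' @param cpd a [cpd_params()].
#' @param seed integer seed governing all stochastic steps (subsampling).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cut1_height_mm = 50, cut2_height_mm = 30,
                            correspondence_height_mm = 25, roi_angle_deg = 90,
                            heatmap_cap_mm = 2, whisker_percentiles = c(1, 99),
                            cpd = cpd_params(), seed = 0L) {
  if (!(cut1_height_mm > cut2_height_mm &&
        cut2_height_mm > correspondence_height_mm &&
        correspondence_height_mm > 0))
    stop("cut heights must satisfy cut1 > cut2 > correspondence_height > 0")
  if (heatmap_cap_mm <= 0) stop("heatmap_cap_mm must be positive")
  cpd$seed <- as.integer(seed)
  structure(list(cut1_height_mm = cut1_height_mm,
                 cut2_height_mm = cut2_height_mm,
                 correspondence_height_mm = correspondence_height_mm,
                 roi_angle_deg = roi_angle_deg,
                 heatmap_cap_mm = heatmap_cap_mm,
                 whisker_percentiles = whisker_percentiles,
                 cpd = cpd, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Summarize correspondence distances
#'
#' Median, quartiles and whisker percentiles by linear interpolation between
#' closest ranks (`stats::quantile` type 7) — stated because interquartile
#' values depend on the percentile method.
#'
#' @param distances non-empty numeric vector of non-negative distances (mm).
#' @param whisker_percentiles whisker percentiles (default 1st and 99th, the
#'   boxplot convention used for reporting).
#' @return An object of class `distance_summary`: `median_mm`, `q1_mm`,
#'   `q3_mm`, `p_lo_mm`, `p_hi_mm`, `max_mm`, `n_points`.
#' @export
summarize_distances <- function(distances, whisker_percentiles = c(1, 99)) {
  d <- as.numeric(distances)
  if (!length(d)) stop("empty distance list")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and non-negative")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75, whisker_percentiles / 100),
                       type = 7, names = FALSE)
  structure(list(median_mm = q[2], q1_mm = q[1], q3_mm = q[3],
                 p_lo_mm = q[4], p_hi_mm = q[5], max_mm = max(d),
                 n_points = length(d)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("median %.2f mm (IQR, %.2f - %.2f), whiskers [%.2f, %.2f], max %.2f mm, n = %d\n",
              x$median_mm, x$q1_mm, x$q3_mm, x$p_lo_mm, x$p_hi_mm, x$max_mm,
              x$n_points))
  invisible(x)
}

check_registration <- function(reg, stage) {
  tr <- reg$report$objective_trace
  if (length(tr) > 3L) {
    inc <- sum(diff(tr) > 1e-6 * abs(tr[-length(tr)]))
    if (inc > 3L)
      stop(structure(class = c("bisym_registration_error", "error", "condition"),
                     list(message = paste0("registration diverged at stage '", stage,
                                           "' (objective increased ", inc, " times)"),
                          call = sys.call(-1), report = reg$report)))
  }
  invisible(reg)
}

non_boundary <- function(mesh) {
  idx <- setdiff(seq_len(n_vertices(mesh)), mesh$boundary)
  mesh$vertices[idx, , drop = FALSE]
}

#' Run the bilateral-symmetry pipeline on one left/right pair
#'
#' Executes, in order: anatomical-frame alignment of both bones; sagittal
#' mirroring of the left; rigid CPD of the mirrored left onto the right
#' (full bones); cutting of both bones `cut1_height_mm` above the right
#' bone's most distal point (the same world plane for both) and rigid
#' re-superposition; a second cut at `cut2_height_mm` and re-superposition,
#' yielding two equally sized plafond models; nonrigid CPD of the right model
#' onto the superimposed mirrored left, restricted to the most distal
#' `correspondence_height_mm`; correspondence extraction (distances from
#' original right vertices to matched left-surface points); the
#' articulating-surface ROI rule; and distance summaries. Cut-boundary
#' vertices are excluded from registration, correspondence and ROI.
#'
#' @param left_mesh,right_mesh [tri_surface()] bones of opposite sides.
#' @param config a [pipeline_config()].
#' @param specimen_id label used in outputs.
#' @param out_dir if non-`NULL`, writes `<id>_heatmap.ply` (distances as PLY
#'   `quality`), `<id>_axial.png` and `<id>_run.json` there.
#' @return An object of class `pair_result`: `specimen_id`, `summary_full`,
#'   `summary_articular`, `correspondences` (a `correspondence_set` with
#'   `articular_mask` filled), `heatmap_mesh` (right plafond with per-vertex
#'   distances, `NA` on the cut boundary), `frame` (the working canonical
#'   frame), `frame_right`, `frame_left` (the fitted input frames, mapping
#'   input coordinates to working coordinates via [to_frame_coords()]),
#'   `reference_point`, `reports` (per-stage registration reports) and
#'   `run_record`.
#' @export
run_pair <- function(left_mesh, right_mesh, config = pipeline_config(),
                     specimen_id = "specimen", out_dir = NULL) {
  frame0 <- anatomical_frame()
  frame_r <- fit_anatomical_frame(right_mesh, "right")
  frame_l <- fit_anatomical_frame(left_mesh, "left")
  right <- to_frame_coords(right_mesh, frame_r)
  leftM <- mirror_sagittal(to_frame_coords(left_mesh, frame_l), frame = frame0)

  reports <- list()
  # stage A: rigid superposition of the full bones
  regA <- rigid_cpd(leftM$vertices, right$vertices, config$cpd)
  check_registration(regA, "full-bone rigid")
  reports$rigid_full <- regA$report
  leftM <- apply_transform(leftM, regA$transform)

  # stage B: cut both at cut1 above the right bone's most distal point
  anchorR <- min(drop(right$vertices %*% frame0$axis_si))
  cutR1 <- cut_at_height(right, frame0, config$cut1_height_mm)
  cutL1 <- cut_at_height(leftM, frame0, config$cut1_height_mm,
                         anchor_level = anchorR)
  regB <- rigid_cpd(non_boundary(cutL1$distal_part),
                    non_boundary(cutR1$distal_part), config$cpd)
  check_registration(regB, "50 mm rigid")
  reports$rigid_cut1 <- regB$report
  left1 <- apply_transform(cutL1$distal_part, regB$transform)
  right1 <- cutR1$distal_part

  # stage C: cut at cut2, re-superimpose -> two equally sized plafonds
  anchorR <- min(drop(right1$vertices %*% frame0$axis_si))
  cutR2 <- cut_at_height(right1, frame0, config$cut2_height_mm)
  cutL2 <- cut_at_height(left1, frame0, config$cut2_height_mm,
                         anchor_level = anchorR)
  regC <- rigid_cpd(non_boundary(cutL2$distal_part),
                    non_boundary(cutR2$distal_part), config$cpd)
  check_registration(regC, "30 mm rigid")
  reports$rigid_cut2 <- regC$report
  left2 <- apply_transform(cutL2$distal_part, regC$transform)
  right2 <- cutR2$distal_part

  # stage D: nonrigid correspondence on the most distal correspondence height
  anchorR <- min(drop(right2$vertices %*% frame0$axis_si))
  cutR3 <- cut_at_height(right2, frame0, config$correspondence_height_mm)
  cutL3 <- cut_at_height(left2, frame0, config$correspondence_height_mm,
                         anchor_level = anchorR)
  right25 <- compute_vertex_normals(cutR3$distal_part)
  left25 <- cutL3$distal_part
  corr_idx <- setdiff(seq_len(n_vertices(right25)), right25$boundary)
  regD <- nonrigid_cpd(right25$vertices[corr_idx, , drop = FALSE],
                       non_boundary(left25), config$cpd)
  check_registration(regD, "nonrigid")
  reports$nonrigid <- regD$report
  corr <- correspondence_from_warp(right25$vertices[corr_idx, , drop = FALSE],
                                   regD$warp, left25)

  # articulating-surface ROI from the 30 mm plafond's reference point
  ref <- reference_point(right2, frame0)
  mask <- select_articulating_surface(right25, ref, config$roi_angle_deg)
  corr$articular_mask <- mask$selected[corr_idx]

  summary_full <- summarize_distances(corr$distances_mm, config$whisker_percentiles)
  if (!any(corr$articular_mask))
    stop("articulating-surface mask selected no correspondence vertices")
  summary_articular <- summarize_distances(corr$distances_mm[corr$articular_mask],
                                           config$whisker_percentiles)

  heat <- rep(NA_real_, n_vertices(right25))
  heat[corr_idx] <- corr$distances_mm

  frame_json <- function(fr) list(origin = fr$origin, axis_ml = fr$axis_ml,
                                  axis_ap = fr$axis_ap, axis_si = fr$axis_si)
  run_record <- list(
    specimen_id = specimen_id,
    config = unclass_config(config),
    seed = config$seed,
    frames = list(right = frame_json(frame_r), left = frame_json(frame_l)),
    reference_point = ref,
    stages = lapply(reports, function(r)
      list(iterations = r$iterations_run, final_sigma2 = r$final_sigma2,
           converged = r$converged)),
    n_correspondences = length(corr$distances_mm),
    package = "bisym",
    package_version = as.character(utils::packageVersion("bisym")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- structure(list(specimen_id = specimen_id,
                           summary_full = summary_full,
                           summary_articular = summary_articular,
                           correspondences = corr,
                           heatmap_mesh = right25,
                           heatmap_distances = heat,
                           frame = frame0,
                           frame_right = frame_r,
                           frame_left = frame_l,
                           reference_point = ref,
                           reports = reports,
                           run_record = run_record),
                      class = "pair_result")
  if (!is.null(out_dir)) write_pair_outputs(result, config, out_dir)
  result
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$cpd <- unclass(cfg$cpd)
  cfg
}

write_pair_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- result$specimen_id
  ply <- file.path(out_dir, paste0(id, "_heatmap.ply"))
  save_mesh(result$heatmap_mesh, ply, per_vertex_scalar = result$heatmap_distances)
  result$run_record$outputs <- list(heatmap_ply = basename(ply))
  if (capabilities("png")) {
    png_path <- file.path(out_dir, paste0(id, "_axial.png"))
    grDevices::png(png_path, width = 800, height = 800)
    render_heatmap(result, cap_mm = config$heatmap_cap_mm)
    grDevices::dev.off()
    result$run_record$outputs$axial_png <- basename(png_path)
  }
  jsonlite::write_json(result$run_record,
                       file.path(out_dir, paste0(id, "_run.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("pair_result '%s'\n", x$specimen_id))
  cat("  entire plafond:      "); print(x$summary_full)
  cat("  articulating surface:"); print(x$summary_articular)
  invisible(x)
}

#' Run the pipeline over a cohort of pairs
#'
#' Accepts either a list of pairs (elements with `specimen_id`, `left`,
#' `right`) or a manifest `data.frame` with columns `specimen_id`,
#' `left_path`, `right_path` (meshes loaded with [load_mesh()]). Individual
#' pair failures are recorded and skipped with a warning. Pooled distance
#' vectors aggregate all correspondence distances across specimens (the
#' primary tables); per-specimen medians are summarized alongside, since a
#' cohort median can be formed either way.
#'
#' @param pairs list of pairs or manifest data frame.
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, writes `cohort.tsv` (one row per specimen),
#'   `cohort_run.json`, and per-pair outputs there.
#' @return An object of class `cohort_result`: `table` (per-specimen
#'   statistics), `pooled_full`, `pooled_articular` (pooled distance
#'   vectors), `summary_pooled_full`, `summary_pooled_articular`,
#'   `per_specimen_median_full`, `per_specimen_median_articular`, `results`
#'   (the `pair_result`s) and `failures`.
#' @export
run_cohort <- function(pairs, config = pipeline_config(), out_dir = NULL) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("specimen_id", "left_path", "right_path") %in% names(pairs)))
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      list(specimen_id = as.character(pairs$specimen_id[i]),
           left = load_mesh(pairs$left_path[i]),
           right = load_mesh(pairs$right_path[i])))
  }
  if (!length(pairs)) stop("empty pair list")
  results <- list(); failures <- list()
  for (p in pairs) {
    id <- if (!is.null(p$specimen_id)) p$specimen_id else sprintf("specimen_%03d", length(results) + 1L)
    res <- tryCatch(run_pair(p$left, p$right, config, specimen_id = id,
                             out_dir = out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("pair '", id, "' failed: ", conditionMessage(res))
      failures[[id]] <- conditionMessage(res)
    } else results[[id]] <- res
  }
  if (!length(results)) stop("all pairs failed")

  fmt <- function(s) c(median = s$median_mm, q1 = s$q1_mm, q3 = s$q3_mm,
                       max = s$max_mm)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(specimen_id = r$specimen_id,
               n_points = r$summary_full$n_points,
               t(stats::setNames(fmt(r$summary_full),
                                 paste0(c("median", "q1", "q3", "max"), "_full_mm"))),
               t(stats::setNames(fmt(r$summary_articular),
                                 paste0(c("median", "q1", "q3", "max"), "_articular_mm"))),
               row.names = NULL, check.names = FALSE)
  }))
  pooled_full <- unlist(lapply(results, function(r) r$correspondences$distances_mm),
                        use.names = FALSE)
  pooled_art <- unlist(lapply(results, function(r)
    r$correspondences$distances_mm[r$correspondences$articular_mask]),
    use.names = FALSE)
  out <- structure(list(
    table = tab,
    pooled_full = pooled_full,
    pooled_articular = pooled_art,
    summary_pooled_full = summarize_distances(pooled_full, config$whisker_percentiles),
    summary_pooled_articular = summarize_distances(pooled_art, config$whisker_percentiles),
    per_specimen_median_full = vapply(results, function(r) r$summary_full$median_mm, 0),
    per_specimen_median_articular = vapply(results, function(r) r$summary_articular$median_mm, 0),
    results = results,
    failures = failures), class = "cohort_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
                       file.path(out_dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(config = unclass_config(config),
                              n_pairs = length(pairs),
                              n_succeeded = length(results),
                              failures = failures,
                              package = "bisym",
                              package_version = as.character(utils::packageVersion("bisym")),
                              r_version = paste(R.version$major, R.version$minor, sep = ".")),
                         file.path(out_dir, "cohort_run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d specimens (%d failed)\n",
              nrow(x$table), length(x$failures)))
  cat("  pooled, entire plafond:       "); print(x$summary_pooled_full)
  cat("  pooled, articulating surface: "); print(x$summary_pooled_articular)
  invisible(x)
}
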