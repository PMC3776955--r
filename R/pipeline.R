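#' Pipeline configuration
#'
#' @param spec a [phantom_spec()].
#' @param boot a [bootstrap_config()].
#' @param pen a [penetration_config()].
#' @param seed master seed; the phantom, session, bootstrap and
#'   penetration seeds are derived from it unless set explicitly.
#' @param thresholds p-value thresholds for the area summary.
#' @param preprocess run homomorphic normalization and high-pass
#'   filtering before amplitude extraction.
#' @param compute_ci compute per-voxel centroid confidence intervals.
#' @param out_dir optional directory for artifacts (NIfTI maps, meshes,
#'   CSV tables, summary JSON); NULL writes nothing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = phantom_spec(), boot = bootstrap_config(),
                            pen = penetration_config(), seed = 1,
                            thresholds = c(0.05, 0.16),
                            preprocess = TRUE, compute_ci = FALSE,
                            out_dir = NULL) {
  spec$seed <- spec$seed + 1000L * seed
  boot$seed <- boot$seed + 1000L * seed
  pen$seed <- pen$seed + 1000L * seed
  structure(list(spec = spec, boot = boot, pen = pen, seed = seed,
                 thresholds = thresholds, preprocess = preprocess,
                 compute_ci = compute_ci, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full depth-gradient pipeline on a synthetic phantom
#'
#' Executes the stages end to end: phantom synthesis (mask, planted
#' frequency field, simulated session), surface modeling (mesh, curvature
#' region), voxel responses (preprocessing, amplitudes, frequency maps),
#' virtual penetrations on the fine analysis grid (depth map, gradient
#' fits, bootstrap p), and the whole-structure summary (areas, mean
#' slope, mean gradient direction), together with ground-truth recovery
#' statistics.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @return List with elements `mask`, `truth`, `session`, `mesh`,
#'   `region`, `resp`, `maps`, `grid`, `depthmap`, `gradients`,
#'   `summary`, `recovery`, `report_row`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  spec <- config$spec

  mask <- stage("synth", make_phantom_mask(spec))
  truth <- stage("synth", plant_frequency_field(mask, spec))
  session <- stage("synth", simulate_session(truth, spec))

  mesh <- stage("surface", extract_surface(mask))
  region <- stage("surface", {
    above_slab <- mesh$vertices[, 3] > spec$slab_top_mm + 0.5
    curvature_and_region(mesh, restrict = above_slab)
  })

  resp <- stage("respond", {
    series <- session$data
    if (config$preprocess) {
      series <- homomorphic_normalize(series, spec$voxel_size_mm)
      series <- highpass(series, session$design$run,
                         stim_cycles_per_run = spec$reps_per_run)
    }
    extract_amplitudes(series, session$design, mask = session$mask)
  })
  maps <- stage("respond", frequency_maps(resp, config$boot,
                                          ci = config$compute_ci))

  grid <- stage("penetrate",
                analysis_grid(mask, spec$voxel_size_mm,
                              config$pen$upsample_factor))
  depthmap <- stage("penetrate",
                    compute_depth_map(grid$mask, mesh, grid$voxel_size))
  gradients <- stage("penetrate",
                     map_gradients(mesh, region, depthmap, grid, resp,
                                   config$pen))

  summary <- stage("summarize",
                   gradient_summary(mesh, region, gradients,
                                    config$thresholds, config$pen))
  recovery <- stage("summarize",
                    recovery_stats(gradients, truth, grid, depthmap,
                                   config$pen))
  out <- list(mask = mask, truth = truth, session = session, mesh = mesh,
              region = region, resp = resp, maps = maps, grid = grid,
              depthmap = depthmap, gradients = gradients,
              summary = summary, recovery = recovery,
              report_row = summary$report_row, config = config)
  if (!is.null(config$out_dir)) write_artifacts(out, config$out_dir)
  out
}

#' Whole-structure gradient summary
#'
#' Areas below each significance threshold, the mean and sd of the fitted
#' slope, fit quality and initial depth over significant penetrations,
#' and the slope-weighted mean gradient direction with its sagittal and
#' axial angles.
#'
#' @param mesh surface mesh.
#' @param region region vertex mask or ids.
#' @param gradients a [map_gradients()] table.
#' @param thresholds significance and trend p thresholds.
#' @param pen the [penetration_config()] used.
#' @return List with `areas`, `total_area_mm2`, `sig_area_mm2`,
#'   `trend_area_mm2`, `mean_slope`, `sd_slope`, `mean_r2`, `mean_d0`,
#'   `direction`, `report_row` (named numeric vector in the report-table
#'   layout).
#' @export
gradient_summary <- function(mesh, region, gradients,
                             thresholds = c(0.05, 0.16),
                             pen = penetration_config()) {
  if (is.logical(region)) region <- which(region)
  areas <- area_summary(mesh, gradients$vertex, gradients$p,
                        c(thresholds, 1.01))
  total <- region_area(mesh, region)
  sig <- !is.na(gradients$p) & gradients$p < thresholds[1]
  dirs <- as.matrix(gradients[, c("nx", "ny", "nz")])
  md <- mean_gradient_direction(dirs, gradients$g, gradients$p,
                                thresholds[1])
  mean_or_na <- function(x) if (any(sig)) mean(x[sig], na.rm = TRUE) else NA_real_
  sd_or_na <- function(x) if (sum(sig) > 1) sd(x[sig], na.rm = TRUE) else NA_real_
  out <- list(areas = areas,
              total_area_mm2 = total,
              sig_area_mm2 = areas$area_mm2[1],
              trend_area_mm2 = areas$area_mm2[2],
              mean_slope = mean_or_na(gradients$g),
              sd_slope = sd_or_na(gradients$g),
              mean_r2 = mean_or_na(gradients$r2),
              mean_d0 = mean_or_na(gradients$d0),
              direction = md,
              n_vertices = nrow(gradients),
              n_significant = sum(sig))
  out$report_row <- c(sig_area_mm2 = out$sig_area_mm2,
                      trend_area_mm2 = out$trend_area_mm2,
                      total_area_mm2 = out$total_area_mm2,
                      depth_slope = out$mean_slope,
                      sagittal_angle_deg = md$sagittal_angle_deg,
                      axial_angle_deg = md$axial_angle_deg,
                      r2 = out$mean_r2,
                      initial_depth_mm = out$mean_d0)
  out
}

# Nearest-voxel ground-truth label/field sampling at fine-grid points.
sample_truth <- function(field, pts, voxel_size) {
  d <- dim(field)
  idx <- pmin(pmax(floor(sweep(pts, 2, voxel_size, "/")) + 1, 1),
              matrix(rep(d, each = nrow(pts)), nrow(pts), 3))
  field[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

#' Ground-truth recovery statistics
#'
#' Matches each usable penetration against the planted field: a
#' penetration is "in patch" when every member voxel below the planted
#' rind carries the tonotopic label, and "reversed" when the gradient
#' there is negated. Reports the significant fraction and mean recovered
#' slope and initial depth within fully tonotopic penetrations.
#'
#' @param gradients a [map_gradients()] table with penetration rows.
#' @param truth the [plant_frequency_field()] ground truth.
#' @param grid the [analysis_grid()].
#' @param depthmap the analysis-grid depth map.
#' @param pen the [penetration_config()].
#' @return List with `in_patch` (logical per vertex), `frac_sig_in_patch`,
#'   `mean_slope_in_patch_sig`, `mean_d0_in_patch_sig`, `frac_sig_all`,
#'   `g_true`, `rind_mm`, `n_in_patch`.
#' @export
recovery_stats <- function(gradients, truth, grid, depthmap,
                           pen = penetration_config()) {
  rows_list <- attr(gradients, "penetration_rows")
  pts <- as.matrix(depthmap$voxels[, c("x", "y", "z")])
  vs <- truth$spec$voxel_size_mm
  lab_fine <- sample_truth(truth$patch_label, pts, vs)
  depth_fine <- sample_truth(truth$depth_mm, pts, vs)
  n <- nrow(gradients)
  in_patch <- rep(FALSE, n)
  reversed <- rep(FALSE, n)
  for (k in seq_len(n)) {
    rows <- rows_list[[k]]
    if (is.null(rows) || !length(rows)) next
    lab <- lab_fine[rows]
    deep <- !is.na(depth_fine[rows]) &
      depth_fine[rows] >= truth$rind_thickness_mm
    if (!any(deep)) next
    in_patch[k] <- all(lab[deep] == 2L, na.rm = TRUE)
    reversed[k] <- all(lab[deep] == 3L, na.rm = TRUE)
  }
  sig <- !is.na(gradients$p) & gradients$p < pen$sig_threshold
  ips <- in_patch & sig
  list(in_patch = in_patch, reversed = reversed,
       n_in_patch = sum(in_patch),
       frac_sig_in_patch = if (any(in_patch)) mean(sig[in_patch]) else NA_real_,
       mean_slope_in_patch_sig = if (any(ips)) mean(gradients$g[ips]) else NA_real_,
       mean_d0_in_patch_sig = if (any(ips)) mean(gradients$d0[ips]) else NA_real_,
       frac_sig_all = mean(sig[gradients$usable]),
       g_true = truth$g_true, rind_mm = truth$rind_thickness_mm)
}

#' Report-table statistics
#'
#' Column-wise unweighted mean and sample sd over per-phantom (or
#' per-subject) rows, plus the pooled significant-to-total area ratio in
#' integer percent.
#'
#' @param rows data frame or matrix of report rows (columns as in
#'   `report_row` of [gradient_summary()]).
#' @return List `mean`, `sd` (named vectors; sd is 0 for a single row)
#'   and `sig_total_ratio_pct` (integer percent, half-up rounding).
#' @export
table_stats <- function(rows) {
  rows <- as.data.frame(rows)
  if (!nrow(rows)) stop("need at least one row")
  mn <- vapply(rows, mean, numeric(1))
  sdv <- if (nrow(rows) > 1) vapply(rows, sd, numeric(1)) else
    vapply(rows, function(x) 0, numeric(1))
  ratio <- NA_real_
  if (all(c("sig_area_mm2", "total_area_mm2") %in% names(rows)))
    ratio <- round_half_up(100 * sum(rows$sig_area_mm2) /
                             sum(rows$total_area_mm2))
  list(mean = mn, sd = sdv, sig_total_ratio_pct = ratio)
}

#' Format a report table for display
#'
#' Rounds to the conventional display precision: areas and angles to
#' integers, slopes, fit quality and initial depth to two decimals
#' (half-up rounding).
#'
#' @param rows report rows (see [table_stats()]).
#' @return Data frame with a `mean` and `sd` row appended.
#' @export
format_report <- function(rows) {
  rows <- as.data.frame(rows)
  st <- table_stats(rows)
  all_rows <- rbind(rows, rbind(st$mean), rbind(st$sd))
  rownames(all_rows) <- c(rownames(rows), "mean", "sd")
  disp <- all_rows
  for (nm in names(disp)) {
    digits <- if (grepl("area|angle", nm)) 0 else 2
    disp[[nm]] <- round_half_up(all_rows[[nm]], digits)
  }
  disp
}

#' Bundled reference values from a published four-subject 3 T study
#'
#' Per-subject summary cells (areas, depth slopes, gradient angles, fit
#' quality, initial depths) of a human inferior-colliculus depth-gradient
#' analysis, bundled as inputs for arithmetic cross-checks of the report
#' machinery.
#'
#' @return Data frame, one row per subject.
#' @export
reference_depth_summary <- function() {
  path <- system.file("extdata", "reference_depth_summary.csv",
                      package = "tonodepth")
  read.csv(path)
}

# Write artifacts of a pipeline result to a directory.
write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- result$config$spec$voxel_size_mm
  write_volume(result$mask, file.path(out_dir, "mask.nii.gz"), vs)
  write_volume(result$truth$depth_mm, file.path(out_dir, "depth_true.nii.gz"), vs)
  for (col in c("f_cent", "f_tune", "hl_diff", "p_sound")) {
    write_volume(maps_as_volume(result$maps, col),
                 file.path(out_dir, paste0(col, ".nii.gz")), vs)
  }
  dm <- array(NA_real_, result$grid$dim)
  dm[result$depthmap$voxels$voxel] <- result$depthmap$voxels$depth_mm
  write_volume(dm, file.path(out_dir, "depth_map.nii.gz"),
               result$grid$voxel_size)
  write_mesh_obj(result$mesh, file.path(out_dir, "surface.obj"))
  scal <- data.frame(curvature = result$mesh$mean_curvature,
                     region = as.numeric(result$region))
  write_mesh_ply(result$mesh, file.path(out_dir, "surface.ply"), scal)
  vertex_results_table(result$gradients, result$mesh,
                       file.path(out_dir, "vertex_gradients.csv"))
  write.csv(result$session$design, file.path(out_dir, "design.csv"),
            row.names = FALSE)
  summ <- list(seed = result$config$seed,
               report_row = as.list(result$report_row),
               recovery = result$recovery[c("n_in_patch",
                                            "frac_sig_in_patch",
                                            "mean_slope_in_patch_sig",
                                            "mean_d0_in_patch_sig",
                                            "frac_sig_all", "g_true")],
               n_vertices = result$summary$n_vertices,
               n_significant = result$summary$n_significant)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Parameter-recovery experiment over replicate sessions
#'
#' Runs the full pipeline on independent simulated sessions of the same
#' phantom and averages the ground-truth recovery statistics: the mean
#' fitted slope and initial depth over fully planted significant
#' penetrations, and the fraction of planted penetrations reaching
#' significance. Session-level results are strongly correlated within a
#' session (penetrations share the session's noise field), so replicate
#' sessions stabilize the estimates.
#'
#' @param n_sessions number of independent sessions.
#' @param seed base seed; session s uses `seed + s - 1`.
#' @param spec phantom specification (defaults plant the gradient over
#'   the whole cap surface, the cleanest recovery design).
#' @param ... passed to [pipeline_config()].
#' @return List with `mean_slope`, `mean_d0`, `frac_sig`, `g_true`,
#'   `rind_mm`, `n_penetrations` (total), and `sessions` (per-session
#'   rows).
#' @export
run_recovery_experiment <- function(n_sessions = 3, seed = 1,
                                    spec = phantom_spec(patch_fraction = 1),
                                    ...) {
  rows <- lapply(seq_len(n_sessions), function(s) {
    res <- run_pipeline(pipeline_config(spec = spec, seed = seed + s - 1,
                                        ...))
    r <- res$recovery
    data.frame(seed = seed + s - 1, slope = r$mean_slope_in_patch_sig,
               d0 = r$mean_d0_in_patch_sig, frac_sig = r$frac_sig_in_patch,
               n_in_patch = r$n_in_patch)
  })
  rows <- do.call(rbind, rows)
  list(mean_slope = mean(rows$slope), mean_d0 = mean(rows$d0),
       frac_sig = mean(rows$frac_sig), g_true = spec$gradient_oct_per_mm,
       rind_mm = spec$rind_thickness_mm,
       n_penetrations = sum(rows$n_in_patch), sessions = rows)
}
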