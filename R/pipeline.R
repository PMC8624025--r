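REPORT_SCHEMA <- "hemitherm-report/1"

roi_to_list <- function(roi) unclass(roi)

roi_from_list <- function(x) {
  roi_spec(x$top, x$left, x$height, x$width,
           laterality = if (is.null(x$laterality)) "left" else x$laterality,
           label = if (is.null(x$label)) "" else x$label)
}

#' Read a ROI / analysis configuration file
#'
#' YAML (or JSON) configuration with `healthy` and `diseased` ROI blocks
#' (`top`, `left`, `height`, `width`, optional `laterality`, `label`) and
#' optional `grade` or `delta_t`, `connectivity`, `min_area`, `axis_col`.
#'
#' @param path Config file path.
#' @return List with `healthy_roi`, `diseased_roi` ([roi_spec()] or `NULL`)
#'   and any further scalar options present.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) ht_io_error("no such config file: %s", path)
  cfg <- yaml::read_yaml(path)
  out <- list(healthy_roi = if (!is.null(cfg$healthy)) roi_from_list(cfg$healthy),
              diseased_roi = if (!is.null(cfg$diseased)) roi_from_list(cfg$diseased))
  for (k in c("grade", "delta_t", "connectivity", "min_area", "axis_col"))
    out[[k]] <- cfg[[k]]
  out
}

resolve_policy <- function(grade = NULL, delta_t = NULL) {
  if (is.null(grade) == is.null(delta_t))
    ht_precondition_error("supply exactly one of grade or delta_t")
  if (!is.null(delta_t)) threshold_policy(delta_t) else threshold_for_grade(grade)
}

as_frame_input <- function(x, what) {
  if (is_thermal_frame(x)) return(list(frame = x, path = NULL))
  if (is.character(x) && length(x) == 1L)
    return(list(frame = read_temperature_grid(x), path = x))
  ht_precondition_error("%s must be a thermal_frame or a grid file path", what)
}

whole_frame_roi <- function(frame, laterality) {
  roi_spec(0, 0, frame$height, frame$width, laterality = laterality)
}

#' Run the full bilateral differential analysis on one case
#'
#' Executes extract -> mirror -> differential -> severity threshold ->
#' hotspot segmentation -> frame repositioning, then writes the analysis
#' artifacts: `report.json`, `regions.csv`, `mask.png` (ROI-local label
#' image), `overlay.png` (main region contoured on the diseased frame) and
#' `surface.png` (3-D differential surface).  All results are computed
#' before any file is written, and each file is written to a temporary name
#' and renamed, so a failed run leaves no ambiguous partial output.
#'
#' The report records every parameter that affects the output (inputs, ROIs,
#' cut-off, connectivity, minimum area, band), so a run can be replayed
#' exactly.
#'
#' @param healthy,diseased [thermal_frame()]s or paths to temperature grids.
#' @param healthy_roi,diseased_roi [roi_spec()]s of identical size; `NULL`
#'   (default) uses each whole frame.
#' @param grade Severity grade (`"severe"`/`"moderate"`); supply exactly one
#'   of `grade` and `delta_t`.
#' @param delta_t Explicit cut-off in deg C.
#' @param outdir Output directory, created if needed; `NULL` skips all file
#'   output and just returns the report and intermediate maps.
#' @param connectivity,min_region_area Passed to [segment_hotspots()].
#' @param thresholds Delta-T levels for the asymmetry summary.
#' @param timestamp Report timestamp string; pass a fixed value for
#'   byte-reproducible reports.
#' @return The analysis report (list, class `hemitherm_report`), with the
#'   intermediate `differential`/`thresholded` matrices and `regions`
#'   attached as attributes.
#' @export
analyze_case <- function(healthy, diseased, healthy_roi = NULL,
                         diseased_roi = NULL, grade = NULL, delta_t = NULL,
                         outdir = NULL, connectivity = 8L,
                         min_region_area = 5L, thresholds = c(2, 3),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  policy <- resolve_policy(grade, delta_t)
  hin <- as_frame_input(healthy, "healthy")
  din <- as_frame_input(diseased, "diseased")
  if (is.null(healthy_roi)) healthy_roi <- whole_frame_roi(hin$frame, "right")
  if (is.null(diseased_roi)) diseased_roi <- whole_frame_roi(din$frame, "left")
  if (healthy_roi$height != diseased_roi$height ||
      healthy_roi$width != diseased_roi$width)
    ht_dimension_error("paired ROIs must match: healthy %dx%d vs diseased %dx%d",
                       healthy_roi$height, healthy_roi$width,
                       diseased_roi$height, diseased_roi$width)

  H <- extract_roi(hin$frame, healthy_roi, "healthy")
  D <- extract_roi(din$frame, diseased_roi, "diseased")
  R <- differential_map(D, H)
  Rp <- threshold_map(R, policy)
  regions <- segment_hotspots(Rp, connectivity = connectivity,
                              min_region_area = min_region_area)
  summ <- asymmetry_summary(R, thresholds = thresholds)
  main <- if (length(regions)) regions[[1L]] else NULL
  placement <- frame_placement(diseased_roi, mirrored = FALSE)
  main_frame_px <- if (!is.null(main))
    map_region_to_frame(main, placement, frame = din$frame)

  artifacts <- if (!is.null(outdir))
    list(report = file.path(outdir, "report.json"),
         regions = file.path(outdir, "regions.csv"),
         mask = file.path(outdir, "mask.png"),
         overlay = file.path(outdir, "overlay.png"),
         surface = file.path(outdir, "surface.png"))

  main_desc <- if (!is.null(main)) {
    list(area_px = main$area, max_delta_t_C = main$max_delta_t,
         mean_delta_t_C = main$mean_delta_t,
         centroid = as.list(main$centroid), bbox = as.list(main$bbox),
         elongation = main$elongation,
         frame_bbox = list(top = min(main_frame_px[, 1L]),
                           left = min(main_frame_px[, 2L]),
                           height = diff(range(main_frame_px[, 1L])) + 1L,
                           width = diff(range(main_frame_px[, 2L])) + 1L))
  }

  report <- list(
    schema = REPORT_SCHEMA,
    tool_version = as.character(utils::packageVersion("hemitherm")),
    timestamp = timestamp,
    inputs = list(healthy = hin$path, diseased = din$path),
    healthy_roi = roi_to_list(healthy_roi),
    diseased_roi = roi_to_list(diseased_roi),
    policy = list(delta_t = policy$delta_t, source = policy$source,
                  grade = policy$grade),
    connectivity = as.integer(connectivity),
    min_region_area = as.integer(min_region_area),
    band = hin$frame$band,
    summary = list(max_delta_t = summ$max_delta_t,
                   mean_delta_t = summ$mean_delta_t,
                   n_valid = summ$n_valid, n_invalid = summ$n_invalid,
                   at_or_above = summ$at_or_above),
    n_regions = length(regions),
    no_suprathreshold_focus = length(regions) == 0L,
    regions = region_table(regions),
    main_region = main_desc,
    # artifact names are relative to the report's directory so that a
    # replayed run into another directory yields a byte-identical report
    artifacts = if (!is.null(outdir)) lapply(artifacts, basename))
  class(report) <- "hemitherm_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_atomic <- function(path, writer) {
      tmp <- paste0(path, ".tmp")
      writer(tmp)
      if (!file.rename(tmp, path)) ht_io_error("cannot write %s", path)
    }
    write_atomic(artifacts$regions, function(p)
      utils::write.csv(region_table(regions), p, row.names = FALSE))
    write_atomic(artifacts$mask, function(p)
      write_label_png(regions, nrow(Rp), ncol(Rp), p))
    write_atomic(artifacts$overlay, function(p) {
      mask <- matrix(FALSE, din$frame$height, din$frame$width)
      if (!is.null(main_frame_px) && nrow(main_frame_px))
        mask[main_frame_px + 1L] <- TRUE
      suppressWarnings(render_overlay(din$frame, mask, p))
    })
    write_atomic(artifacts$surface, function(p) render_surface(R, p))
    write_atomic(artifacts$report, function(p) write_report(report, p))
  }
  attr(report, "differential") <- R
  attr(report, "thresholded") <- Rp
  attr(report, "hotspots") <- regions
  report
}

#' @export
print.hemitherm_report <- function(x, ...) {
  cat(sprintf("<hemitherm_report> cut-off %g degC (%s), %d region(s)\n",
              x$policy$delta_t, x$policy$source, x$n_regions))
  cat(sprintf("  max dT %.2f degC, mean dT %.3f degC over %d valid px\n",
              x$summary$max_delta_t, x$summary$mean_delta_t, x$summary$n_valid))
  if (x$no_suprathreshold_focus)
    cat("  no suprathreshold focus detected\n")
  invisible(x)
}

#' Write / read an analysis report
#'
#' Reports are JSON (schema `hemitherm-report/1`), written with full numeric
#' precision so a re-read report compares exactly.
#'
#' @param report A report from [analyze_case()].
#' @param path JSON path.
#' @return `write_report`: `path` invisibly; `read_report`: the report list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) ht_io_error("no such report: %s", path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "hemitherm_report"
  rep
}

report_geometry <- function(r) {
  list(h = c(r$healthy_roi$height, r$healthy_roi$width),
       d = c(r$diseased_roi$height, r$diseased_roi$width),
       delta_t = r$policy$delta_t)
}

main_area <- function(r) if (is.null(r$main_region)) 0L else r$main_region$area_px

#' Compare two longitudinal analysis sessions
#'
#' Thermographic follow-up (e.g. a control at 48 h under antibiotics)
#' compares two analyses of the same ROI geometry and cut-off.  Reports
#' per-session max/mean Delta-T and main-region area, their changes, and a
#' descriptive label: `"regressing"` when both max Delta-T and area
#' decreased (or a focus disappeared), `"progressing"` when both increased
#' (or a focus appeared), `"stable"` when nothing changed, `"mixed"`
#' otherwise.  The label is descriptive only, not a clinical call.
#'
#' @param report_t1,report_t2 Reports from [analyze_case()] (objects or JSON
#'   paths), earlier session first.
#' @return A list with per-session statistics, `change` (deltas) and
#'   `label`.
#' @export
compare_sessions <- function(report_t1, report_t2) {
  r1 <- if (is.character(report_t1)) read_report(report_t1) else report_t1
  r2 <- if (is.character(report_t2)) read_report(report_t2) else report_t2
  g1 <- report_geometry(r1); g2 <- report_geometry(r2)
  if (!isTRUE(all.equal(g1, g2)))
    ht_comparability_error("sessions are not comparable: ROI geometry or cut-off differ (t1: %s/%s dT=%g; t2: %s/%s dT=%g)",
                           paste(g1$h, collapse = "x"), paste(g1$d, collapse = "x"), g1$delta_t,
                           paste(g2$h, collapse = "x"), paste(g2$d, collapse = "x"), g2$delta_t)
  a1 <- main_area(r1); a2 <- main_area(r2)
  d_max <- r2$summary$max_delta_t - r1$summary$max_delta_t
  d_mean <- r2$summary$mean_delta_t - r1$summary$mean_delta_t
  d_area <- a2 - a1
  label <- if (d_max == 0 && d_area == 0 && d_mean == 0) "stable"
  else if (a1 == 0L && a2 > 0L) "progressing"
  else if (a1 > 0L && a2 == 0L) "regressing"
  else if (d_max < 0 && d_area <= 0 || d_max <= 0 && d_area < 0) "regressing"
  else if (d_max > 0 && d_area >= 0 || d_max >= 0 && d_area > 0) "progressing"
  else "mixed"
  list(t1 = list(max_delta_t = r1$summary$max_delta_t,
                 mean_delta_t = r1$summary$mean_delta_t, main_area_px = a1),
       t2 = list(max_delta_t = r2$summary$max_delta_t,
                 mean_delta_t = r2$summary$mean_delta_t, main_area_px = a2),
       change = list(max_delta_t = d_max, mean_delta_t = d_mean,
                     main_area_px = d_area),
       label = label)
}
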