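#' Run the full analysis on an in-memory thermogram
#'
#' Executes background removal, automatic breast segmentation, gray-to-
#' temperature conversion and the bilateral asymmetry evaluation; when (and
#' only when) the asymmetry rule fires, the hotter breast is watershed-
#' segmented and the hottest region localized. Segmentation failures never
#' crash the pipeline: they yield the `"unknown"` outcome.
#'
#' @param x a [thermogram()].
#' @param delta_t asymmetry decision threshold, degrees C (default 1.0).
#' @param fold_offset fold threshold offset in gray levels (default 10).
#' @param h armpit secant half-step in pixels (default 10).
#' @param delta_min watershed peak-prominence suppression, degrees C
#'   (default 0.5).
#' @param fold_margin rows excluded above the fold polynomial (default 8).
#' @param scale_bar optional scale-bar rectangle, see [extract_body_mask()].
#' @param invert set `TRUE` for hot-dark palettes.
#' @return an object of class `thermo_report`: `status` (`"no_problem"`,
#'   `"problem"` or `"unknown"`), the exact user `message`
#'   (`"no problem detected"`, `"problem detected"` or `"unknown"`),
#'   `body`, `segmentation`, `evaluation`, `watershed`, `hotspot`,
#'   `pattern`, the failure `reason` when unknown, and the `params` used.
#' @export
analyze_thermogram <- function(x, delta_t = 1.0, fold_offset = 10, h = 10,
                               delta_min = 0.5, fold_margin = 8,
                               scale_bar = NULL, invert = FALSE) {
  stopifnot(inherits(x, "thermogram"))
  params <- list(delta_t = delta_t, fold_offset = fold_offset, h = h,
                 delta_min = delta_min, fold_margin = fold_margin,
                 scale_bar = scale_bar, invert = invert)
  out <- list(status = "unknown", message = "unknown", body = NULL,
              segmentation = NULL, evaluation = NULL, watershed = NULL,
              hotspot = NULL, pattern = NULL, reason = NULL, params = params)
  res <- tryCatch({
    body <- extract_body_mask(x, scale_bar = scale_bar, invert = invert)
    seg <- segment_breasts(x, body = body, offset = fold_offset, h = h,
                           fold_margin = fold_margin)
    thermal <- to_thermal(x)
    ev <- evaluate_sides(thermal, seg, delta_t = delta_t)
    out$body <- body; out$segmentation <- seg; out$evaluation <- ev
    if (ev$verdict == "problem_detected") {
      hot_mask <- if (ev$hotter_side == "left") seg$left_mask else seg$right_mask
      ws <- watershed_segment(thermal, hot_mask, delta = delta_min)
      hs <- locate_hotspot(thermal, ws)
      out$watershed <- ws
      out$hotspot <- hs
      out$pattern <- describe_pattern(ws, hs$basin_id)
      out$status <- "problem"; out$message <- "problem detected"
    } else {
      out$status <- "no_problem"; out$message <- "no problem detected"
    }
    out
  }, thermaseg_error = function(e) {
    out$reason <- conditionMessage(e)
    out
  })
  structure(res, class = "thermo_report")
}

#' @export
print.thermo_report <- function(x, ...) {
  cat(sprintf("<thermo_report> %s\n", x$message))
  if (!is.null(x$reason)) cat(sprintf("  reason: %s\n", x$reason))
  if (!is.null(x$evaluation)) print(x$evaluation)
  if (!is.null(x$hotspot)) print(x$hotspot)
  invisible(x)
}

report_exit_code <- function(report) {
  switch(report$status, no_problem = 0L, problem = 2L, 3L)
}

report_json_payload <- function(report) {
  ev <- report$evaluation
  list(
    status = report$status,
    message = report$message,
    reason = report$reason,
    params = report$params[c("delta_t", "fold_offset", "h", "delta_min",
                             "fold_margin")],
    evaluation = if (!is.null(ev)) list(
      verdict = ev$verdict, hotter_side = ev$hotter_side,
      diff_avg = ev$diff_avg, diff_max = ev$diff_max,
      diff_min = ev$diff_min, diff_sd = ev$diff_sd,
      left = unclass(ev$left)[c("avg", "max", "min", "sd", "pixel_count")],
      right = unclass(ev$right)[c("avg", "max", "min", "sd", "pixel_count")]
    ),
    segmentation = if (!is.null(report$segmentation)) list(
      split_point = c(x = report$segmentation$split$x,
                      y = report$segmentation$split$y),
      low_confidence = isTRUE(report$segmentation$split$low_confidence) ||
        isTRUE(report$segmentation$armpits$low_confidence),
      fold_right = as.list(report$segmentation$fold_right$coef),
      fold_left = as.list(report$segmentation$fold_left$coef),
      armpit_right = report$segmentation$armpits$right,
      armpit_left = report$segmentation$armpits$left
    ),
    hotspot = if (!is.null(report$hotspot)) list(
      basin_id = report$hotspot$basin_id,
      centroid = report$hotspot$centroid,
      area_px = report$hotspot$area_px,
      mean_temp = report$hotspot$mean_temp,
      max_temp = report$hotspot$max_temp,
      shape = report$pattern
    )
  )
}

# Overlay: the input gray image with a white ring around the hotspot.
overlay_image <- function(x, hotspot) {
  g <- x$pixels / (x$levels - 1L)
  r <- sqrt(hotspot$area_px / pi) + 3
  d <- sqrt((col(g) - hotspot$centroid[["x"]])^2 +
              (row(g) - hotspot$centroid[["y"]])^2)
  g[abs(d - r) <= 1] <- 1
  g
}

#' Run the pipeline on files
#'
#' Reads an image (PNG/TIFF) or temperature CSV plus its radiometric
#' sidecar, runs [analyze_thermogram()], and optionally writes the report
#' artifacts: `report.json`, `stats.csv` (per-side statistics table),
#' left/right mask PNGs and — when a problem is detected — the watershed
#' label map and an overlay with the hotspot circled. Outputs contain no
#' timestamps, so re-running on identical inputs reproduces them byte for
#' byte.
#'
#' @param image path to the thermogram (`.png`, `.tif(f)`) or temperature
#'   matrix (`.csv`).
#' @param sidecar path to the radiometric sidecar YAML (optional for CSV
#'   input).
#' @param out_dir directory for artifacts; `NULL` writes nothing.
#' @param ... passed to [analyze_thermogram()].
#' @return the `thermo_report`, invisibly; its exit-code convention is
#'   0 = no problem, 2 = problem detected, 3 = unknown.
#' @export
run_pipeline <- function(image, sidecar = NULL, out_dir = NULL, ...) {
  ext <- tolower(tools::file_ext(image))
  x <- if (ext == "csv") {
    meta <- if (!is.null(sidecar)) read_sidecar(sidecar) else NULL
    thermal_to_thermogram(read_temperature_csv(image, meta))
  } else {
    if (is.null(sidecar)) stop_degenerate("image input requires a sidecar")
    read_thermogram(image, sidecar)
  }
  report <- analyze_thermogram(x, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_json_payload(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (!is.null(report$evaluation)) {
      write_stats_csv(report$evaluation, file.path(out_dir, "stats.csv"))
    }
    if (!is.null(report$segmentation)) {
      write_mask_png(report$segmentation$right_mask,
                     file.path(out_dir, "right_mask.png"))
      write_mask_png(report$segmentation$left_mask,
                     file.path(out_dir, "left_mask.png"))
    }
    if (!is.null(report$hotspot)) {
      lab <- report$watershed$labels
      png::writePNG(lab / max(1L, max(lab)), file.path(out_dir, "labels.png"))
      png::writePNG(overlay_image(x, report$hotspot),
                    file.path(out_dir, "overlay.png"))
    }
  }
  invisible(report)
}
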