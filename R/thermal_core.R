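#' Radiometric metadata for a thermogram
#'
#' The scene calibration recorded by the camera software alongside the 8-bit
#' image: scene minimum and maximum temperature, skin emissivity, camera
#' distance and the sensor's instantaneous field of view. Only `t_min_c` and
#' `t_max_c` enter the gray-to-temperature mapping; emissivity and the
#' optics are carried as acquisition metadata.
#'
#' @param t_min_c scene minimum temperature, degrees C.
#' @param t_max_c scene maximum temperature, degrees C; must exceed `t_min_c`.
#' @param emissivity surface emissivity in (0, 1]; human skin is about 0.97.
#' @param distance_m camera-to-subject distance in meters.
#' @param ifov_mrad instantaneous field of view of the sensor, milliradians.
#' @return an object of class `radiometric_meta`.
#' @examples
#' radiometric_meta(24.04, 36.5)
#' @export
radiometric_meta <- function(t_min_c, t_max_c, emissivity = 0.97,
                             distance_m = 1.2, ifov_mrad = 1.36) {
  stopifnot(is.numeric(t_min_c), is.numeric(t_max_c), length(t_min_c) == 1L,
            length(t_max_c) == 1L, is.finite(t_min_c), is.finite(t_max_c))
  if (t_min_c >= t_max_c) {
    stop_degenerate("`t_min_c` must be strictly less than `t_max_c`")
  }
  if (!is.numeric(emissivity) || emissivity <= 0 || emissivity > 1) {
    stop_degenerate("`emissivity` must lie in (0, 1]")
  }
  structure(
    list(t_min_c = t_min_c, t_max_c = t_max_c, emissivity = emissivity,
         distance_m = distance_m, ifov_mrad = ifov_mrad),
    class = "radiometric_meta"
  )
}

#' Construct a thermogram
#'
#' A thermogram couples an integer matrix of gray intensities (0 to
#' `levels - 1`, rows = image rows) with its radiometric metadata.
#'
#' @param pixels integer matrix of gray intensities.
#' @param meta a [radiometric_meta()] object.
#' @param levels number of gray levels L (256 for 8-bit images).
#' @return an object of class `thermogram`.
#' @examples
#' m <- matrix(sample(0:255, 64, TRUE), 8, 8)
#' tg <- thermogram(m, radiometric_meta(24, 36.5))
#' @export
thermogram <- function(pixels, meta, levels = 256L) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_degenerate("`pixels` must be a non-empty matrix")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > levels - 1L)) {
    stop_degenerate(sprintf("gray intensities must lie in [0, %d]", levels - 1L))
  }
  if (any(pixels != round(pixels))) {
    stop_degenerate("gray intensities must be integers")
  }
  stopifnot(inherits(meta, "radiometric_meta"))
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
         meta = meta, levels = as.integer(levels)),
    class = "thermogram"
  )
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d x %d px, %d gray levels, scene %.2f..%.2f degC\n",
              nrow(x$pixels), ncol(x$pixels), x$levels,
              x$meta$t_min_c, x$meta$t_max_c))
  invisible(x)
}

#' Convert a thermogram to a temperature matrix
#'
#' Maps gray intensities affinely onto the scene temperature range:
#' `Tr = Tmin + Tgray / Tvgm * (Tmax - Tmin)`, where `Tvgm` is the maximum
#' gray intensity *present in the image* (not `L - 1`). A pixel at gray 0
#' therefore maps to `Tmin` and the brightest pixel maps exactly to `Tmax`;
#' the calibration is image-dependent by construction.
#'
#' @param x a [thermogram()].
#' @return an object of class `thermal_matrix`: a numeric matrix of degrees C
#'   (field `temps`) with the source metadata attached.
#' @examples
#' tg <- thermogram(matrix(c(0L, 128L, 255L, 64L), 2, 2),
#'                  radiometric_meta(24.04, 36.5))
#' to_thermal(tg)$temps
#' @export
to_thermal <- function(x) {
  stopifnot(inherits(x, "thermogram"))
  tvgm <- max(x$pixels)
  if (tvgm == 0L) {
    stop_degenerate("all-zero image: Tvgm is 0, the thermal scale is undefined")
  }
  temps <- x$meta$t_min_c + x$pixels / tvgm * (x$meta$t_max_c - x$meta$t_min_c)
  structure(list(temps = temps, meta = x$meta, tvgm = tvgm),
            class = "thermal_matrix")
}

#' @export
print.thermal_matrix <- function(x, ...) {
  cat(sprintf("<thermal_matrix> %d x %d px, %.2f..%.2f degC (Tvgm = %d)\n",
              nrow(x$temps), ncol(x$temps), min(x$temps), max(x$temps), x$tvgm))
  invisible(x)
}

temps_of <- function(x) {
  if (inherits(x, "thermal_matrix")) x$temps
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_degenerate("expected a thermal_matrix or a numeric matrix")
}

#' Temperature statistics over a masked region
#'
#' Average, maximum, minimum and population standard deviation (divide by n)
#' of the temperatures under a binary mask — the per-side statistics reported
#' for each segmented breast.
#'
#' @param thermal a `thermal_matrix` or plain numeric matrix of degrees C.
#' @param mask logical matrix of the same shape; at least one `TRUE` pixel.
#' @return an object of class `region_stats` with fields `avg`, `max`, `min`,
#'   `sd`, `pixel_count`.
#' @examples
#' m <- matrix(c(25, 27, 30, 30), 2, 2)
#' region_stats(m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
#' @export
region_stats <- function(thermal, mask) {
  t <- temps_of(thermal)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(t), dim(mask))) {
    stop_degenerate("`mask` must have the same shape as the temperature matrix")
  }
  v <- t[mask]
  if (length(v) == 0L) stop_degenerate("empty mask: no pixels to summarize")
  m <- mean(v)
  structure(
    list(avg = m, max = max(v), min = min(v),
         sd = sqrt(mean((v - m)^2)), pixel_count = length(v)),
    class = "region_stats"
  )
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("<region_stats> n=%d  avg=%.2f  max=%.2f  min=%.2f  sd=%.2f degC\n",
              x$pixel_count, x$avg, x$max, x$min, x$sd))
  invisible(x)
}

#' Measurable spot size of the infrared sensor
#'
#' Theoretical spot size is `(IFOV / 1000) * distance`; real lenses require a
#' safety factor, conventionally 3 (the measurement field of view, MFOV).
#' At IFOV 1.36 mrad and 1.2 m the theoretical spot is 0.001632 m and the
#' MFOV spot about 0.5 cm, the scale of the smallest reliably measurable
#' tumor (T1b and larger).
#'
#' @param ifov_mrad instantaneous field of view, milliradians (> 0).
#' @param distance_m distance to the target, meters (> 0).
#' @param safety_factor integer >= 1; 1 = theoretical spot, 3 = MFOV.
#' @return spot size in meters.
#' @examples
#' spot_size(1.36, 1.2)      # 0.001632
#' spot_size(1.36, 1.2, 3)   # ~0.005 m
#' @export
spot_size <- function(ifov_mrad, distance_m, safety_factor = 1L) {
  if (!is.numeric(ifov_mrad) || ifov_mrad <= 0 ||
      !is.numeric(distance_m) || distance_m <= 0) {
    stop_degenerate("`ifov_mrad` and `distance_m` must be positive")
  }
  if (safety_factor < 1) stop_degenerate("`safety_factor` must be >= 1")
  safety_factor * (ifov_mrad / 1000) * distance_m
}

#' Time to thermal stabilization of a temperature series
#'
#' Patients must rest until skin temperature stops drifting before a
#' thermogram is diagnostic (about 25 minutes under the acquisition protocol
#' this package targets). Given a time series of mean skin temperatures,
#' returns the first time point from which every subsequent successive slope
#' satisfies `|dT/dt| <= slope_tol`; `Inf` if the series never stabilizes.
#'
#' @param minutes numeric vector of sampling times, strictly increasing.
#' @param temps_c temperatures at those times, degrees C.
#' @param slope_tol tolerated drift, degrees C per minute (default 0.05).
#' @return the stabilization time in minutes, or `Inf`.
#' @examples
#' t <- seq(0, 40, by = 5)
#' stabilization_time(t, 34 + 2 * exp(-t / 6))
#' @export
stabilization_time <- function(minutes, temps_c, slope_tol = 0.05) {
  stopifnot(is.numeric(minutes), is.numeric(temps_c))
  if (length(minutes) < 3L || length(minutes) != length(temps_c)) {
    stop_degenerate("need at least 3 (time, temperature) points")
  }
  if (any(diff(minutes) <= 0)) {
    stop_degenerate("`minutes` must be strictly increasing")
  }
  slopes <- abs(diff(temps_c) / diff(minutes))
  ok <- rev(cumprod(rev(slopes <= slope_tol))) == 1  # all slopes from i on
  i <- which(ok)[1L]
  if (is.na(i)) Inf else minutes[i]
}
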