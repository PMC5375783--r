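#' Watershed segmentation of a temperature region
#'
#' Partitions the masked temperatures into catchment basins by morphological
#' flooding. The classical operator floods from regional minima; since the
#' regions of interest here are the *hottest* ones, flooding is applied to
#' the additive inverse of temperature, so every hot peak becomes a basin.
#' Shallow peaks are suppressed: a peak whose prominence above the point of
#' first contact with a neighboring basin is below `delta` is merged into
#' that neighbor, curbing noise-driven over-segmentation.
#'
#' @param thermal a `thermal_matrix` or numeric matrix of degrees C.
#' @param mask logical matrix restricting the flooding domain.
#' @param delta minimum peak prominence in degrees C (default 0.5).
#' @return an object of class `watershed_labels`: integer `labels` (0 =
#'   watershed line or outside mask, k >= 1 = basin), logical `lines`,
#'   `basin_ids` and per-basin [region_stats()] in `basin_stats`.
#' @export
watershed_segment <- function(thermal, mask, delta = 0.5) {
  t <- temps_of(thermal)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(t), dim(mask))) {
    stop_degenerate("`mask` must have the same shape as the temperature matrix")
  }
  if (!any(mask)) stop_degenerate("empty mask")
  rng <- range(t[mask])
  if (diff(rng) < 1e-9) {
    labels <- matrix(0L, nrow(t), ncol(t)); labels[mask] <- 1L
  } else {
    # hot peaks become basins of the flooded relief
    relief <- matrix(0, nrow(t), ncol(t))
    relief[mask] <- t[mask] - rng[1L] + 1e-6
    labels <- EBImage::watershed(relief, tolerance = delta, ext = 1)
    storage.mode(labels) <- "integer"
  }
  lines <- watershed_lines(labels)
  labels[lines] <- 0L
  ids <- sort(unique(labels[labels > 0L]))
  stats <- lapply(ids, function(k) region_stats(t, labels == k))
  names(stats) <- as.character(ids)
  structure(
    list(labels = labels, lines = lines, mask = mask,
         basin_ids = ids, basin_stats = stats, delta = delta),
    class = "watershed_labels"
  )
}

# A pixel is on a watershed line when a 4-neighbor belongs to a different
# basin with a smaller id; each inter-basin boundary thus yields a
# one-pixel line carved from the higher-id side (deterministic, keeps every
# basin connected).
watershed_lines <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  lines <- matrix(FALSE, n, m)
  cmp <- function(a, b) a > 0L & b > 0L & b < a
  lines[-1, ] <- lines[-1, ] | cmp(labels[-1, ], labels[-n, ])
  lines[-n, ] <- lines[-n, ] | cmp(labels[-n, ], labels[-1, ])
  lines[, -1] <- lines[, -1] | cmp(labels[, -1], labels[, -m])
  lines[, -m] <- lines[, -m] | cmp(labels[, -m], labels[, -1])
  lines
}

#' @export
print.watershed_labels <- function(x, ...) {
  cat(sprintf("<watershed_labels> %d basin(s), %d line px (delta = %.2f degC)\n",
              length(x$basin_ids), sum(x$lines), x$delta))
  invisible(x)
}

#' Locate the hottest region
#'
#' The hotspot is the watershed basin containing the hottest labeled pixel.
#' Its centroid is weighted by temperature elevation above the basin's
#' coolest pixel (uniform when the basin is isothermal), so the reported
#' point tracks the heat mass rather than the basin outline.
#'
#' @param thermal the temperature matrix used for the watershed.
#' @param ws a [watershed_segment()] result.
#' @return an object of class `hotspot_result`: `basin_id`, `centroid`
#'   (`c(x, y)`), `area_px`, `mean_temp`, `max_temp` and
#'   `contains_global_max` (true by construction).
#' @export
locate_hotspot <- function(thermal, ws) {
  t <- temps_of(thermal)
  stopifnot(inherits(ws, "watershed_labels"))
  lab <- ws$labels
  if (!any(lab > 0L)) stop_degenerate("no basins to search")
  tt <- t; tt[lab == 0L] <- -Inf
  peak <- which.max(tt)
  k <- lab[peak]
  sel <- lab == k
  w <- t[sel] - min(t[sel])
  if (sum(w) <= 0) w <- rep(1, sum(sel))
  structure(
    list(basin_id = k,
         centroid = c(x = sum(w * col(t)[sel]) / sum(w),
                      y = sum(w * row(t)[sel]) / sum(w)),
         area_px = sum(sel),
         mean_temp = mean(t[sel]),
         max_temp = max(t[sel]),
         contains_global_max = TRUE),
    class = "hotspot_result"
  )
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf(
    "<hotspot_result> basin %d at (%.1f, %.1f), %d px, mean %.2f / max %.2f degC\n",
    x$basin_id, x$centroid[["x"]], x$centroid[["y"]], x$area_px,
    x$mean_temp, x$max_temp))
  invisible(x)
}

#' Shape descriptors of a watershed basin
#'
#' Tumors tend to produce compact hot regions while angiogenesis produces
#' elongated, vessel-like ones. This reports geometry only — area,
#' eccentricity of the best-fit ellipse and elongation (major/minor axis
#' ratio) from the second moments of the basin pixels — and leaves the
#' interpretation to the expert.
#'
#' @param ws a [watershed_segment()] result.
#' @param basin_id basin to describe (e.g. `hotspot$basin_id`).
#' @return list with `area_px`, `eccentricity`, `elongation`,
#'   `major_axis`, `minor_axis`.
#' @export
describe_pattern <- function(ws, basin_id) {
  stopifnot(inherits(ws, "watershed_labels"))
  sel <- ws$labels == basin_id
  if (!any(sel)) stop_degenerate("basin id not present")
  xy <- cbind(col(ws$labels)[sel], row(ws$labels)[sel])
  # 1/12 is the variance of a unit pixel: keeps 1-px-wide basins finite
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy) + diag(1 / 12, 2)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(area_px = sum(sel),
       eccentricity = sqrt(max(0, 1 - ev[2] / ev[1])),
       elongation = sqrt(ev[1] / ev[2]),
       major_axis = 2 * sqrt(ev[1]),
       minor_axis = 2 * sqrt(ev[2]))
}
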