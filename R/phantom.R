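#' Specification of a synthetic torso phantom
#'
#' Describes a seated frontal torso thermogram as the acquisition protocol
#' produces it: a warm body silhouette with raised arms (hands at the nape)
#' on a cold background, a hot skin-contact ridge along each inframammary
#' fold, an abrupt contour slope change at each armpit, an optional warm
#' lesion confined to one breast, and additive Gaussian noise. The defaults
#' reproduce the acquisition conditions this package targets: 320 x 240 px
#' frames, a scene floor of 24.04 degrees C, skin near 32.5 degrees C and a
#' fold ridge about 4 degrees C above the skin baseline.
#'
#' The lesion is rendered as a two-scale Gaussian elevation centred at
#' `center` (by default the centroid of the ground-truth breast mask, hence
#' off the fold): a focal peak of amplitude `dt` with sigma `radius / 2`,
#' and a broad hypervascular component of amplitude `0.925 * dt` with sigma
#' `1.3 * breast_radius`, truncated to the affected side. The affected
#' breast's mean elevation is then about `0.8 * dt`, so lesions with
#' `dt >= 1.5` produce bilateral mean differences comfortably above the
#' 1 degree C screening threshold while the focal peak stays below the fold
#' ridge (keeping the fold the hottest structure, as in real thermograms).
#'
#' @param image_size `c(rows, cols)` of the frame.
#' @param background_t,body_t background and skin baseline, degrees C.
#' @param torso_halfwidth torso half-width in px at the armpit row.
#' @param top_row,bottom_row first and last body rows.
#' @param armpit_row_right,armpit_row_left armpit rows (patient sides).
#' @param arm_slope outward slope of the raised-arm contour (px per row).
#' @param taper outward taper of the torso below the armpit (px per row).
#' @param breast_offset_x distance from the body midline to each breast
#'   centre column, px.
#' @param fold_vertex_row row of the lowest fold point.
#' @param fold_k curvature of the fold parabola (px^-1).
#' @param fold_halfspan rendered half-extent of each fold ridge, px.
#' @param ridge_dt fold ridge contrast above the skin baseline, degrees C.
#' @param ridge_sigma vertical Gaussian sigma of the ridge, px.
#' @param breast_radius nominal breast radius, px (sets the broad lesion
#'   scale).
#' @param lesion `NULL` for a healthy phantom, or a list with `side`
#'   (`"left"`/`"right"`), `dt` (degrees C, > 0), `radius` (px, >= 3) and
#'   optional `center = c(x, y)`.
#' @param noise_sd additive Gaussian noise, degrees C.
#' @param fold_margin rows excluded above the fold when building the
#'   ground-truth breast masks (must match the pipeline setting for IoU
#'   comparisons).
#' @param seed integer seed making the phantom reproducible; `NULL` uses the
#'   current RNG state.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(240L, 320L),
                         background_t = 24.04, body_t = 32.5,
                         torso_halfwidth = 55,
                         top_row = 30, bottom_row = 230,
                         armpit_row_right = 80, armpit_row_left = 80,
                         arm_slope = 1.2, taper = 0.05,
                         breast_offset_x = 42,
                         fold_vertex_row = 172, fold_k = 0.02,
                         fold_halfspan = 36,
                         ridge_dt = 4.0, ridge_sigma = 3.0,
                         breast_radius = 38,
                         lesion = NULL,
                         noise_sd = 0.1,
                         fold_margin = 8,
                         seed = NULL) {
  if (background_t >= body_t) {
    stop_degenerate("`background_t` must be below `body_t`")
  }
  if (ridge_dt <= 0) stop_degenerate("`ridge_dt` must be positive")
  if (!is.null(lesion)) {
    if (!lesion$side %in% c("left", "right")) {
      stop_degenerate("lesion side must be 'left' or 'right'")
    }
    if (lesion$dt <= 0) stop_degenerate("lesion `dt` must be positive")
    if (lesion$radius < 3) stop_degenerate("lesion `radius` must be >= 3 px")
    if (lesion$dt > ridge_dt - 0.6) {
      warning("lesion contrast approaches the fold ridge contrast; ",
              "the fold threshold may capture the lesion", call. = FALSE)
    }
  }
  structure(
    list(image_size = as.integer(image_size),
         background_t = background_t, body_t = body_t,
         torso_halfwidth = torso_halfwidth,
         top_row = top_row, bottom_row = bottom_row,
         armpit_row_right = armpit_row_right,
         armpit_row_left = armpit_row_left,
         arm_slope = arm_slope, taper = taper,
         breast_offset_x = breast_offset_x,
         fold_vertex_row = fold_vertex_row, fold_k = fold_k,
         fold_halfspan = fold_halfspan,
         ridge_dt = ridge_dt, ridge_sigma = ridge_sigma,
         breast_radius = breast_radius,
         lesion = lesion, noise_sd = noise_sd,
         fold_margin = fold_margin, seed = seed),
    class = "phantom_spec"
  )
}

# Half-width of the silhouette at each row for one side; NA outside the body.
silhouette_halfwidth <- function(spec, armpit_row) {
  y <- seq_len(spec$image_size[1L])
  hw <- rep(NA_real_, length(y))
  arms <- y >= spec$top_row & y < armpit_row
  torso <- y >= armpit_row & y <= spec$bottom_row
  hw[arms] <- spec$torso_halfwidth + spec$arm_slope * (armpit_row - y[arms])
  hw[torso] <- spec$torso_halfwidth + spec$taper * (y[torso] - armpit_row)
  hw
}

fold_poly_truth <- function(spec, xc) {
  k <- spec$fold_k
  structure(
    list(coef = c(a0 = spec$fold_vertex_row - k * xc^2, a1 = 2 * k * xc,
                  a2 = -k),
         rms = 0, n = NA_integer_),
    class = "polynomial2"
  )
}

#' Generate a synthetic thermogram with ground truth
#'
#' Renders the temperature field described by a [phantom_spec()], quantizes
#' it to an 8-bit thermogram using the rendered scene minimum/maximum as
#' the radiometric calibration (phantoms are self-calibrating), and returns
#' the ground truth every pipeline stage can be checked against.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: `thermogram`, the rendered noisy
#'   `thermal` matrix (degrees C), the `spec`, and `truth` — a list with
#'   `body_mask`, `right_breast_mask`, `left_breast_mask`, per-side
#'   `ridge_curves`, `armpit_points`, `split`, `fold_right`/`fold_left`
#'   truth polynomials, `lesion` (with resolved `center`), `lesion_mask`
#'   and `expected_verdict` (computed from the noiseless field over the
#'   truth masks, not assumed from lesion presence).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  R <- spec$image_size[1L]; C <- spec$image_size[2L]
  cx <- (C + 1) / 2
  X <- matrix(seq_len(C), R, C, byrow = TRUE)
  Y <- matrix(seq_len(R), R, C)

  hw_r <- silhouette_halfwidth(spec, spec$armpit_row_right)
  hw_l <- silhouette_halfwidth(spec, spec$armpit_row_left)
  xmin <- cx - hw_r; xmax <- cx + hw_l
  body <- !is.na(xmin[Y]) & X >= xmin[Y] & X <= xmax[Y]

  # truth geometry
  xc_r <- cx - spec$breast_offset_x
  xc_l <- cx + spec$breast_offset_x
  fold_r <- fold_poly_truth(spec, xc_r)
  fold_l <- fold_poly_truth(spec, xc_l)
  split <- intersect_folds(fold_r, fold_l, x_range = c(1, C), midline = cx)
  armpits <- structure(
    list(right = c(x = cx - spec$torso_halfwidth, y = spec$armpit_row_right),
         left = c(x = cx + spec$torso_halfwidth, y = spec$armpit_row_left),
         low_confidence = FALSE),
    class = "armpit_points"
  )
  seg_truth <- assemble_breast_masks(body, fold_r, fold_l, split, armpits,
                                     fold_margin = spec$fold_margin)

  # noiseless temperature field
  t0 <- matrix(spec$background_t, R, C)
  t0[body] <- spec$body_t

  lesion <- spec$lesion
  if (!is.null(lesion)) {
    side_mask <- if (lesion$side == "right") seg_truth$right_mask
                 else seg_truth$left_mask
    if (is.null(lesion$center)) {
      lesion$center <- c(x = mean(col(side_mask)[side_mask]),
                         y = mean(row(side_mask)[side_mask]))
    }
    ci <- as.integer(round(lesion$center))
    if (ci[1] < 1L || ci[1] > C || ci[2] < 1L || ci[2] > R ||
        !body[ci[2], ci[1]]) {
      stop_degenerate("lesion center lies outside the body")
    }
    d2 <- (X - lesion$center[["x"]])^2 + (Y - lesion$center[["y"]])^2
    sf <- lesion$radius / 2
    sb <- 1.3 * spec$breast_radius
    elev <- lesion$dt * pmax(exp(-d2 / (2 * sf^2)),
                             0.925 * exp(-d2 / (2 * sb^2)))
    on_side <- if (lesion$side == "right") X < split$x else X > split$x
    sel <- body & on_side
    t0[sel] <- t0[sel] + elev[sel]
  }

  # fold ridges: skin-contact temperature, same contrast on both sides,
  # composed with pmax so the fold stays the hottest structure
  ridge_curves <- list()
  for (side in c("right", "left")) {
    xc <- if (side == "right") xc_r else xc_l
    cols <- seq(max(1L, ceiling(xc - spec$fold_halfspan)),
                min(C, floor(xc + spec$fold_halfspan)))
    fold <- if (side == "right") fold_r else fold_l
    yf <- poly2_eval(fold, cols)
    ridge <- spec$ridge_dt *
      exp(-sweep(matrix(seq_len(R), R, length(cols)), 2, yf, "-")^2 /
            (2 * spec$ridge_sigma^2))
    sub <- body[, cols, drop = FALSE]
    blk <- t0[, cols, drop = FALSE]
    blk[sub] <- pmax(blk[sub], (spec$body_t + ridge)[sub])
    t0[, cols] <- blk
    ridge_curves[[side]] <- data.frame(x = cols, y = yf)
  }

  expected_verdict <- {
    d <- abs(mean(t0[seg_truth$left_mask]) - mean(t0[seg_truth$right_mask]))
    if (d >= 1.0) "problem_detected" else "no_problem"
  }

  t_noisy <- t0 + rnorm(R * C, sd = spec$noise_sd)

  tmin <- min(t_noisy); tmax <- max(t_noisy)
  gray <- matrix(as.integer(round((t_noisy - tmin) / (tmax - tmin) * 255)),
                 R, C)
  meta <- radiometric_meta(tmin, tmax)

  lesion_mask <- NULL
  if (!is.null(lesion)) {
    lesion_mask <- (X - lesion$center[["x"]])^2 +
      (Y - lesion$center[["y"]])^2 <= lesion$radius^2
  }

  structure(
    list(thermogram = thermogram(gray, meta),
         thermal = t_noisy,
         spec = spec,
         truth = list(body_mask = body,
                      right_breast_mask = seg_truth$right_mask,
                      left_breast_mask = seg_truth$left_mask,
                      ridge_curves = ridge_curves,
                      armpit_points = armpits,
                      split = split,
                      fold_right = fold_r, fold_left = fold_l,
                      lesion = lesion, lesion_mask = lesion_mask,
                      expected_verdict = expected_verdict)),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, %s, expected verdict: %s\n",
              nrow(x$thermal), ncol(x$thermal),
              if (is.null(x$truth$lesion)) "healthy"
              else sprintf("lesion dT=%.2f degC (%s breast)",
                           x$truth$lesion$dt, x$truth$lesion$side),
              x$truth$expected_verdict))
  invisible(x)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices of equal shape.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Monte-Carlo phantom sweep through the full pipeline
#'
#' Generates `n` randomized phantoms (geometry, skin temperature and noise
#' drawn uniformly from realistic ranges; a `lesion_fraction` share carry a
#' lesion with contrast drawn from `lesion_dt_range`), runs the complete
#' analysis pipeline on each, and tabulates the outcomes against ground
#' truth: the screening confusion table, per-side mask IoU, and — for
#' detected lesion cases — whether the watershed hotspot centroid fell
#' inside the true lesion disk.
#'
#' @param n number of phantoms (>= 1).
#' @param seed integer seed; each phantom `i` uses `seed + i`.
#' @param lesion_dt_range lesion contrast range, degrees C.
#' @param lesion_fraction share of phantoms carrying a lesion.
#' @param delta_t screening threshold passed to the pipeline.
#' @return an object of class `phantom_sweep`: per-case data frame `cases`
#'   (`truth`, `predicted`, `iou_right`, `iou_left`, `hotspot_hit`, ...),
#'   the [confusion_table()] and summary rates.
#' @export
phantom_sweep <- function(n, seed = 1L, lesion_dt_range = c(1.5, 3.0),
                          lesion_fraction = 0.5, delta_t = 1.0) {
  stopifnot(n >= 1)
  set.seed(seed)
  has_lesion <- seq_len(n) <= round(n * lesion_fraction)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    les <- NULL
    if (has_lesion[i]) {
      les <- list(side = sample(c("left", "right"), 1L),
                  dt = runif(1, lesion_dt_range[1], lesion_dt_range[2]),
                  radius = runif(1, 7, 12))
    }
    spec <- phantom_spec(
      torso_halfwidth = runif(1, 48, 62),
      arm_slope = runif(1, 1.0, 1.5),
      armpit_row_right = runif(1, 72, 90),
      armpit_row_left = runif(1, 72, 90),
      body_t = runif(1, 31.5, 33.5),
      breast_offset_x = runif(1, 38, 46),
      fold_vertex_row = runif(1, 165, 180),
      fold_k = runif(1, 0.016, 0.024),
      noise_sd = runif(1, 0.05, 0.15),
      lesion = les,
      seed = seed + i
    )
    ph <- generate_phantom(spec)
    rep_i <- analyze_thermogram(ph$thermogram, delta_t = delta_t)
    predicted <- switch(rep_i$status,
                        problem = "sick", no_problem = "healthy", "unknown")
    iou_r <- iou_l <- NA_real_
    hit <- NA
    if (!is.null(rep_i$segmentation)) {
      iou_r <- iou(rep_i$segmentation$right_mask, ph$truth$right_breast_mask)
      iou_l <- iou(rep_i$segmentation$left_mask, ph$truth$left_breast_mask)
    }
    if (has_lesion[i] && !is.null(rep_i$hotspot)) {
      ctr <- rep_i$hotspot$centroid
      lc <- ph$truth$lesion$center
      hit <- sqrt((ctr[["x"]] - lc[["x"]])^2 + (ctr[["y"]] - lc[["y"]])^2) <=
        ph$truth$lesion$radius
    }
    rows[[i]] <- data.frame(
      id = i,
      truth = if (has_lesion[i]) "sick" else "healthy",
      predicted = predicted,
      lesion_dt = if (has_lesion[i]) ph$truth$lesion$dt else NA_real_,
      diff_avg = if (!is.null(rep_i$evaluation)) rep_i$evaluation$diff_avg
                 else NA_real_,
      iou_right = iou_r, iou_left = iou_l,
      hotspot_hit = hit
    )
  }
  cases <- do.call(rbind, rows)
  cnt <- function(truth, pred) sum(cases$truth == truth & cases$predicted == pred)
  tab <- confusion_table(
    healthy = c(cnt("healthy", "healthy"), cnt("healthy", "sick"),
                cnt("healthy", "unknown")),
    sick = c(cnt("sick", "healthy"), cnt("sick", "sick"),
             cnt("sick", "unknown"))
  )
  segmented <- cases$predicted != "unknown"
  structure(
    list(cases = cases, table = tab, n = n,
         segmentation_success = mean(segmented),
         mean_iou = mean(c(cases$iou_right[segmented],
                           cases$iou_left[segmented])),
         hotspot_hit_rate = if (any(!is.na(cases$hotspot_hit)))
           mean(cases$hotspot_hit, na.rm = TRUE) else NA_real_),
    class = "phantom_sweep"
  )
}

#' @export
print.phantom_sweep <- function(x, ...) {
  cat(sprintf("<phantom_sweep> n=%d  segmentation success %.1f%%  mean IoU %.3f\n",
              x$n, 100 * x$segmentation_success, x$mean_iou))
  print(x$table)
  if (!is.na(x$hotspot_hit_rate)) {
    cat(sprintf("hotspot hit rate (detected lesion cases): %.1f%%\n",
                100 * x$hotspot_hit_rate))
  }
  invisible(x)
}
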