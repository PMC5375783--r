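mask_of <- function(body) {
  if (inherits(body, "body_mask")) body$mask
  else if (is.logical(body) && is.matrix(body)) body
  else stop_degenerate("expected a body_mask or logical matrix")
}

# Per-column topmost (minimum row) pixel of a logical matrix, as an (x, y)
# data frame ordered by column.
top_profile <- function(mask) {
  cols <- which(colSums(mask) > 0)
  y <- vapply(cols, function(j) which(mask[, j])[1L], integer(1))
  data.frame(x = cols, y = y)
}

# Split a connected component that spans the body midline into two halves.
# The two fold arcs curve upward toward the sternum, so when they merge the
# junction is the highest point (smallest row) of the top profile near the
# midline; we cut there, falling back to the midline column.
split_spanning_component <- function(comp_mask, midline) {
  prof <- top_profile(comp_mask)
  span <- diff(range(prof$x))
  near <- prof[abs(prof$x - midline) <= max(3, 0.15 * span), , drop = FALSE]
  cut_x <- if (nrow(near) > 0) near$x[which.min(near$y)] else round(midline)
  cols <- col(comp_mask)
  list(right = comp_mask & cols <= cut_x, left = comp_mask & cols > cut_x)
}

#' Detect inframammary fold candidates
#'
#' Under a resting acquisition protocol the crease below each breast is one
#' of the hottest skin regions. Thresholding the image at the highest gray
#' level found inside the body minus `offset` (default 10, found
#' heuristically) isolates a set of hot objects; the fold is the *thickest*
#' of them, ranked by the maximum of the Euclidean distance transform inside
#' each connected component (area breaks ties). One component is kept per
#' lateral half, and its per-column topmost pixels are the ridge points used
#' to fit the fold polynomials.
#'
#' @param x a [thermogram()].
#' @param body a [extract_body_mask()] result (or logical matrix).
#' @param offset gray levels subtracted from the within-body maximum.
#' @param smooth apply a 3 x 3 median filter before thresholding
#'   (default `TRUE`). The threshold is anchored at the *sample* gray
#'   maximum, which pixel noise inflates; without smoothing the
#'   supra-threshold band fragments into specks at realistic noise levels.
#'   A one-pixel morphological closing heals remaining single-pixel gaps in
#'   the band.
#' @return an object of class `fold_evidence`: ridge point data frames
#'   `right`/`left` (patient sides), the supra-threshold `hot_mask`, the
#'   `threshold` used and the body `midline` column.
#' @export
detect_fold_candidates <- function(x, body, offset = 10, smooth = TRUE) {
  g <- gray_of(x)
  bm <- mask_of(body)
  if (!identical(dim(g), dim(bm))) {
    stop_degenerate("body mask shape does not match the thermogram")
  }
  L <- levels_of(x)
  if (smooth) {
    g <- round(EBImage::medianFilter(g / (L - 1L), 1) * (L - 1L))
  }
  gmax <- max(g[bm])
  thr <- gmax - offset
  if (thr <= 0) {
    stop_segmentation("fold threshold is not positive: offset exceeds the image maximum")
  }
  hot <- bm & g >= thr
  if (!any(hot)) stop_segmentation("no pixels above the fold threshold")
  if (smooth) {
    k <- EBImage::makeBrush(3, "box")
    hot <- bm & (EBImage::erode(EBImage::dilate(hot * 1, k), k) > 0)
  }

  midline <- mean(col(bm)[bm])
  lab <- EBImage::bwlabel(hot * 1)
  dist <- EBImage::distmap(hot * 1)

  comps <- list()
  for (k in seq_len(max(lab))) {
    cm <- lab == k
    xs <- range(col(cm)[cm])
    if (xs[1] < midline - 5 && xs[2] > midline + 5) {
      halves <- split_spanning_component(cm, midline)
      if (any(halves$right)) comps[[length(comps) + 1L]] <- halves$right
      if (any(halves$left)) comps[[length(comps) + 1L]] <- halves$left
    } else {
      comps[[length(comps) + 1L]] <- cm
    }
  }

  pick_side <- function(side_right) {
    best <- NULL; best_key <- c(-Inf, -Inf)
    for (cm in comps) {
      cx <- mean(col(cm)[cm])
      on_side <- if (side_right) cx < midline else cx >= midline
      if (!on_side) next
      key <- c(max(dist[cm]), sum(cm))   # thickness first, area as tie-break
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- cm; best_key <- key
      }
    }
    best
  }
  right_cm <- pick_side(TRUE)
  left_cm <- pick_side(FALSE)
  if (is.null(right_cm) || is.null(left_cm)) {
    stop_segmentation("no fold candidate found on one lateral half")
  }
  structure(
    list(right = top_profile(right_cm), left = top_profile(left_cm),
         hot_mask = hot, threshold = thr, midline = midline),
    class = "fold_evidence"
  )
}

#' Fit a second-degree fold polynomial
#'
#' Least-squares fit of `y = a0 + a1 x + a2 x^2` to ridge points, completing
#' the partially detected crease below a breast.
#'
#' @param points data frame (or list) with columns `x`, `y` in pixels;
#'   at least three distinct `x` values.
#' @return an object of class `polynomial2`: coefficients `coef`
#'   (`a0`, `a1`, `a2`) and the residual RMS of the fit.
#' @examples
#' p <- fit_fold_polynomial(data.frame(x = 1:10, y = 1 + 2 * (1:10) + 3 * (1:10)^2))
#' p$coef
#' @export
fit_fold_polynomial <- function(points) {
  x <- points$x; y <- points$y
  if (length(x) < 3L || length(unique(x)) < 3L) {
    stop_degenerate("need at least 3 points with 3 distinct x to fit a quadratic")
  }
  fit <- lm(y ~ x + I(x^2))
  a <- unname(coef(fit))
  if (anyNA(a)) stop_degenerate("degenerate design: quadratic fit is singular")
  structure(
    list(coef = c(a0 = a[1], a1 = a[2], a2 = a[3]),
         rms = sqrt(mean(fit$residuals^2)), n = length(x)),
    class = "polynomial2"
  )
}

poly2_eval <- function(p, x) {
  a <- p$coef
  a[[1]] + a[[2]] * x + a[[3]] * x^2
}

#' @export
print.polynomial2 <- function(x, ...) {
  cat(sprintf("<polynomial2> y = %.4g + %.4g x + %.4g x^2  (rms %.2f px, n=%d)\n",
              x$coef[[1]], x$coef[[2]], x$coef[[3]], x$rms, x$n))
  invisible(x)
}

#' Intersection of the two fold polynomials
#'
#' The extended fold curves cross near the sternum; that crossing is the
#' control point at which the torso is split into left and right breast
#' regions. Among real roots of `p_right - p_left` inside `x_range` the one
#' nearest the midline is chosen. If there is none (or the polynomials
#' coincide) the split falls back to the midline at the mean fold height and
#' is flagged low-confidence.
#'
#' @param p_right,p_left `polynomial2` objects (patient right / left folds).
#' @param x_range numeric length-2 interval of admissible x (columns).
#' @param midline reference column; defaults to the middle of `x_range`.
#' @return list with continuous `x`, `y` and `low_confidence`.
#' @export
intersect_folds <- function(p_right, p_left, x_range, midline = mean(x_range)) {
  d <- p_right$coef - p_left$coef   # d0 + d1 x + d2 x^2 = 0
  roots <- numeric(0)
  if (abs(d[[3]]) > 1e-12) {
    disc <- d[[2]]^2 - 4 * d[[3]] * d[[1]]
    if (disc >= 0) {
      roots <- (-d[[2]] + c(-1, 1) * sqrt(disc)) / (2 * d[[3]])
    }
  } else if (abs(d[[2]]) > 1e-12) {
    roots <- -d[[1]] / d[[2]]
  }
  roots <- roots[roots >= min(x_range) & roots <= max(x_range)]
  if (length(roots) == 0L) {
    y <- mean(c(poly2_eval(p_right, midline), poly2_eval(p_left, midline)))
    return(list(x = midline, y = y, low_confidence = TRUE))
  }
  x0 <- roots[which.min(abs(roots - midline))]
  list(x = x0, y = poly2_eval(p_right, x0), low_confidence = FALSE)
}

# Lateral contour x(y) of the body silhouette from the morphological
# gradient (mask minus its erosion), one column per row, top to bottom.
lateral_contour <- function(mask, side_right, y_max) {
  grad <- mask & !(EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0)
  rows <- which(rowSums(grad) > 0)
  rows <- rows[rows <= y_max]
  if (length(rows) == 0L) stop_segmentation("no contour above the fold line")
  xs <- vapply(rows, function(i) {
    j <- which(grad[i, ])
    if (side_right) min(j) else max(j)
  }, integer(1))
  data.frame(x = xs, y = rows)
}

two_point_slopes <- function(xs, h) {
  n <- length(xs)
  i <- seq_len(n)
  lo <- pmax(1L, i - h)   # clamp to forward/backward differences at the ends
  hi <- pmin(n, i + h)
  (xs[hi] - xs[lo]) / (hi - lo)
}

#' Locate the armpit points on the body contour
#'
#' With the hands held at the nape, the silhouette has an abrupt slope
#' change where the arm contour meets the chest wall. The lateral contours
#' (from the morphological gradient of the body mask) are parameterized top
#' to bottom as x(y); the slope at each point is the central two-point
#' secant `(f(y + h) - f(y - h)) / (2h)` with `h` clamped near the ends, and
#' the armpit is the point with the largest absolute change between
#' successive slopes, searched strictly above `fold_y`.
#'
#' @param body a [extract_body_mask()] result or logical matrix.
#' @param fold_y row of the fold intersection; armpits must lie above it.
#' @param h secant half-step in pixels (default 10).
#' @return an object of class `armpit_points`: `right`/`left` points
#'   `c(x, y)` (patient sides), the per-side slope profiles, and a
#'   `low_confidence` flag set when no slope change stands out (straight
#'   contours).
#' @export
find_armpit_points <- function(body, fold_y, h = 10) {
  bm <- mask_of(body)
  one_side <- function(side_right) {
    ct <- lateral_contour(bm, side_right, ceiling(fold_y) - 1L)
    if (nrow(ct) < 2L * h + 1L) {
      stop_segmentation("lateral contour shorter than 2h + 1 pixels")
    }
    s <- two_point_slopes(ct$x, h)
    # slope-change gradient: the secant formula applied to the slope profile
    # peaks at the kink, whereas successive slope differences smear it into a
    # ~2h-wide plateau on pixelated contours
    score <- abs(two_point_slopes(s, h))
    k0 <- which.max(score)
    # centre of any residual tie plateau (pixel quantization)
    run <- k0
    while (run[1] > 1L && score[run[1] - 1L] >= 0.999 * score[k0]) {
      run <- c(run[1] - 1L, run)
    }
    while (run[length(run)] < length(score) &&
           score[run[length(run)] + 1L] >= 0.999 * score[k0]) {
      run <- c(run, run[length(run)] + 1L)
    }
    k <- run[ceiling(length(run) / 2)]
    list(point = c(x = ct$x[k], y = ct$y[k]), slopes = s,
         strength = max(score))
  }
  r <- one_side(TRUE)
  l <- one_side(FALSE)
  structure(
    list(right = r$point, left = l$point,
         slope_profile_right = r$slopes, slope_profile_left = l$slopes,
         low_confidence = max(r$strength, l$strength) < 1e-8),
    class = "armpit_points"
  )
}

# Continuous upper-boundary row at column x for one breast: the straight
# segment from the armpit point to the split point, extended horizontally
# lateral of the armpit.
upper_boundary <- function(xcol, armpit, split) {
  ax <- armpit[["x"]]; ay <- armpit[["y"]]
  if (abs(split$x - ax) < 1e-9) return(rep(ay, length(xcol)))
  slope <- (split$y - ay) / (split$x - ax)
  y <- ay + slope * (xcol - ax)
  # lateral of the armpit the boundary stays at the armpit height
  lateral <- if (split$x > ax) xcol < ax else xcol > ax
  y[lateral] <- ay
  y
}

#' Assemble the left and right breast masks
#'
#' The breast region on each side is bounded above by the straight segment
#' from the armpit point to the fold intersection, below by the fitted fold
#' polynomial minus `fold_margin` rows (excluding the hot skin-contact ridge
#' itself from the region), laterally by the body silhouette, and medially
#' by the vertical through the (continuous) split point: patient-right
#' pixels have column strictly less than `split$x`, patient-left strictly
#' greater.
#'
#' @param body a [extract_body_mask()] result or logical matrix.
#' @param fold_right,fold_left `polynomial2` fold fits (patient sides).
#' @param split fold intersection, list with `x`, `y` (from
#'   [intersect_folds()]).
#' @param armpits an [find_armpit_points()] result.
#' @param fold_margin rows excluded above the fold polynomial (default 8).
#' @return an object of class `breast_segmentation` with logical
#'   `right_mask`/`left_mask`, the geometric evidence, and any
#'   low-confidence flags carried through.
#' @export
assemble_breast_masks <- function(body, fold_right, fold_left, split, armpits,
                                  fold_margin = 8) {
  bm <- mask_of(body)
  sx <- as.integer(round(split$x)); sy <- as.integer(round(split$y))
  if (sx < 1L || sx > ncol(bm) || sy < 1L || sy > nrow(bm) || !bm[sy, sx]) {
    stop_segmentation("fold intersection point lies outside the body")
  }
  xs <- seq_len(ncol(bm))
  side_mask <- function(fold, armpit, is_right) {
    up <- upper_boundary(xs, armpit, split)
    lo <- poly2_eval(fold, xs) - fold_margin
    inside_x <- if (is_right) xs < split$x else xs > split$x
    yy <- row(bm); xxok <- matrix(inside_x, nrow(bm), ncol(bm), byrow = TRUE)
    upm <- matrix(up, nrow(bm), ncol(bm), byrow = TRUE)
    lom <- matrix(lo, nrow(bm), ncol(bm), byrow = TRUE)
    bm & xxok & yy >= upm & yy <= lom
  }
  right <- side_mask(fold_right, armpits$right, TRUE)
  left <- side_mask(fold_left, armpits$left, FALSE)
  if (!any(right) || !any(left)) {
    stop_segmentation("breast mask empty on one side")
  }
  structure(
    list(right_mask = right, left_mask = left,
         fold_right = fold_right, fold_left = fold_left,
         split = split, armpits = armpits, fold_margin = fold_margin),
    class = "breast_segmentation"
  )
}

#' @export
print.breast_segmentation <- function(x, ...) {
  cat(sprintf(
    "<breast_segmentation> right %d px | left %d px, split at (%.1f, %.1f)%s\n",
    sum(x$right_mask), sum(x$left_mask), x$split$x, x$split$y,
    if (isTRUE(x$split$low_confidence) || isTRUE(x$armpits$low_confidence))
      " [low confidence]" else ""))
  invisible(x)
}

#' Fully automatic breast segmentation
#'
#' Runs the complete geometric chain on a thermogram: fold-candidate
#' detection, per-side quadratic fits, fold intersection, armpit detection
#' and mask assembly.
#'
#' @param x a [thermogram()].
#' @param body optional precomputed [extract_body_mask()]; computed if
#'   missing.
#' @param offset fold threshold offset in gray levels (default 10).
#' @param h armpit secant half-step in pixels (default 10).
#' @param fold_margin rows excluded above the fold polynomial (default 8).
#' @param ... passed to [extract_body_mask()] when `body` is missing.
#' @return a `breast_segmentation` (see [assemble_breast_masks()]) with the
#'   `fold_evidence` attached as `$evidence` and the body mask as `$body`.
#' @export
segment_breasts <- function(x, body = NULL, offset = 10, h = 10,
                            fold_margin = 8, ...) {
  if (is.null(body)) body <- extract_body_mask(x, ...)
  ev <- detect_fold_candidates(x, body, offset = offset)
  fr <- fit_fold_polynomial(ev$right)
  fl <- fit_fold_polynomial(ev$left)
  xr <- range(c(ev$right$x, ev$left$x))
  split <- intersect_folds(fr, fl, x_range = xr, midline = ev$midline)
  ap <- find_armpit_points(body, fold_y = split$y, h = h)
  seg <- assemble_breast_masks(body, fr, fl, split, ap,
                               fold_margin = fold_margin)
  seg$evidence <- ev
  seg$body <- body
  seg
}
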