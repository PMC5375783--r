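gray_of <- function(x) {
  if (inherits(x, "thermogram")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_degenerate("expected a thermogram or a numeric matrix")
}

levels_of <- function(x) if (inherits(x, "thermogram")) x$levels else 256L

#' Otsu threshold of a thermogram
#'
#' Exhaustively maximizes the between-class variance
#' `sigmaB^2(t) = w1 (mu1 - muT)^2 + w2 (mu2 - muT)^2` over all gray
#' thresholds `t`, where class 1 is `gray <= t` and class 2 is `gray > t`,
#' `w` are class probabilities and `mu` class means. `sigmaB^2` is defined
#' as 0 whenever a class is empty; ties are broken toward the lowest `t`.
#'
#' @param x a [thermogram()] or gray-intensity matrix.
#' @return an object of class `otsu_result`: `threshold`, `criterion`
#'   (sigmaB^2 for t = 0..L-1), `class_probs`, `class_means` and
#'   `global_mean` at the selected threshold.
#' @examples
#' g <- matrix(c(10L, 10L, 10L, 200L), 2, 2)
#' otsu_threshold(thermogram(g, radiometric_meta(24, 36)))
#' @export
otsu_threshold <- function(x) {
  g <- gray_of(x)
  L <- levels_of(x)
  if (length(unique(as.vector(g))) < 2L) {
    stop_degenerate("constant image: Otsu threshold is undefined")
  }
  h <- tabulate(as.vector(g) + 1L, nbins = L)
  p <- h / sum(h)
  lev <- 0:(L - 1L)
  mu_t <- sum(lev * p)
  w1 <- cumsum(p)                # P(gray <= t)
  m1 <- cumsum(lev * p)          # unnormalized class-1 mean
  w2 <- 1 - w1
  mu1 <- ifelse(w1 > 0, m1 / w1, 0)
  mu2 <- ifelse(w2 > 0, (mu_t - m1) / w2, 0)
  crit <- w1 * (mu1 - mu_t)^2 + w2 * (mu2 - mu_t)^2
  crit[w1 == 0 | w2 == 0] <- 0
  t_star <- which.max(crit) - 1L   # lowest maximizer
  structure(
    list(threshold = t_star,
         criterion = crit,
         class_probs = c(w1 = w1[t_star + 1L], w2 = w2[t_star + 1L]),
         class_means = c(mu1 = mu1[t_star + 1L], mu2 = mu2[t_star + 1L]),
         global_mean = mu_t),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "<otsu_result> t* = %d  (w1=%.3f, w2=%.3f, mu1=%.2f, mu2=%.2f, muT=%.2f)\n",
    x$threshold, x$class_probs[["w1"]], x$class_probs[["w2"]],
    x$class_means[["mu1"]], x$class_means[["mu2"]], x$global_mean))
  invisible(x)
}

#' Hamadani's global threshold
#'
#' The alternative global threshold `k1 * muT + k2 * sigmaT` built from the
#' global mean and standard deviation of the gray levels (population SD).
#' With `k1 = k2 = 1` this is the variant usually compared against Otsu for
#' thermogram background removal.
#'
#' @param x a [thermogram()] or gray matrix.
#' @param k1,k2 weights of the mean and SD terms.
#' @return the (possibly fractional) threshold gray level.
#' @export
hamadani_threshold <- function(x, k1 = 1, k2 = 1) {
  g <- as.vector(gray_of(x))
  if (length(unique(g)) < 2L) {
    stop_degenerate("constant image: Hamadani threshold is undefined")
  }
  k1 * mean(g) + k2 * sqrt(mean((g - mean(g))^2))
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Separate the patient from the background
#'
#' Removes the temperature scale bar (if its position is known), applies the
#' Otsu threshold, keeps pixels *brighter* than the threshold (in a
#' hot-bright palette the body is the warm, bright class), retains the
#' largest connected component and fills its holes, yielding a
#' simply-connected body silhouette.
#'
#' @param x a [thermogram()].
#' @param scale_bar optional rectangle `c(x0, y0, x1, y1)` (columns/rows,
#'   inclusive) zeroed before thresholding, e.g. the palette indicator the
#'   camera burns into a fixed image corner.
#' @param invert set `TRUE` for inverted palettes (hot = dark).
#' @return an object of class `body_mask`: logical `mask`, the `otsu` result
#'   and the `scale_bar` used.
#' @export
extract_body_mask <- function(x, scale_bar = NULL, invert = FALSE) {
  stopifnot(inherits(x, "thermogram"))
  g <- x$pixels
  if (invert) g <- (x$levels - 1L) - g
  if (!is.null(scale_bar)) {
    sb <- as.integer(round(scale_bar))
    if (length(sb) != 4L) stop_degenerate("`scale_bar` must be c(x0, y0, x1, y1)")
    cols <- max(1L, sb[1L]):min(ncol(g), sb[3L])
    rows <- max(1L, sb[2L]):min(nrow(g), sb[4L])
    g[rows, cols] <- 0L
  }
  ot <- otsu_threshold(thermogram(g, x$meta, x$levels))
  fg <- g > ot$threshold
  frac <- mean(fg)
  if (!any(fg) || frac > 0.95) {
    stop_segmentation(sprintf(
      "body/background separation failed (foreground fraction %.2f)", frac))
  }
  mask <- largest_component(fg)
  mask <- EBImage::fillHull(mask * 1) > 0
  structure(list(mask = mask, otsu = ot, scale_bar = scale_bar,
                 invert = invert),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %d x %d px, %d body pixels (t* = %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$otsu$threshold))
  invisible(x)
}
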