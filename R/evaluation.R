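#' Bilateral asymmetry verdict from per-side statistics
#'
#' Applies the screening rule: a left/right difference in *average* breast
#' temperature of at least `delta_t` (1 degree C by default) flags a possible
#' tumor or angiogenesis; smaller differences are reported as normal. Max,
#' min and SD differences are reported alongside but never drive the
#' verdict.
#'
#' @param left,right [region_stats()] objects (or lists with `avg`, `max`,
#'   `min`, `sd`) for the patient's left and right breast.
#' @param delta_t decision threshold in degrees C; the rule is
#'   `|avg_left - avg_right| >= delta_t` (the boundary case is positive).
#' @return an object of class `evaluation_result`: the two stats, all
#'   absolute differences, `verdict` (`"no_problem"` or
#'   `"problem_detected"`) and `hotter_side` (`"left"`, `"right"` or
#'   `"none"`).
#' @examples
#' l <- list(avg = 26.43, max = 35.56, min = 24.04, sd = 3.34)
#' r <- list(avg = 25.70, max = 36.50, min = 24.04, sd = 3.61)
#' evaluate_asymmetry(l, r)
#' @export
evaluate_asymmetry <- function(left, right, delta_t = 1.0) {
  for (s in list(left, right)) {
    if (!all(c("avg", "max", "min", "sd") %in% names(s))) {
      stop_degenerate("side statistics need fields avg, max, min, sd")
    }
  }
  diff_avg <- abs(left$avg - right$avg)
  problem <- diff_avg >= delta_t
  structure(
    list(left = left, right = right,
         diff_avg = diff_avg,
         diff_max = abs(left$max - right$max),
         diff_min = abs(left$min - right$min),
         diff_sd = abs(left$sd - right$sd),
         verdict = if (problem) "problem_detected" else "no_problem",
         hotter_side = if (!problem) "none"
                       else if (left$avg > right$avg) "left" else "right",
         delta_t = delta_t),
    class = "evaluation_result"
  )
}

#' Evaluate a segmented thermogram
#'
#' Computes per-side temperature statistics over the segmentation masks and
#' applies the asymmetry rule.
#'
#' @param thermal a `thermal_matrix` (see [to_thermal()]).
#' @param seg a `breast_segmentation`.
#' @inheritParams evaluate_asymmetry
#' @return an `evaluation_result`.
#' @export
evaluate_sides <- function(thermal, seg, delta_t = 1.0) {
  stopifnot(inherits(seg, "breast_segmentation"))
  evaluate_asymmetry(region_stats(thermal, seg$left_mask),
                     region_stats(thermal, seg$right_mask),
                     delta_t = delta_t)
}

#' Per-side statistics as a report table
#'
#' @param x an `evaluation_result`.
#' @param digits decimals for the printed degrees C (default 2).
#' @return data frame with rows Average/Max/Min/SD and columns
#'   Left/Right/Difference, in degrees C.
#' @export
as_stats_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "evaluation_result"))
  rnd <- function(v) round(v, digits)
  data.frame(
    Temperature = c("Average", "Max", "Min", "SD"),
    Left = rnd(c(x$left$avg, x$left$max, x$left$min, x$left$sd)),
    Right = rnd(c(x$right$avg, x$right$max, x$right$min, x$right$sd)),
    Difference = rnd(c(x$diff_avg, x$diff_max, x$diff_min, x$diff_sd))
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>\n")
  print(as_stats_table(x), row.names = FALSE)
  msg <- if (x$verdict == "problem_detected") "problem detected" else "no problem detected"
  cat(sprintf("verdict: %s (|dT| = %.2f degC, threshold %.2f)%s\n",
              msg, x$diff_avg, x$delta_t,
              if (x$hotter_side != "none")
                sprintf(", hotter side: %s", x$hotter_side) else ""))
  invisible(x)
}

#' Write the per-side statistics table as CSV
#'
#' @param x an `evaluation_result`.
#' @param path output CSV path.
#' @inheritParams as_stats_table
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(x, path, digits = 2) {
  write.csv(as_stats_table(x, digits), path, row.names = FALSE)
  invisible(path)
}
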