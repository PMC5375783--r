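#' Screening confusion table
#'
#' Bookkeeping for a screening study where each case with a known true
#' class (healthy or sick) is classified healthy, sick, or left unresolved
#' ("unknown") when the automatic segmentation fails.
#'
#' @param healthy counts for true-healthy cases: classified
#'   `c(healthy, sick, unknown)`.
#' @param sick counts for true-sick cases, same order.
#' @return an object of class `confusion_table` (a 2 x 3 integer matrix).
#' @examples
#' confusion_table(healthy = c(17, 4, 16), sick = c(5, 18, 19))
#' @export
confusion_table <- function(healthy, sick) {
  stopifnot(length(healthy) == 3L, length(sick) == 3L)
  m <- rbind(healthy = as.numeric(healthy), sick = as.numeric(sick))
  colnames(m) <- c("healthy", "sick", "unknown")
  if (any(m < 0) || anyNA(m)) stop_degenerate("counts must be non-negative")
  structure(m, class = c("confusion_table", class(m)))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>  (rows: true class, cols: classified)\n")
  print(unclass(x))
  invisible(x)
}

trunc4 <- function(x) trunc(x * 1e4) / 1e4

#' Screening metrics from a confusion table
#'
#' Sensitivity (TPR), FPR, FNR and specificity computed over *resolved*
#' cases only: unknowns — cases the segmentation could not process — are
#' excluded from every rate denominator and reported separately as the
#' unknown rate over all cases. `per_class_match` is the per-class share of
#' correct classifications among resolved cases and `mean_match` their
#' unweighted mean.
#'
#' Full-precision rates are returned together with a `$rounded` list
#' truncated (not rounded) to 4 decimals, the precision screening studies
#' conventionally print; `rounded$mean_match` is the mean of the truncated
#' per-class matches. The identities `tpr + fnr = 1` and
#' `fpr + specificity = 1` hold exactly on the full-precision values.
#'
#' @param table a [confusion_table()].
#' @return an object of class `screening_metrics`.
#' @examples
#' screening_metrics(confusion_table(c(17, 4, 16), c(5, 18, 19)))
#' @export
screening_metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  res_h <- table["healthy", "healthy"] + table["healthy", "sick"]
  res_s <- table["sick", "healthy"] + table["sick", "sick"]
  if (res_h == 0 || res_s == 0) {
    stop_degenerate("no resolved cases in one class: rates are undefined")
  }
  tpr <- table["sick", "sick"] / res_s
  fpr <- table["healthy", "sick"] / res_h
  match_h <- table["healthy", "healthy"] / res_h
  match_s <- table["sick", "sick"] / res_s
  out <- list(
    tpr = tpr, fnr = 1 - tpr,
    fpr = fpr, specificity = 1 - fpr,
    per_class_match = c(healthy = match_h, sick = match_s),
    mean_match = (match_h + match_s) / 2,
    unknown_rate = sum(table[, "unknown"]) / sum(table),
    table = table
  )
  out$rounded <- list(
    tpr = trunc4(tpr), fnr = trunc4(1 - tpr),
    fpr = trunc4(fpr), specificity = trunc4(1 - fpr),
    per_class_match = trunc4(c(healthy = match_h, sick = match_s)),
    mean_match = mean(trunc4(c(match_h, match_s))),
    unknown_rate = trunc4(out$unknown_rate)
  )
  structure(out, class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  r <- x$rounded
  cat("<screening_metrics> (rates over resolved cases, 4 decimals truncated)\n")
  cat(sprintf("  sensitivity (TPR) %.4f   FNR %.4f\n", r$tpr, r$fnr))
  cat(sprintf("  specificity       %.4f   FPR %.4f\n", r$specificity, r$fpr))
  cat(sprintf("  per-class match: healthy %.4f, sick %.4f (mean %.5f)\n",
              r$per_class_match[["healthy"]], r$per_class_match[["sick"]],
              r$mean_match))
  cat(sprintf("  unknown rate: %.1f%% of all cases\n", 100 * x$unknown_rate))
  invisible(x)
}
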