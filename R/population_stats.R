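# Ratiometric biosensor readouts and cell-size population statistics:
# per-timepoint median + interquartile range, window mean-of-medians,
# excess-control normalization.

#' Ratiometric QUEEN-2m (ATP) readout
#'
#' The ATP level reported by the QUEEN-2m biosensor is the ratio of the
#' uvGFP to the GFP channel; a higher ratio indicates a higher ATP
#' level.  Records with a missing or non-positive channel yield `NA`
#' (skipped by all downstream summaries); a message counts skipped
#' records with invalid (non-positive) intensities.
#'
#' @param gray_uvgfp,gray_gfp Background-corrected mean gray values.
#' @return Numeric vector of ratios.
#' @export
queen_ratio <- function(gray_uvgfp, gray_gfp) {
  ratio_channels(gray_uvgfp, gray_gfp, "queen_ratio")
}

#' Ratiometric GlyRNA (glycolytic flux) readout
#'
#' The fructose-1,6-bisphosphate level reported by the GlyRNA biosensor
#' is the ratio of the CFP to the RFP channel; a *lower* ratio indicates
#' a *higher* glycolytic flux.
#'
#' @param gray_cfp,gray_rfp Background-corrected mean gray values.
#' @return Numeric vector of ratios.
#' @export
glyrna_ratio <- function(gray_cfp, gray_rfp) {
  ratio_channels(gray_cfp, gray_rfp, "glyrna_ratio")
}

ratio_channels <- function(num, den, what) {
  stopifnot(length(num) == length(den))
  bad <- (!is.na(num) & num <= 0) | (!is.na(den) & den <= 0)
  if (any(bad))
    message(sprintf("%s: skipped %d record(s) with non-positive intensities",
                    what, sum(bad)))
  out <- num / den
  out[bad | is.na(num) | is.na(den)] <- NA_real_
  out
}

#' Median and interquartile range of a population sample
#'
#' @param values Numeric values of all observed cells of one condition
#'   at one timepoint (`NA`s dropped).
#' @return A list `median`, `q25`, `q75`, `n` (percentiles by linear
#'   interpolation between order statistics, `stats::quantile` type 7).
#' @export
timepoint_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values at this timepoint", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Mean of the per-timepoint medians inside a fixed window
#'
#' One plotted data point of a condition: the arithmetic mean of the
#' per-timepoint medians (and of the quartiles) across all timepoints in
#' the closed window, by default 10-18 h of cultivation (6 h after the
#' onset of the dynamics).
#'
#' @param per_timepoint Data frame with columns `time_h`, `median`,
#'   `q25`, `q75` (and optionally `n`).
#' @param window `c(start, end)` in hours, both ends included.
#' @return A list `window_mean_median`, `window_mean_iqr` (length-2),
#'   `n_timepoints`.
#' @export
window_mean_of_medians <- function(per_timepoint, window = c(10, 18)) {
  stopifnot(is.data.frame(per_timepoint),
            all(c("time_h", "median", "q25", "q75") %in%
                  names(per_timepoint)))
  sel <- per_timepoint$time_h >= window[1] - 1e-9 &
    per_timepoint$time_h <= window[2] + 1e-9
  if (!any(sel))
    stop(sprintf("no timepoints inside window [%g, %g] h",
                 window[1], window[2]), call. = FALSE)
  list(window_mean_median = mean(per_timepoint$median[sel]),
       window_mean_iqr = c(mean(per_timepoint$q25[sel]),
                           mean(per_timepoint$q75[sel])),
       n_timepoints = sum(sel))
}

#' Population summary of a biosensor ratio or the cell size
#'
#' Computes the per-timepoint median + IQR(25-75) of a metric over all
#' pooled cells of a condition, and the window mean of those medians.
#' Biosensor ratios use only fluorescence frames (rows where the
#' required channels are present); cell size uses every phase-contrast
#' frame.
#'
#' @param table A pooled `cell_table`.
#' @param metric `"queen_ratio"`, `"glyrna_ratio"` or `"area_um2"`.
#' @param window Fixed evaluation window in hours (default `c(10, 18)`).
#' @return An object of class `pop_summary`: `metric`, `per_timepoint`
#'   (data frame `time_h`, `median`, `q25`, `q75`, `n`), `window`,
#'   `window_mean_median`, `window_mean_iqr`, and `normalized = NA`
#'   until [normalize_summary()] is applied.
#' @export
pop_summary <- function(table, metric = c("queen_ratio", "glyrna_ratio",
                                          "area_um2"),
                        window = c(10, 18)) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  vals <- switch(metric,
    queen_ratio = queen_ratio(table$gray_uvgfp, table$gray_gfp),
    glyrna_ratio = glyrna_ratio(table$gray_cfp, table$gray_rfp),
    area_um2 = table$area_um2)
  keep <- !is.na(vals)
  if (!any(keep))
    stop(sprintf("no usable records for metric '%s'", metric), call. = FALSE)
  sp <- split(vals[keep], table$time_h[keep])
  per <- do.call(rbind, lapply(names(sp), function(tm) {
    s <- timepoint_summary(sp[[tm]])
    data.frame(time_h = as.numeric(tm), median = s$median, q25 = s$q25,
               q75 = s$q75, n = s$n)
  }))
  per <- per[order(per$time_h), , drop = FALSE]
  rownames(per) <- NULL
  wm <- window_mean_of_medians(per, window)
  structure(
    list(metric = metric, per_timepoint = per, window = window,
         window_mean_median = wm$window_mean_median,
         window_mean_iqr = wm$window_mean_iqr,
         n_timepoints = wm$n_timepoints, normalized = NA_real_,
         normalized_iqr = c(NA_real_, NA_real_)),
    class = "pop_summary")
}

#' Cell-size population summary
#'
#' [pop_summary()] applied to the cell area at phase-contrast cadence.
#'
#' @inheritParams pop_summary
#' @return A `pop_summary` for `area_um2`.
#' @export
size_summary <- function(table, window = c(10, 18)) {
  pop_summary(table, "area_um2", window)
}

#' Normalize a population summary to the excess control
#'
#' Divides the window mean-of-medians (and mean IQR) by those of the
#' constant-excess control of the same experiment and window; the
#' control normalizes to exactly 1.
#'
#' @param summary,control `pop_summary` objects of the same metric.
#' @return `summary` with `normalized` and `normalized_iqr` filled in.
#' @export
normalize_summary <- function(summary, control) {
  stopifnot(inherits(summary, "pop_summary"), inherits(control, "pop_summary"))
  if (!identical(summary$metric, control$metric))
    stop(sprintf("metric mismatch: '%s' vs control '%s'", summary$metric,
                 control$metric), call. = FALSE)
  if (!is.finite(control$window_mean_median) ||
      control$window_mean_median <= 0)
    stop("control window mean must be positive", call. = FALSE)
  summary$normalized <- summary$window_mean_median / control$window_mean_median
  summary$normalized_iqr <- summary$window_mean_iqr /
    control$window_mean_median
  summary
}

#' @export
print.pop_summary <- function(x, ...) {
  cat(sprintf(
    "<pop_summary> %s: window [%g, %g] h mean-of-medians %.4f (IQR %.4f-%.4f, %d timepoints)%s\n",
    x$metric, x$window[1], x$window[2], x$window_mean_median,
    x$window_mean_iqr[1], x$window_mean_iqr[2], x$n_timepoints,
    if (is.na(x$normalized)) "" else sprintf(", normalized %.4f",
                                             x$normalized)))
  invisible(x)
}
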