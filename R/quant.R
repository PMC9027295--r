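#' Background-subtracted area under a chromatogram range
#'
#' Trapezoidal integral of intensity over `[rt_start, rt_end]`, with the
#' endpoint intensities obtained by linear interpolation so integration
#' ranges need not coincide with sampling points. `background = "linear"`
#' subtracts the trapezoid under the straight line joining the interpolated
#' endpoint intensities (the standard chromatographic drop-line baseline);
#' `"none"` subtracts nothing. The integration range is clipped to the
#' acquired span; an empty intersection is an error.
#'
#' @param times,intensities the chromatogram
#' @param rt_start,rt_end integration range in minutes (defaults: the whole
#'   chromatogram)
#' @param background `"none"` (default) or `"linear"`
#' @return area in intensity x minutes
#' @examples
#' integrate_range(c(0, 1, 2), c(0, 100, 0))              # 100
#' integrate_range(c(0, 1, 2), c(10, 10, 10), background = "linear")  # 0
#' @export
integrate_range <- function(times, intensities, rt_start = NULL, rt_end = NULL,
                            background = c("none", "linear")) {
  background <- match.arg(background)
  validate_chromatogram(times, intensities)
  if (length(times) < 2L) return(0)
  if (is.null(rt_start)) rt_start <- times[1L]
  if (is.null(rt_end)) rt_end <- times[length(times)]
  stopifnot(rt_start < rt_end)
  lo <- max(rt_start, times[1L])
  hi <- min(rt_end, times[length(times)])
  if (lo >= hi) {
    stop("integration range [", rt_start, ", ", rt_end,
         "] does not intersect the acquired span", call. = FALSE)
  }
  inside <- times > lo & times < hi
  tt <- c(lo, times[inside], hi)
  yy <- c(stats::approx(times, intensities, lo)$y,
          intensities[inside],
          stats::approx(times, intensities, hi)$y)
  auc <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  if (background == "linear") {
    auc <- auc - (hi - lo) * (yy[1L] + yy[length(yy)]) / 2
  }
  auc
}

#' Before/after deisotoping AUC report
#'
#' For every channel: the AUC before and after correction, averaged
#' (arithmetic mean) across runs, and the percentage of signal remaining,
#' `100 * after / before`. The integration range is the matching target's
#' range when a targets table is given, otherwise the entire chromatogram.
#' Channels whose mean before-AUC is not positive are excluded from the
#' report body and counted in the `excluded` attribute (percent remaining is
#' undefined there).
#'
#' @param before,after [mrm_dataset()] objects sharing runs and channel ids
#'   (e.g. the input and output of [deisotope_dataset()])
#' @param targets optional targets data.frame ([read_targets()]); channels
#'   without a matching target use the full-trace default
#' @param background background model passed to [integrate_range()]
#'   (default `"none"`)
#' @return data.frame `channel_id, target, mean_auc_before, mean_auc_after,
#'   percent_remaining`, with attribute `excluded` (count of channels with
#'   nonpositive before-AUC)
#' @export
deisotoping_report <- function(before, after, targets = NULL,
                               background = "none") {
  stopifnot(inherits(before, "mrm_dataset"), inherits(after, "mrm_dataset"))
  if (!identical(sort(names(before$runs)), sort(names(after$runs)))) {
    stop("before/after datasets do not share run ids", call. = FALSE)
  }
  target_for <- function(id) {
    if (is.null(targets) || !nrow(targets)) return(NULL)
    tid <- channel_id(targets$q1, targets$q3, targets$polarity, targets$ce)
    hit <- which(tid == id)
    if (length(hit)) targets[hit[1L], ] else NULL
  }
  ids <- names(dataset_channel_index(before))
  rows <- list(); excluded <- 0L
  for (id in ids) {
    tg <- target_for(id)
    auc_in <- function(ds) {
      vals <- numeric(0)
      for (run in ds$runs) {
        ch <- run$channels[[id]]
        if (is.null(ch) || length(ch$times) < 2L) next
        vals <- c(vals, integrate_range(
          ch$times, ch$intensities,
          rt_start = if (is.null(tg)) NULL else tg$rt_start_min,
          rt_end = if (is.null(tg)) NULL else tg$rt_end_min,
          background = background))
      }
      vals
    }
    b <- auc_in(before); a <- auc_in(after)
    if (!length(b)) next
    if (length(b) != length(a)) {
      stop("channel ", id, " present in different run subsets before/after",
           call. = FALSE)
    }
    mb <- mean(b); ma <- mean(a)
    if (mb <= 0) { excluded <- excluded + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      channel_id = id,
      target = if (is.null(tg)) NA_character_ else tg$name,
      mean_auc_before = mb, mean_auc_after = ma,
      percent_remaining = 100 * ma / mb, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel_id = character(0), target = character(0),
               mean_auc_before = numeric(0), mean_auc_after = numeric(0),
               percent_remaining = numeric(0))
  attr(out, "excluded") <- excluded
  out
}
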