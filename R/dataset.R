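#' MRM channel constructor
#'
#' A channel is one MRM transition (Q1/Q3 m/z, polarity, collision energy)
#' together with its chromatogram: paired vectors of retention times
#' (minutes, strictly increasing) and intensities (arbitrary units, finite;
#' negatives are permitted after subtraction).
#'
#' The channel id is a deterministic key derived from the transition with
#' Q1/Q3 rounded to 4 decimals and CE to 1 decimal, absorbing trailing-digit
#' jitter in instrument exports while staying injective for genuinely
#' different transitions.
#'
#' @param q1,q3 precursor and product m/z in Da (> 0)
#' @param polarity `"Positive"` or `"Negative"`
#' @param ce collision energy in volts (0 when unknown)
#' @param times retention times in minutes, strictly increasing
#' @param intensities intensities, same length as `times`
#' @return an object of class `mrm_channel`
#' @export
mrm_channel <- function(q1, q3, polarity, ce = 0, times = numeric(0),
                        intensities = numeric(0)) {
  polarity <- match.arg(polarity, c("Positive", "Negative"))
  stopifnot(q1 > 0, q3 > 0, ce >= 0)
  validate_chromatogram(times, intensities)
  structure(list(id = channel_id(q1, q3, polarity, ce),
                 q1 = as.numeric(q1), q3 = as.numeric(q3),
                 polarity = polarity, ce = as.numeric(ce),
                 times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "mrm_channel")
}

validate_chromatogram <- function(times, intensities) {
  if (length(times) != length(intensities)) {
    stop("times and intensities differ in length", call. = FALSE)
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop("chromatogram times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(intensities))) {
    stop("chromatogram values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Deterministic channel id for a transition
#' @param q1,q3 m/z values; `polarity` `"Positive"`/`"Negative"`; `ce` volts
#' @return string key, e.g. `"(+)758.6000>184.0700@33.0V"`
#' @export
channel_id <- function(q1, q3, polarity, ce = 0) {
  sgn <- ifelse(polarity == "Positive", "+", "-")
  sprintf("(%s)%.4f>%.4f@%.1fV", sgn, q1, q3, ce)
}

#' Human-readable transition label
#'
#' The display form used in channel lists and search, e.g.
#' `"(+)760.6 > 184.05@33V"`.
#' @param channel an `mrm_channel`
#' @return string
#' @export
format_transition <- function(channel) {
  sgn <- if (channel$polarity == "Positive") "+" else "-"
  num <- function(x) formatC(x, format = "fg", digits = 15)
  sprintf("(%s)%s > %s@%sV", sgn, num(channel$q1), num(channel$q3),
          num(channel$ce))
}

#' @export
print.mrm_channel <- function(x, ...) {
  cat("<mrm_channel> ", x$id, "  [", length(x$times), " points]\n", sep = "")
  invisible(x)
}

#' One acquisition run: a set of MRM channels
#' @param run_id string identifying the run (e.g. file stem)
#' @param channels list of [mrm_channel()] objects, ids unique within the run
#' @return an object of class `mrm_run`
#' @export
mrm_run <- function(run_id, channels) {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  stopifnot(all(vapply(channels, inherits, logical(1), "mrm_channel")))
  ids <- vapply(channels, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate channel ids in run '", run_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(channels) <- ids
  structure(list(run_id = run_id, channels = channels), class = "mrm_run")
}

#' @export
print.mrm_run <- function(x, ...) {
  cat("<mrm_run> ", x$run_id, ": ", length(x$channels), " channels\n", sep = "")
  invisible(x)
}

#' A dataset: one or more runs sharing a transition schema
#' @param runs list of [mrm_run()] objects (nonempty)
#' @return an object of class `mrm_dataset`
#' @export
mrm_dataset <- function(runs) {
  if (inherits(runs, "mrm_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "mrm_run")))
  names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  if (anyDuplicated(names(runs))) stop("duplicate run ids", call. = FALSE)
  structure(list(runs = runs), class = "mrm_dataset")
}

#' @export
print.mrm_dataset <- function(x, ...) {
  cat("<mrm_dataset> ", length(x$runs), " run(s): ",
      paste(names(x$runs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Resample a chromatogram onto another time grid
#'
#' Linear interpolation at the target times; zero outside the source's
#' acquired span. Needed because scheduled-MRM channels are measured on
#' channel-specific time grids, so source and affected chromatograms rarely
#' share sampling points.
#'
#' @param times,intensities source chromatogram (>= 2 points)
#' @param target_times times (minutes) at which to evaluate
#' @return numeric vector of interpolated intensities at `target_times`
#' @export
resample_onto <- function(times, intensities, target_times) {
  if (length(times) < 2L) {
    stop("resampling requires a source chromatogram with >= 2 points",
         call. = FALSE)
  }
  out <- stats::approx(times, intensities, xout = target_times,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Clip a chromatogram at a detector saturation ceiling
#' @param intensities intensity vector
#' @param limit positive ceiling (arbitrary units)
#' @return pointwise `min(intensities, limit)`
#' @export
clip_saturation <- function(intensities, limit) {
  stopifnot(length(limit) == 1L, limit > 0)
  pmin(intensities, limit)
}

# apply a function(channel) -> channel over all channels of all runs
map_channels <- function(dataset, fn) {
  dataset$runs <- lapply(dataset$runs, function(run) {
    run$channels <- lapply(run$channels, fn)
    run
  })
  dataset
}

# all distinct channels across runs (first occurrence wins), as a list
dataset_channel_index <- function(dataset) {
  out <- list()
  for (run in dataset$runs) {
    for (ch in run$channels) if (is.null(out[[ch$id]])) out[[ch$id]] <- ch
  }
  out
}
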