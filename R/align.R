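#' Build a retention-time warp from anchor points
#'
#' Anchor points pair an observed retention time in one run with a reference
#' time on the shared timeline. The warp is the piecewise-linear monotone
#' map through the anchors: with no anchors it is the identity, with one
#' anchor a constant shift, and with two or more anchors linear
#' interpolation between them with constant-offset extrapolation beyond the
#' outermost anchors (the offset of the nearest anchor — avoids wild linear
#' extrapolation at gradient ends).
#'
#' @param observed_rt,reference_rt equal-length numeric vectors of anchor
#'   coordinates in minutes; must be jointly strictly increasing
#' @return a function `warp(t)` mapping observed to corrected minutes;
#'   strictly increasing and continuous
#' @export
build_warp <- function(observed_rt = numeric(0), reference_rt = numeric(0)) {
  stopifnot(length(observed_rt) == length(reference_rt))
  if (!length(observed_rt)) return(identity)
  ord <- order(observed_rt)
  obs <- observed_rt[ord]; ref <- reference_rt[ord]
  if (any(obs <= 0)) stop("anchor observed times must be > 0", call. = FALSE)
  if (length(obs) > 1L && (any(diff(obs) <= 0) || any(diff(ref) <= 0))) {
    stop("anchors must be strictly increasing in both observed and ",
         "reference coordinates", call. = FALSE)
  }
  if (length(obs) == 1L) {
    shift <- ref - obs
    return(function(t) t + shift)
  }
  function(t) {
    out <- stats::approx(obs, ref, xout = t, method = "linear", rule = 1)$y
    low <- !is.na(t) & t < obs[1L]
    high <- !is.na(t) & t > obs[length(obs)]
    out[low] <- t[low] + (ref[1L] - obs[1L])
    out[high] <- t[high] + (ref[length(ref)] - obs[length(obs)])
    out
  }
}

#' Warp a dataset's retention-time axes
#'
#' Applies per-run warps built from an anchor table to every chromatogram of
#' the dataset. Sampling times are transformed in place (lossless — no
#' resampling onto a common grid); intensities and point counts are
#' untouched. Runs without anchors keep the identity warp.
#'
#' @param dataset an [mrm_dataset()]
#' @param anchors data.frame `run_id, observed_rt, reference_rt` (see
#'   [read_anchors()]); may be empty
#' @return the dataset with corrected time axes
#' @export
warp_dataset <- function(dataset, anchors) {
  stopifnot(inherits(dataset, "mrm_dataset"))
  if (is.null(anchors) || !nrow(anchors)) return(dataset)
  unknown <- setdiff(unique(anchors$run_id), names(dataset$runs))
  if (length(unknown)) {
    stop("anchors reference unknown run(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dataset$runs <- lapply(dataset$runs, function(run) {
    a <- anchors[anchors$run_id == run$run_id, , drop = FALSE]
    if (!nrow(a)) return(run)
    warp <- build_warp(a$observed_rt, a$reference_rt)
    run$channels <- lapply(run$channels, function(ch) {
      ch$times <- warp(ch$times)
      if (length(ch$times) > 1L && any(diff(ch$times) <= 0)) {
        stop("warp produced non-increasing times in run '", run$run_id, "'",
             call. = FALSE)
      }
      ch
    })
    run
  })
  dataset
}

#' Derive shared reference times for anchors by median
#'
#' Helper for the common case where the same landmark peak was marked in
#' every run: given one observed time per run for each landmark, the
#' reference time is the median across runs, yielding a minimal-displacement
#' shared timeline.
#'
#' @param anchors data.frame `run_id, observed_rt, landmark` where
#'   `landmark` labels corresponding peaks across runs
#' @return data.frame `run_id, observed_rt, reference_rt` usable with
#'   [warp_dataset()]
#' @export
median_reference_anchors <- function(anchors) {
  stopifnot(all(c("run_id", "observed_rt", "landmark") %in% names(anchors)))
  ref <- tapply(anchors$observed_rt, anchors$landmark, stats::median)
  data.frame(run_id = anchors$run_id,
             observed_rt = anchors$observed_rt,
             reference_rt = as.numeric(ref[as.character(anchors$landmark)]),
             stringsAsFactors = FALSE)
}
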