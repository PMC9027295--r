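#' Annotation matching configuration
#'
#' Tolerances for linking compound-library entries to MRM channels. The
#' default mass tolerance of 0.2 Da matches unit-resolution quadrupole
#' windows. Matches at exactly the tolerance boundary are included. CE is
#' ignored for annotation by default — collision energy affects intensity,
#' not whether a channel could detect the compound; set `ce_tol` for a
#' strict mode.
#'
#' @param q1_tol,q3_tol m/z tolerances in Da (> 0)
#' @param require_polarity if `TRUE` (default) polarity must match
#' @param ce_tol optional CE tolerance in volts; `NULL` ignores CE
#' @return a `match_config` list
#' @export
match_config <- function(q1_tol = 0.2, q3_tol = 0.2, require_polarity = TRUE,
                         ce_tol = NULL) {
  stopifnot(q1_tol > 0, q3_tol > 0, is.null(ce_tol) || ce_tol > 0)
  structure(list(q1_tol = q1_tol, q3_tol = q3_tol,
                 require_polarity = isTRUE(require_polarity),
                 ce_tol = ce_tol), class = "match_config")
}

#' Annotate dataset channels with compound-library entries
#'
#' Links each library entry to every channel whose transition falls within
#' the configured tolerances. A link marks a possible detection target, not
#' an identification: one channel may carry many annotations and one entry
#' may hit many channels. The result is independent of channel and library
#' row order.
#'
#' @param dataset an [mrm_dataset()] (or a single [mrm_run()])
#' @param library compound library data.frame ([read_compound_library()])
#' @param config a [match_config()]
#' @return data.frame `channel_id, compound, dq1, dq3` (channel minus entry),
#'   zero rows when nothing matches
#' @export
annotate_dataset <- function(dataset, library, config = match_config()) {
  if (inherits(dataset, "mrm_run")) dataset <- mrm_dataset(list(dataset))
  stopifnot(inherits(dataset, "mrm_dataset"), inherits(config, "match_config"))
  channels <- dataset_channel_index(dataset)
  rows <- list()
  for (ch in channels) {
    for (k in seq_len(nrow(library))) {
      if (config$require_polarity && library$polarity[k] != ch$polarity) next
      dq1 <- ch$q1 - library$q1[k]
      dq3 <- ch$q3 - library$q3[k]
      if (abs(dq1) > config$q1_tol || abs(dq3) > config$q3_tol) next
      if (!is.null(config$ce_tol) && !is.na(library$ce[k]) &&
          abs(ch$ce - library$ce[k]) > config$ce_tol) next
      rows[[length(rows) + 1L]] <- data.frame(
        channel_id = ch$id, compound = library$name[k],
        dq1 = dq1, dq3 = dq3, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(channel_id = character(0), compound = character(0),
                      dq1 = numeric(0), dq3 = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$channel_id, out$compound), , drop = FALSE]
}

#' Filter channels by a search query
#'
#' Case-insensitive substring match against the channel id, the rendered
#' transition label (e.g. `"(+)760.6 > 184.05@33V"`), the names of
#' compounds annotated to the channel, and the names of integration targets
#' attached to it. Mirrors interactive search-box narrowing of a large
#' channel list.
#'
#' @param dataset an [mrm_dataset()] or [mrm_run()]
#' @param query nonempty search string
#' @param annotations optional annotation data.frame ([annotate_dataset()])
#' @param targets optional targets data.frame ([read_targets()])
#' @return character vector of matching channel ids (dataset order)
#' @export
filter_channels <- function(dataset, query, annotations = NULL, targets = NULL) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  if (inherits(dataset, "mrm_run")) dataset <- mrm_dataset(list(dataset))
  channels <- dataset_channel_index(dataset)
  q <- tolower(query)
  hits <- character(0)
  for (ch in channels) {
    hay <- c(ch$id, format_transition(ch))
    if (!is.null(annotations)) {
      hay <- c(hay, annotations$compound[annotations$channel_id == ch$id])
    }
    if (!is.null(targets) && nrow(targets)) {
      tid <- channel_id(targets$q1, targets$q3, targets$polarity, targets$ce)
      hay <- c(hay, targets$name[tid == ch$id])
    }
    if (any(grepl(q, tolower(hay), fixed = TRUE))) hits <- c(hits, ch$id)
  }
  hits
}
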