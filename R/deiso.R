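#' Deisotoping configuration
#'
#' Parameters controlling interference discovery and subtraction. Q1/Q3 of a
#' predicted interfered transition are matched against acquired channels
#' within `mass_tol`; corrections are applied only between channels whose
#' collision energies differ by at most `ce_tol` (different CEs give
#' different intensities and are not comparable). Isotopologue spacing is
#' the 13C-12C mass difference; at +/-0.2 Da tolerance the distinction from
#' other single-nucleon spacings is immaterial through M10.
#'
#' @param mass_tol Q1/Q3 match tolerance in Da (default 0.2)
#' @param ce_tol collision-energy match tolerance in volts (default 1.0)
#' @param max_order highest isotopologue order considered (default 10)
#' @param isotope_spacing m/z per nucleon offset (default 1.00335 Da)
#' @param clamp_negative floor corrected intensities at 0 (default `FALSE`;
#'   negative residuals are diagnostic and preserve linearity)
#' @return a `deiso_config` list
#' @export
deiso_config <- function(mass_tol = 0.2, ce_tol = 1.0, max_order = 10L,
                         isotope_spacing = 1.00335, clamp_negative = FALSE) {
  stopifnot(mass_tol > 0, ce_tol >= 0, max_order >= 0, max_order <= 10,
            isotope_spacing > 0)
  structure(list(mass_tol = mass_tol, ce_tol = ce_tol,
                 max_order = as.integer(max_order),
                 isotope_spacing = isotope_spacing,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "deiso_config")
}

empty_edges <- function() {
  data.frame(source_id = character(0), affected_id = character(0),
             compound = character(0), i = integer(0), j = integer(0),
             factor = numeric(0), stringsAsFactors = FALSE)
}

#' Discover isotopic interference relations among a run's channels
#'
#' For every deisotoping-eligible annotation (a library compound with
#' precursor and MS2 formulas linked to a source channel) and every
#' isotopologue pair (i, j) with 1 <= i <= max_order, 0 <= j <= i, the
#' interfered transition is predicted at
#' (Q1 + i * spacing, Q3 + j * spacing). Each acquired channel of the same
#' polarity matching the prediction within `mass_tol`, with CE within
#' `ce_tol` of the source, receives an edge weighted by the transition
#' factor f(i, j). Factors below 1e-12 are dropped. The resulting graph is
#' acyclic because every edge increases Q1.
#'
#' @param run an [mrm_run()]
#' @param annotations annotation data.frame from [annotate_dataset()]
#' @param library compound library data.frame (supplies the formulas)
#' @param config a [deiso_config()]
#' @return an `interference_graph`: list with `edges` (data.frame
#'   `source_id, affected_id, compound, i, j, factor`) and `order` (affected
#'   channel ids in cascade order: ascending Q1, ties by Q3 then CE)
#' @export
find_interference_edges <- function(run, annotations, library,
                                    config = deiso_config()) {
  stopifnot(inherits(run, "mrm_run"), inherits(config, "deiso_config"))
  channels <- run$channels
  ch_q1 <- vapply(channels, `[[`, numeric(1), "q1")
  ch_q3 <- vapply(channels, `[[`, numeric(1), "q3")
  ch_ce <- vapply(channels, `[[`, numeric(1), "ce")
  ch_pol <- vapply(channels, `[[`, character(1), "polarity")
  ids <- names(channels)

  eligible <- annotations[annotations$compound %in%
                            library$name[library$deiso_eligible], , drop = FALSE]
  eligible <- eligible[eligible$channel_id %in% ids, , drop = FALSE]

  rows <- list()
  pattern_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(eligible))) {
    sid <- eligible$channel_id[k]
    comp <- eligible$compound[k]
    lib <- library[library$name == comp & library$deiso_eligible, , drop = FALSE][1, ]
    key <- paste(lib$formula, lib$ms2_formula, lib$ms2_formula_type)
    tp <- pattern_cache[[key]]
    if (is.null(tp)) {
      tp <- transition_pattern(lib$formula, lib$ms2_formula,
                               lib$ms2_formula_type, config$max_order)
      pattern_cache[[key]] <- tp
    }
    src <- channels[[sid]]
    for (i in seq_len(config$max_order)) {
      pred_q1 <- src$q1 + i * config$isotope_spacing
      for (j in 0:i) {
        fij <- tp$factors[i + 1L, j + 1L]
        if (fij < 1e-12) next
        pred_q3 <- src$q3 + j * config$isotope_spacing
        hit <- ch_pol == src$polarity &
          abs(ch_q1 - pred_q1) <= config$mass_tol &
          abs(ch_q3 - pred_q3) <= config$mass_tol &
          abs(ch_ce - src$ce) <= config$ce_tol
        for (tid in ids[hit]) {
          rows[[length(rows) + 1L]] <- data.frame(
            source_id = sid, affected_id = tid, compound = comp,
            i = i, j = j, factor = fij, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  affected <- unique(edges$affected_id)
  ord <- affected[order(ch_q1[affected], ch_q3[affected], ch_ce[affected])]
  structure(list(edges = edges, order = ord), class = "interference_graph")
}

#' @export
print.interference_graph <- function(x, ...) {
  cat("<interference_graph> ", nrow(x$edges), " edge(s), ",
      length(x$order), " affected channel(s)\n", sep = "")
  invisible(x)
}

#' Remove isotopic interference by cascaded chromatogram subtraction
#'
#' Processes affected channels in ascending Q1 (ties: Q3, then CE), so that
#' every subtraction uses the already-corrected source chromatograms —
#' nested (chained) interference is handled by construction, the graph being
#' a DAG ordered by Q1.
#'
#' Per affected channel, redundant contributions are collapsed before
#' subtracting: if a source channel carries several eligible annotations,
#' only the one with the maximum factor is used; if several redundant source
#' channels carry the same compound, the subtracted trace is the point-by-
#' point maximum over them of factor x resampled source intensity,
#' subtracted once. This guards against over-subtraction when the
#' acquisition contains duplicate transitions. Source chromatograms are
#' linearly resampled onto the affected channel's time grid (zero outside
#' their span). Negative residuals are kept unless `clamp_negative` is set.
#'
#' @param run an [mrm_run()]
#' @param graph an `interference_graph` built from this run
#' @param config the [deiso_config()] used to build the graph
#' @return list with `run` (corrected [mrm_run()]) and `report` (data.frame
#'   of applied contributions: `affected_id, compound, source_id, i, j,
#'   factor`)
#' @export
apply_deisotoping <- function(run, graph, config = deiso_config()) {
  stopifnot(inherits(run, "mrm_run"), inherits(graph, "interference_graph"))
  edges <- graph$edges
  unknown <- setdiff(unique(c(edges$source_id, edges$affected_id)),
                     names(run$channels))
  if (length(unknown)) {
    stop("graph references channel(s) absent from run '", run$run_id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  corrected <- run$channels
  applied <- list()
  for (aid in graph$order) {
    target <- corrected[[aid]]
    if (!length(target$times)) next
    inc <- edges[edges$affected_id == aid, , drop = FALSE]
    # one annotation per source channel: keep the compound with max factor
    keep <- unlist(lapply(split(seq_len(nrow(inc)), inc$source_id), function(ix) {
      sub <- inc[ix, , drop = FALSE]
      best <- sub$compound[which.max(sub$factor)]
      ix[sub$compound == best]
    }), use.names = FALSE)
    inc <- inc[sort(keep), , drop = FALSE]
    total <- numeric(length(target$times))
    # one subtraction per source compound; max over redundant source channels
    for (comp in unique(inc$compound)) {
      sub <- inc[inc$compound == comp, , drop = FALSE]
      contrib <- NULL
      for (e in seq_len(nrow(sub))) {
        src <- corrected[[sub$source_id[e]]]
        if (length(src$times) < 2L) next
        trace <- sub$factor[e] *
          resample_onto(src$times, src$intensities, target$times)
        contrib <- if (is.null(contrib)) trace else pmax(contrib, trace)
        applied[[length(applied) + 1L]] <- data.frame(
          affected_id = aid, compound = comp, source_id = sub$source_id[e],
          i = sub$i[e], j = sub$j[e], factor = sub$factor[e],
          stringsAsFactors = FALSE)
      }
      if (!is.null(contrib)) total <- total + contrib
    }
    target$intensities <- target$intensities - total
    if (config$clamp_negative) target$intensities <- pmax(target$intensities, 0)
    corrected[[aid]] <- target
  }
  run$channels <- corrected
  list(run = run,
       report = if (length(applied)) do.call(rbind, applied) else
         data.frame(affected_id = character(0), compound = character(0),
                    source_id = character(0), i = integer(0), j = integer(0),
                    factor = numeric(0)))
}

#' Deisotope a whole dataset
#'
#' Convenience wrapper: annotates each run's channels against the library,
#' builds the interference graph per run (channel sets may differ between
#' runs; factors are run-independent), and applies the cascaded
#' subtraction.
#'
#' @param dataset an [mrm_dataset()]
#' @param library compound library data.frame
#' @param config a [deiso_config()]
#' @param match a [match_config()] for the annotation step
#' @return list with `dataset` (corrected), `edges` (per-run graph edge
#'   data.frame with a `run_id` column) and `report` (applied contributions,
#'   `run_id` column added)
#' @export
deisotope_dataset <- function(dataset, library, config = deiso_config(),
                              match = match_config()) {
  stopifnot(inherits(dataset, "mrm_dataset"))
  annotations <- annotate_dataset(dataset, library, match)
  all_edges <- list(); all_report <- list()
  dataset$runs <- lapply(dataset$runs, function(run) {
    graph <- find_interference_edges(run, annotations, library, config)
    res <- apply_deisotoping(run, graph, config)
    if (nrow(graph$edges)) {
      all_edges[[length(all_edges) + 1L]] <<-
        cbind(run_id = run$run_id, graph$edges)
    }
    if (nrow(res$report)) {
      all_report[[length(all_report) + 1L]] <<-
        cbind(run_id = run$run_id, res$report)
    }
    res$run
  })
  list(dataset = dataset,
       edges = if (length(all_edges)) do.call(rbind, all_edges) else
         cbind(run_id = character(0), empty_edges()),
       report = if (length(all_report)) do.call(rbind, all_report) else NULL)
}
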