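#' Declare a synthetic compound for simulation
#'
#' A compound contributes one declared MRM channel (its own transition) and,
#' through its isotopologues, interference into any other declared channel
#' that matches a shifted transition. Compounds without formulas act as
#' blank "monitor" channels: they can receive interference but never source
#' it (mirroring library rows lacking the formula trio).
#'
#' @param name compound name (underscores, not spaces)
#' @param q1,q3 transition m/z in Da; when `NULL` and formulas are given,
#'   derived from the monoisotopic masses
#' @param polarity `"Positive"` or `"Negative"`
#' @param ce collision energy in volts
#' @param formula precursor-ion formula string, or `NULL`
#' @param ms2_formula product-ion or neutral-loss formula string, or `NULL`
#' @param ms2_formula_type `"ConstantProduct"` or `"ConstantNeutralLoss"`
#' @param peaks data.frame `rt, sigma, height` of Gaussian elution peaks
#'   (minutes, minutes, arbitrary units); zero rows for a blank channel
#' @return a `synthetic_compound` list
#' @export
synthetic_compound <- function(name, q1 = NULL, q3 = NULL,
                               polarity = "Positive", ce = 33,
                               formula = NULL, ms2_formula = NULL,
                               ms2_formula_type = "ConstantProduct",
                               peaks = data.frame(rt = numeric(0),
                                                  sigma = numeric(0),
                                                  height = numeric(0))) {
  has_formulas <- !is.null(formula) && !is.null(ms2_formula)
  if (is.null(q1)) {
    if (!has_formulas) stop("q1 required when no formula is given", call. = FALSE)
    q1 <- monoisotopic_mass(formula)
  }
  if (is.null(q3)) {
    if (!has_formulas) stop("q3 required when no formula is given", call. = FALSE)
    q3 <- if (ms2_formula_type == "ConstantProduct") {
      monoisotopic_mass(ms2_formula)
    } else {
      monoisotopic_mass(formula_subtract(formula, ms2_formula))
    }
  }
  stopifnot(nrow(peaks) == 0 || (all(peaks$height > 0) && all(peaks$sigma > 0)))
  if (has_formulas) {
    if (abs(monoisotopic_mass(formula) - q1) > 0.2) {
      warning("declared Q1 ", q1, " of '", name,
              "' is > 0.2 Da from the formula mass", call. = FALSE)
    }
  }
  structure(list(name = name, q1 = q1, q3 = q3, polarity = polarity, ce = ce,
                 formula = formula, ms2_formula = ms2_formula,
                 ms2_formula_type = if (has_formulas) ms2_formula_type else NULL,
                 peaks = peaks),
            class = "synthetic_compound")
}

#' Simulation specification
#'
#' @param compounds list of [synthetic_compound()] objects
#' @param runs number of runs (>= 1)
#' @param sampling_interval chromatogram sampling step in minutes
#' @param time_start,time_end acquired span in minutes
#' @param noise_sd additive Gaussian noise SD in intensity units (0 = off)
#' @param saturation_limit detector ceiling in intensity units, or `NULL`
#' @param rt_drift per-run retention-time shift in minutes (recycled /
#'   defaulted to a small linear drift across runs)
#' @param max_order highest isotopologue order in the forward model
#' @param seed RNG seed for the noise (simulation is deterministic given it)
#' @return a `simulation_spec` list
#' @export
simulation_spec <- function(compounds, runs = 5L, sampling_interval = 0.01,
                            time_start = 11.5, time_end = 13.5,
                            noise_sd = 0, saturation_limit = NULL,
                            rt_drift = NULL, max_order = 10L, seed = 1L) {
  stopifnot(length(compounds) >= 1L, runs >= 1L, sampling_interval > 0,
            time_end > time_start, noise_sd >= 0,
            is.null(saturation_limit) || saturation_limit > 0)
  if (is.null(rt_drift)) {
    rt_drift <- if (runs == 1L) 0 else seq(-0.02, 0.02, length.out = runs)
  }
  rt_drift <- rep_len(rt_drift, runs)
  structure(list(compounds = compounds, runs = as.integer(runs),
                 sampling_interval = sampling_interval,
                 time_start = time_start, time_end = time_end,
                 noise_sd = noise_sd, saturation_limit = saturation_limit,
                 rt_drift = rt_drift, max_order = as.integer(max_order),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' The default simulated scenario: nested PC/SM isotopic interference
#'
#' Three phospholipid head-group channels in a chain — PC 38:4 (810.6 > 184),
#' SM 42:3;O2 (811.7 > 184) and PC 38:3 (812.6 > 184) — plus three blank
#' monitor channels placed on higher-order shifted transitions, giving six
#' channels in total with cascaded (nested) interference: the PC 38:3
#' channel both receives interference (M2 of PC 38:4, M1 of SM) and sources
#' it (into the M1 monitor). Peak heights span the upper end of a TQMS
#' working range so that saturation experiments clip the dominant source
#' peak.
#'
#' @param ... overrides passed on to [simulation_spec()]
#' @return a `simulation_spec`
#' @export
default_simulation_spec <- function(...) {
  pk <- function(rt, height, sigma = 0.05) data.frame(rt = rt, sigma = sigma,
                                                      height = height)
  compounds <- list(
    synthetic_compound("PC_38:4", formula = "C46H85O8NP",
                       ms2_formula = "C5H15O4NP", peaks = pk(12.0, 1e6)),
    synthetic_compound("SM_42:3;O2", formula = "C47H92N2O6P",
                       ms2_formula = "C5H15O4NP", peaks = pk(12.6, 3e5)),
    synthetic_compound("PC_38:3", formula = "C46H87O8NP",
                       ms2_formula = "C5H15O4NP", peaks = pk(12.3, 5e5)),
    synthetic_compound("monitor_811.6/185.1", q1 = 811.60, q3 = 185.07),
    synthetic_compound("monitor_812.6/185.1", q1 = 812.60, q3 = 185.07),
    synthetic_compound("monitor_813.6/184.1", q1 = 813.62, q3 = 184.07))
  simulation_spec(compounds, ...)
}

#' Compound library table for a simulation spec
#' @param spec a `simulation_spec`
#' @return data.frame in [read_compound_library()] layout
#' @export
simulation_library <- function(spec) {
  rows <- lapply(spec$compounds, function(cp) {
    data.frame(name = cp$name, q1 = cp$q1, q3 = cp$q3, ce = cp$ce,
               polarity = cp$polarity,
               formula = if (is.null(cp$formula)) NA_character_ else cp$formula,
               ms2_formula = if (is.null(cp$ms2_formula)) NA_character_ else cp$ms2_formula,
               ms2_formula_type = if (is.null(cp$ms2_formula_type)) NA_character_ else cp$ms2_formula_type,
               tags = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$deiso_eligible <- !is.na(out$formula) & !is.na(out$ms2_formula) &
    !is.na(out$ms2_formula_type)
  out
}

#' Simulate a scheduled-MRM dataset with forward-modelled interference
#'
#' The clean intensity of each channel is the sum of its own compound's
#' Gaussian peaks. The contaminated intensity additionally receives, for
#' every other formula-bearing compound C and isotopologue pair (i, j), the
#' term `f(i, j) * clean trace of C` whenever C's shifted transition
#' `(Q1 + i * 1.00335, Q3 + j * 1.00335)` matches the channel within 0.2 Da
#' (same polarity, CE within 1.0 V) — the exact forward counterpart of the
#' interference-discovery rule. Per-run retention-time drift shifts every
#' peak, then Gaussian noise is added and values clipped at the saturation
#' ceiling when one is set. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [simulation_spec()]
#' @return list with `contaminated` (the observed [mrm_dataset()]), `clean`
#'   (interference-free, noise-free ground truth), `edges` (the true
#'   interference edge list: `source_id, affected_id, compound, i, j,
#'   factor`), and `library` (matching compound-library data.frame)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  grid <- seq(spec$time_start, spec$time_end, by = spec$sampling_interval)
  comps <- spec$compounds
  n <- length(comps)
  ids <- vapply(comps, function(cp) channel_id(cp$q1, cp$q3, cp$polarity, cp$ce),
                character(1))
  if (anyDuplicated(ids)) stop("duplicate declared transitions", call. = FALSE)

  # true interference edges (run-independent; shared channel set)
  spacing <- 1.00335
  edges <- empty_edges()
  tps <- lapply(comps, function(cp) {
    if (is.null(cp$ms2_formula_type)) return(NULL)
    transition_pattern(cp$formula, cp$ms2_formula, cp$ms2_formula_type,
                       spec$max_order)
  })
  for (s in seq_len(n)) {
    if (is.null(tps[[s]])) next
    for (i in seq_len(spec$max_order)) {
      for (j in 0:i) {
        fij <- tps[[s]]$factors[i + 1L, j + 1L]
        if (fij < 1e-12) next
        for (t in seq_len(n)) {
          if (comps[[t]]$polarity != comps[[s]]$polarity) next
          if (abs(comps[[t]]$ce - comps[[s]]$ce) > 1.0) next
          if (abs(comps[[t]]$q1 - (comps[[s]]$q1 + i * spacing)) > 0.2) next
          if (abs(comps[[t]]$q3 - (comps[[s]]$q3 + j * spacing)) > 0.2) next
          edges <- rbind(edges, data.frame(
            source_id = ids[s], affected_id = ids[t],
            compound = comps[[s]]$name, i = i, j = j, factor = fij,
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  gauss_trace <- function(cp, drift) {
    y <- numeric(length(grid))
    for (p in seq_len(nrow(cp$peaks))) {
      y <- y + cp$peaks$height[p] *
        exp(-((grid - (cp$peaks$rt[p] + drift))^2) / (2 * cp$peaks$sigma[p]^2))
    }
    y
  }

  clean_runs <- list(); cont_runs <- list()
  for (r in seq_len(spec$runs)) {
    drift <- spec$rt_drift[r]
    clean_traces <- lapply(comps, gauss_trace, drift = drift)
    names(clean_traces) <- ids
    cont_traces <- clean_traces
    for (e in seq_len(nrow(edges))) {
      cont_traces[[edges$affected_id[e]]] <-
        cont_traces[[edges$affected_id[e]]] +
        edges$factor[e] * clean_traces[[edges$source_id[e]]]
    }
    if (spec$noise_sd > 0) {
      cont_traces <- lapply(cont_traces, function(y) {
        y + stats::rnorm(length(y), sd = spec$noise_sd)
      })
    }
    if (!is.null(spec$saturation_limit)) {
      cont_traces <- lapply(cont_traces, clip_saturation,
                            limit = spec$saturation_limit)
    }
    make_run <- function(traces, run_id) {
      mrm_run(run_id, lapply(seq_len(n), function(k) {
        cp <- comps[[k]]
        mrm_channel(cp$q1, cp$q3, cp$polarity, cp$ce, grid, traces[[k]])
      }))
    }
    run_id <- sprintf("run%02d", r)
    clean_runs[[r]] <- make_run(clean_traces, run_id)
    cont_runs[[r]] <- make_run(cont_traces, run_id)
  }
  list(contaminated = mrm_dataset(cont_runs),
       clean = mrm_dataset(clean_runs),
       edges = edges,
       library = simulation_library(spec))
}
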