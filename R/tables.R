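# Tab-delimited interchange formats. All files are UTF-8, '.' decimal
# separator, header row mandatory. The long dataset table is the open
# reference format for chromatogram exchange (mzML is ingest-only).

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read / write a chromatogram dataset in the tabular interchange format
#'
#' Long format, tab-delimited, one row per chromatogram point, columns
#' `run_id, polarity, q1, q3, ce, time_min, intensity`. Write-then-read is
#' lossless: values round-trip at 9 significant digits.
#'
#' @param path file path
#' @return [read_dataset_table()]: an [mrm_dataset()]
#' @export
read_dataset_table <- function(path) {
  cols <- c("run_id", "polarity", "q1", "q3", "ce", "time_min", "intensity")
  df <- read_tsv_checked(path, cols)
  if (!nrow(df)) stop("dataset table is empty: ", path, call. = FALSE)
  for (col in c("q1", "q3", "ce", "time_min", "intensity")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(is.na(df[[col]]))) {
      stop("non-numeric value in column '", col, "' of ", path, call. = FALSE)
    }
  }
  runs <- lapply(split(df, df$run_id), function(rd) {
    key <- channel_id(rd$q1, rd$q3, rd$polarity, rd$ce)
    channels <- lapply(split(rd, key), function(cd) {
      if (any(diff(cd$time_min) <= 0)) {
        stop("non-monotone times in channel ",
             channel_id(cd$q1[1], cd$q3[1], cd$polarity[1], cd$ce[1]),
             " of run '", cd$run_id[1], "'", call. = FALSE)
      }
      mrm_channel(cd$q1[1], cd$q3[1], cd$polarity[1], cd$ce[1],
                  cd$time_min, cd$intensity)
    })
    mrm_run(rd$run_id[1], unname(channels))
  })
  mrm_dataset(unname(runs)[order(names(runs))])
}

#' @param dataset an [mrm_dataset()]
#' @rdname read_dataset_table
#' @export
write_dataset_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mrm_dataset"))
  rows <- list()
  for (run in dataset$runs) {
    for (ch in run$channels) {
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run$run_id, polarity = ch$polarity,
        q1 = ch$q1, q3 = ch$q3, ce = ch$ce,
        time_min = formatC(ch$times, format = "g", digits = 9),
        intensity = formatC(ch$intensities, format = "g", digits = 9),
        stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a compound library
#'
#' Tab-delimited library with header fields `Name`, `Q1`, `Q3`, `CE`
#' (optional), `Polarity`, `Formula`, `MS2Formula`, `MS2FormulaType`
#' (optional trio), `Tags` (optional). Compound names use underscores
#' instead of spaces. Rows carrying the full formula trio are eligible as
#' deisotoping sources; rows without it are kept but flagged ineligible
#' (they may still be annotated and receive corrections).
#'
#' @param path file path
#' @return data.frame with columns `name, q1, q3, ce, polarity, formula,
#'   ms2_formula, ms2_formula_type, tags, deiso_eligible`
#' @export
read_compound_library <- function(path) {
  df <- read_tsv_checked(path, c("Name", "Q1", "Q3", "Polarity"))
  for (opt in c("CE", "Formula", "MS2Formula", "MS2FormulaType", "Tags")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA
  }
  out <- data.frame(
    name = as.character(df$Name),
    q1 = suppressWarnings(as.numeric(df$Q1)),
    q3 = suppressWarnings(as.numeric(df$Q3)),
    ce = ifelse(is.na(df$CE) | df$CE == "", NA_real_, suppressWarnings(as.numeric(df$CE))),
    polarity = as.character(df$Polarity),
    formula = blank_to_na(df$Formula),
    ms2_formula = blank_to_na(df$MS2Formula),
    ms2_formula_type = blank_to_na(df$MS2FormulaType),
    tags = blank_to_na(df$Tags),
    stringsAsFactors = FALSE)
  if (any(is.na(out$q1)) || any(is.na(out$q3))) {
    stop("unparseable Q1/Q3 in library ", path, call. = FALSE)
  }
  bad_ce <- !is.na(df$CE) & df$CE != "" & is.na(out$ce)
  if (any(bad_ce)) stop("unparseable CE in library ", path, call. = FALSE)
  if (!all(out$polarity %in% c("Positive", "Negative"))) {
    stop("Polarity must be 'Positive' or 'Negative'", call. = FALSE)
  }
  known_type <- is.na(out$ms2_formula_type) |
    out$ms2_formula_type %in% c("ConstantProduct", "ConstantNeutralLoss")
  if (!all(known_type)) {
    stop("unknown MS2FormulaType token: ",
         paste(unique(out$ms2_formula_type[!known_type]), collapse = ", "),
         call. = FALSE)
  }
  out$deiso_eligible <- !is.na(out$formula) & !is.na(out$ms2_formula) &
    !is.na(out$ms2_formula_type)
  # validate formulas early so a bad library fails at load, not mid-deisotoping
  for (k in which(out$deiso_eligible)) {
    prec <- parse_formula(out$formula[k])
    parse_formula(out$ms2_formula[k])
    mz <- monoisotopic_mass(prec)
    if (abs(mz - out$q1[k]) > 0.5) {
      warning("library row '", out$name[k], "': monoisotopic mass ",
              round(mz, 3), " differs from declared Q1 ", out$q1[k],
              call. = FALSE)
    }
  }
  out
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA_character_
  x
}

#' Write a compound library
#' @param library data.frame as returned by [read_compound_library()]
#' @param path file path
#' @export
write_compound_library <- function(library, path) {
  na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
  df <- data.frame(Name = library$name, Q1 = library$q1, Q3 = library$q3,
                   CE = na_blank(library$ce), Polarity = library$polarity,
                   Formula = na_blank(library$formula),
                   MS2Formula = na_blank(library$ms2_formula),
                   MS2FormulaType = na_blank(library$ms2_formula_type),
                   Tags = na_blank(library$tags),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read / write integration target definitions
#'
#' Tab-delimited, columns `name, polarity, q1, q3, ce, rt_start_min,
#' rt_end_min`. A target is an MRM channel plus an integration range; it
#' carries no peak model. An empty target list writes a header-only file
#' that reads back empty.
#'
#' @param path file path
#' @return [read_targets()]: data.frame with the columns above
#' @export
read_targets <- function(path) {
  cols <- c("name", "polarity", "q1", "q3", "ce", "rt_start_min", "rt_end_min")
  df <- read_tsv_checked(path, cols)[cols]
  for (col in c("q1", "q3", "ce", "rt_start_min", "rt_end_min")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) && any(df$rt_start_min >= df$rt_end_min)) {
    stop("target with rt_start >= rt_end in ", path, call. = FALSE)
  }
  df
}

#' @param targets data.frame of targets
#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  cols <- c("name", "polarity", "q1", "q3", "ce", "rt_start_min", "rt_end_min")
  stopifnot(all(cols %in% names(targets)))
  if (nrow(targets) && any(targets$rt_start_min >= targets$rt_end_min)) {
    stop("target with rt_start >= rt_end", call. = FALSE)
  }
  write_tsv(targets[cols], path)
  invisible(path)
}

#' Read / write retention-time anchor tables
#'
#' Tab-delimited, columns `run_id, observed_rt_min, reference_rt_min`.
#' @param path file path
#' @return [read_anchors()]: data.frame `run_id, observed_rt, reference_rt`
#' @export
read_anchors <- function(path) {
  df <- read_tsv_checked(path, c("run_id", "observed_rt_min", "reference_rt_min"))
  data.frame(run_id = as.character(df$run_id),
             observed_rt = as.numeric(df$observed_rt_min),
             reference_rt = as.numeric(df$reference_rt_min),
             stringsAsFactors = FALSE)
}

#' @param anchors data.frame of anchors
#' @rdname read_anchors
#' @export
write_anchors <- function(anchors, path) {
  write_tsv(data.frame(run_id = anchors$run_id,
                       observed_rt_min = anchors$observed_rt,
                       reference_rt_min = anchors$reference_rt), path)
  invisible(path)
}
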