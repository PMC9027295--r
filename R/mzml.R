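#' Read SRM chromatograms from an mzML file
#'
#' Parses the chromatogram list of a PSI mzML file and returns one channel
#' per SRM (selected reaction monitoring) chromatogram. Non-SRM
#' chromatograms — TIC, pressure traces, anything without both precursor and
#' product isolation windows — are skipped. Q1/Q3 are taken from the
#' isolation window target m/z cvParams, collision energy from the
#' activation element (0 V with a warning when absent, as happens with
#' msconvert output), polarity from chromatogram-level cvParams with a
#' file-level scan-settings fallback. Times are converted to minutes.
#'
#' Only uncompressed and zlib-compressed 32/64-bit float binary arrays are
#' supported (the encodings mzML writers emit for chromatograms).
#'
#' @param path path to an mzML file
#' @param run_id run identifier; default is the file name without extension
#' @return an [mrm_run()]
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("invalid mzML: ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  chrom_nodes <- xml2::xml_find_all(doc, ".//chromatogramList/chromatogram")
  if (!length(chrom_nodes)) stop("mzML contains no chromatograms: ", path,
                                 call. = FALSE)
  file_polarity <- mzml_file_polarity(doc)
  channels <- list()
  for (node in chrom_nodes) {
    q1 <- mzml_isolation_mz(node, "precursor")
    q3 <- mzml_isolation_mz(node, "product")
    if (is.na(q1) || is.na(q3)) next  # TIC / pressure / non-SRM trace
    ce <- mzml_cv_value(node, "MS:1000045")
    if (is.na(ce)) {
      warning("SRM chromatogram without collision energy in ", basename(path),
              "; recording 0 V (CE matching downstream will degrade)",
              call. = FALSE)
      ce <- 0
    }
    polarity <- mzml_node_polarity(node)
    if (is.na(polarity)) polarity <- file_polarity
    if (is.na(polarity)) {
      stop("polarity not present at chromatogram or file level in ", path,
           call. = FALSE)
    }
    arr <- mzml_binary_arrays(node)
    channels[[length(channels) + 1L]] <-
      mrm_channel(q1, q3, polarity, ce, arr$time, arr$intensity)
  }
  if (!length(channels)) {
    stop("mzML contains no SRM chromatograms: ", path, call. = FALSE)
  }
  mrm_run(run_id, channels)
}

mzml_cv_value <- function(node, accession, xpath = ".") {
  v <- xml2::xml_attr(xml2::xml_find_first(
    node, sprintf("%s//cvParam[@accession='%s']", xpath, accession)), "value")
  suppressWarnings(as.numeric(v))
}

mzml_isolation_mz <- function(node, which) {
  # MS:1000827 isolation window target m/z
  mzml_cv_value(node, "MS:1000827", sprintf("./%s/isolationWindow", which))
}

mzml_node_polarity <- function(node) {
  if (length(xml2::xml_find_first(node, "./cvParam[@accession='MS:1000130']")) > 0)
    return("Positive")
  if (length(xml2::xml_find_first(node, "./cvParam[@accession='MS:1000129']")) > 0)
    return("Negative")
  NA_character_
}

mzml_file_polarity <- function(doc) {
  pos <- xml2::xml_find_first(doc, ".//scanSettingsList//cvParam[@accession='MS:1000130']")
  neg <- xml2::xml_find_first(doc, ".//scanSettingsList//cvParam[@accession='MS:1000129']")
  if (length(pos)) return("Positive")
  if (length(neg)) return("Negative")
  NA_character_
}

mzml_binary_arrays <- function(node) {
  arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
  time <- NULL; intensity <- NULL
  for (a in arrays) {
    has <- function(acc) length(xml2::xml_find_first(
      a, sprintf("./cvParam[@accession='%s']", acc))) > 0
    txt <- xml2::xml_text(xml2::xml_find_first(a, "./binary"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (has("MS:1000574")) {  # zlib compression
      raw <- memDecompress(raw, type = "gzip")
    }
    size <- if (has("MS:1000521")) 4L else 8L  # 32-bit vs 64-bit float
    vals <- readBin(raw, what = "double", size = size,
                    n = length(raw) %/% size, endian = "little")
    if (has("MS:1000595")) {          # time array
      if (length(xml2::xml_find_first(
        a, "./cvParam[@accession='MS:1000595'][@unitName='second']")) > 0) {
        vals <- vals / 60
      }
      time <- vals
    } else if (has("MS:1000515")) {   # intensity array
      intensity <- vals
    }
  }
  if (is.null(time) || is.null(intensity)) {
    stop("chromatogram without time/intensity binary arrays", call. = FALSE)
  }
  list(time = time, intensity = intensity)
}
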