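# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

# --- brute-force multinomial oracle -----------------------------------------
# Enumerates every isotope assignment over the individual atoms of a formula
# (feasible for <= ~6 atoms) and aggregates probability by total nucleon
# offset. Independent of the package's convolution path.
oracle_pattern <- function(counts, max_order = 10L) {
  tab <- isotope_table()
  atoms <- rep(names(counts), counts)
  p <- numeric(max_order + 1L)
  if (!length(atoms)) { p[1L] <- 1; return(p) }
  choices <- lapply(atoms, function(sym) seq_along(tab[[sym]]$offset))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (row in seq_len(nrow(grid))) {
    off <- 0L; prob <- 1
    for (a in seq_along(atoms)) {
      k <- grid[row, a]
      off <- off + tab[[atoms[a]]]$offset[k]
      prob <- prob * tab[[atoms[a]]]$abundance[k]
    }
    if (off <= max_order) p[off + 1L] <- p[off + 1L] + prob
  }
  p
}

# random small formula as a named count vector (always contains >= 1 carbon
# so patterns are nondegenerate)
random_formula <- function(max_atoms = 30L) {
  syms <- supported_elements()
  n <- sample(seq_along(syms), 1)
  picked <- sample(syms, n)
  counts <- sapply(picked, function(s) sample.int(max_atoms, 1))
  if (!"C" %in% names(counts)) counts <- c(counts, C = sample.int(max_atoms, 1))
  counts
}

# --- channel/dataset builders ------------------------------------------------
const_channel <- function(q1, q3 = 184.07, value = 100, ce = 33,
                          polarity = "Positive",
                          times = seq(0, 10, by = 0.5)) {
  mrm_channel(q1, q3, polarity, ce, times, rep(value, length(times)))
}

gaussian_channel <- function(q1, q3 = 184.07, apex = 5, sigma = 0.2,
                             height = 1000, ce = 33, polarity = "Positive",
                             times = seq(0, 10, by = 0.02)) {
  mrm_channel(q1, q3, polarity, ce, times,
              height * exp(-(times - apex)^2 / (2 * sigma^2)))
}

# minimal deisotoping-eligible library row(s)
lib_row <- function(name, q1, q3, formula = NA, ms2_formula = NA,
                    ms2_formula_type = NA, ce = 33, polarity = "Positive") {
  data.frame(name = name, q1 = q1, q3 = q3, ce = ce, polarity = polarity,
             formula = formula, ms2_formula = ms2_formula,
             ms2_formula_type = ms2_formula_type, tags = NA_character_,
             deiso_eligible = !is.na(formula) & !is.na(ms2_formula) &
               !is.na(ms2_formula_type),
             stringsAsFactors = FALSE)
}

# --- mzML fixture writer ------------------------------------------------------
# Emits a minimal but standard-conformant mzML chromatogram list with
# uncompressed little-endian base64 binary arrays.
mzml_binary <- function(values, size = 8L) {
  jsonlite::base64_enc(writeBin(as.numeric(values), raw(), size = size,
                                endian = "little"))
}

mzml_chromatogram <- function(index, id, times_min, intensities,
                              q1 = NULL, q3 = NULL, ce = NULL,
                              polarity = "Positive", time_unit = "minute",
                              tic = FALSE) {
  t_vals <- if (time_unit == "second") times_min * 60 else times_min
  cv_pol <- if (is.null(polarity) || is.na(polarity)) "" else if (polarity == "Positive") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }
  prec <- if (is.null(q1)) "" else sprintf(paste0(
    '<precursor><isolationWindow>',
    '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%s"/>',
    '</isolationWindow>%s</precursor>'), q1,
    if (is.null(ce)) "" else sprintf(paste0(
      '<activation><cvParam cvRef="MS" accession="MS:1000045" ',
      'name="collision energy" value="%s" unitName="electronvolt"/></activation>'), ce))
  prod <- if (is.null(q3)) "" else sprintf(paste0(
    '<product><isolationWindow>',
    '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%s"/>',
    '</isolationWindow></product>'), q3)
  kind <- if (tic) {
    '<cvParam cvRef="MS" accession="MS:1000235" name="total ion current chromatogram" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>'
  }
  sprintf(paste0(
    '<chromatogram index="%d" id="%s" defaultArrayLength="%d">%s%s%s%s',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitName="%s"/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></chromatogram>'),
    index, id, length(t_vals), kind, cv_pol, prec, prod,
    time_unit, mzml_binary(t_vals), mzml_binary(intensities))
}

write_fixture_mzml <- function(path, chromatograms, file_polarity = NULL) {
  settings <- if (is.null(file_polarity)) "" else sprintf(paste0(
    '<scanSettingsList count="1"><scanSettings id="s1">',
    '<cvParam cvRef="MS" accession="%s" name="%s scan" value=""/>',
    '</scanSettings></scanSettingsList>'),
    if (file_polarity == "Positive") "MS:1000130" else "MS:1000129",
    tolower(file_polarity))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    settings,
    '<run id="fixture">',
    sprintf('<chromatogramList count="%d" defaultDataProcessingRef="dp1">',
            length(chromatograms)),
    paste(chromatograms, collapse = ""),
    '</chromatogramList></run></mzML>')
  writeLines(xml, path)
  path
}

# maximum relative deviation between two datasets' intensities
max_rel_error <- function(a, b, floor = 1) {
  err <- 0
  for (rn in names(b$runs)) {
    for (id in names(b$runs[[rn]]$channels)) {
      x <- a$runs[[rn]]$channels[[id]]$intensities
      y <- b$runs[[rn]]$channels[[id]]$intensities
      err <- max(err, max(abs(x - y) / pmax(abs(y), floor)))
    }
  }
  err
}
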