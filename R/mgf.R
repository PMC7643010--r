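# Minimal MGF (Mascot generic format) reader/writer for fragment spectra.
# Only the fields the phospho stage needs are handled: TITLE, PEPMASS,
# CHARGE and the peak list. Writing is fully deterministic (fixed number
# formatting) so identical inputs produce byte-identical files.

#' Read fragment spectra from an MGF file
#'
#' @param path path to an MGF file.
#' @return list of spectra; each spectrum is a list with `spectrum_id`
#'   (TITLE), `precursor_mz` (first PEPMASS token), `charge` (integer) and
#'   `peaks` (data.frame `mz, intensity`, sorted by m/z).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path))
    abort(sprintf("MGF file not found: %s", path), "apms_io_error")
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
    mz <- numeric(); intensity <- numeric()
    i <- i + 1L
    while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
      line <- trimws(lines[i])
      if (startsWith(line, "TITLE=")) {
        title <- sub("^TITLE=", "", line)
      } else if (startsWith(line, "PEPMASS=")) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                       "\\s+")[[1]][1])
      } else if (startsWith(line, "CHARGE=")) {
        charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", line)))
      } else if (nzchar(line) && !grepl("=", line, fixed = TRUE)) {
        parts <- as.numeric(strsplit(line, "\\s+")[[1]])
        if (length(parts) < 2L || anyNA(parts))
          abort(sprintf("malformed peak line in '%s': '%s'", path, line),
                "apms_parse_error")
        mz <- c(mz, parts[1]); intensity <- c(intensity, parts[2])
      }
      i <- i + 1L
    }
    peaks <- data.frame(mz = mz, intensity = intensity)
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    spectra[[length(spectra) + 1L]] <-
      list(spectrum_id = title, precursor_mz = pepmass, charge = charge,
           peaks = peaks)
    i <- i + 1L
  }
  if (!length(spectra))
    abort(sprintf("no spectra found in '%s'", path), "apms_parse_error")
  spectra
}

#' Write fragment spectra to an MGF file
#'
#' @param spectra list of spectra (see [read_mgf()] for the layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.5f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    pk <- sp$peaks[order(sp$peaks$mz), , drop = FALSE]
    writeLines(sprintf("%.5f %.2f", pk$mz, pk$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
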