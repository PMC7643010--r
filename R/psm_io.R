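# PSM / protein data model: FASTA and PSM-table readers, peptide-protein
# mapping, in-silico tryptic digestion.

#: required header of the tab-separated PSM dialect
PSM_COLUMNS <- c("spectrum_id", "peptide", "modifications", "charge",
                 "intensity", "sample_id", "band", "condition", "replicate",
                 "q_value", "e_value")

#' Read a protein database from FASTA
#'
#' Parses a FASTA file into a protein table. The accession is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description. Sequences are upper-cased and whitespace-stripped, and must
#' use only the 20 canonical amino-acid letters (ambiguity codes such as
#' B/J/O/U/X/Z are rejected with an error naming the offending record).
#'
#' @param path path to a FASTA file.
#' @return A `data.frame` of class `protein_db` with columns `accession`,
#'   `description`, `sequence`, one row per record, input order preserved.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo protein", "ACDK"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path))
    abort(sprintf("FASTA file not found: %s", path), "apms_io_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    abort(sprintf("malformed FASTA '%s': %s",
                                  path, conditionMessage(e)),
                          "apms_parse_error"))
  if (!length(set))
    abort(sprintf("FASTA '%s' contains no records", path), "apms_parse_error")
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(sequence)) {
    label <- if (nzchar(accession[i])) accession[i] else sprintf("record %d", i)
    check_sequence(sequence[i], label)
  }
  out <- data.frame(accession = accession, description = description,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_db", "data.frame")
  out
}

#' Write a protein table to FASTA
#'
#' @param proteins a `protein_db` data frame (see [read_fasta()]).
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    desc <- proteins$description[i] %||% ""
    header <- if (nzchar(desc))
      paste(proteins$accession[i], desc) else proteins$accession[i]
    writeLines(paste0(">", header), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a modification string
#'
#' The PSM dialect encodes modifications as `"pos:delta"` pairs separated by
#' semicolons, with `pos` a 1-based residue index within the peptide and
#' `delta` a mass shift in Daltons (e.g. `"3:79.9663"` for a phosphosite on
#' residue 3). An empty string means no modifications.
#'
#' @param x a single modification string.
#' @return data.frame with columns `position` (integer) and `mass_delta`.
#' @export
parse_modifications <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(position = integer(), mass_delta = numeric()))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, ":", fixed = TRUE)
  ok <- vapply(fields, length, 1L) == 2L
  if (!all(ok))
    abort(sprintf("malformed modification string: '%s'", x),
          "apms_parse_error")
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  delta <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos) || anyNA(delta))
    abort(sprintf("malformed modification string: '%s'", x),
          "apms_parse_error")
  data.frame(position = pos, mass_delta = delta)
}

format_modifications <- function(mods) {
  if (!nrow(mods)) return("")
  paste(sprintf("%d:%.4f", mods$position, mods$mass_delta), collapse = ";")
}

#' Read a PSM table
#'
#' Reads the tab-separated peptide-spectrum-match dialect (one row per PSM,
#' header columns `spectrum_id, peptide, modifications, charge, intensity,
#' sample_id, band, condition, replicate, q_value, e_value`). Rows whose
#' q-value exceeds `q_cutoff` are excluded; the number of exclusions is
#' recorded in the `"n_excluded"` attribute and reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param q_cutoff q-value threshold used for quality control on input;
#'   rows with `q_value > q_cutoff` are dropped. Default 0.01.
#' @return A `data.frame` of class `psm_table` with the dialect's columns
#'   (`modifications` kept as strings; use [parse_modifications()]), plus
#'   attribute `n_excluded`.
#' @export
read_psm_table <- function(path, q_cutoff = 0.01) {
  if (!file.exists(path))
    abort(sprintf("PSM table not found: %s", path), "apms_io_error")
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing))
    abort(sprintf("PSM table '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")), "apms_schema_error")
  raw <- raw[PSM_COLUMNS]
  num_cols <- c("charge", "intensity", "replicate", "q_value", "e_value")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & nzchar(raw[[col]]))
    if (length(bad) || anyNA(vals))
      abort(sprintf("PSM table '%s': non-numeric '%s' at line %d",
                    path, col,
                    (if (length(bad)) bad[1] else which(is.na(vals))[1]) + 1L),
            "apms_parse_error")
    raw[[col]] <- vals
  }
  raw$charge <- as.integer(raw$charge)
  raw$replicate <- as.integer(raw$replicate)
  if (any(raw$intensity < 0))
    abort(sprintf("PSM table '%s': negative intensity at line %d",
                  path, which(raw$intensity < 0)[1] + 1L), "apms_parse_error")
  # validate modification strings and positions up front
  for (i in seq_len(nrow(raw))) {
    mods <- parse_modifications(raw$modifications[i])
    if (nrow(mods) &&
        any(mods$position < 1L | mods$position > nchar(raw$peptide[i])))
      abort(sprintf(
        "PSM table '%s': modification position outside peptide at line %d",
        path, i + 1L), "apms_parse_error")
  }
  keep <- raw$q_value <= q_cutoff
  n_excluded <- sum(!keep)
  if (n_excluded)
    message(sprintf("read_psm_table: excluded %d of %d rows with q_value > %g",
                    n_excluded, nrow(raw), q_cutoff))
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; numeric fields are written with enough
#' digits that reading the file back reproduces them bit-identically.
#'
#' @param psms PSM data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  stopifnot(all(PSM_COLUMNS %in% names(psms)))
  out <- psms[PSM_COLUMNS]
  for (col in c("intensity", "q_value", "e_value"))
    out[[col]] <- format_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map peptides to proteins by exact substring search
#'
#' Every occurrence of each peptide in each protein sequence is recorded as
#' a 1-based inclusive span. Isoleucine and leucine are treated as distinct
#' letters: search-engine output is already database-resolved, so mapping is
#' exact-match. A peptide is flagged `unique` when it matches exactly one
#' accession (possibly at several positions within it).
#'
#' @param peptides character vector of peptide sequences (or a `psm_table`,
#'   whose distinct peptides are used).
#' @param proteins a `protein_db` data frame.
#' @return An object of class `peptide_map`: a list with `hits` (data.frame
#'   `peptide, accession, start, end`) and `peptides` (data.frame `peptide,
#'   n_accessions, unique`). Unmatched peptides get no hits, `unique = FALSE`
#'   and a warning.
#' @export
map_peptides <- function(peptides, proteins) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(as.character(peptides))
  if (!nrow(proteins))
    abort("protein list is empty", "apms_value_error")
  hits <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    rows <- list()
    for (j in seq_len(nrow(proteins))) {
      m <- gregexpr(pep, proteins$sequence[j], fixed = TRUE)[[1]]
      if (m[1] != -1L)
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, accession = proteins$accession[j],
          start = as.integer(m), end = as.integer(m) + nchar(pep) - 1L,
          stringsAsFactors = FALSE)
    }
    hits[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  nonempty <- hits[!vapply(hits, is.null, TRUE)]
  hit_df <- if (length(nonempty))
    do.call(rbind, c(nonempty, list(make.row.names = FALSE)))
  else
    data.frame(peptide = character(), accession = character(),
               start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  n_acc <- vapply(peptides, function(p)
    length(unique(hit_df$accession[hit_df$peptide == p])), 1L)
  unmatched <- peptides[n_acc == 0L]
  if (length(unmatched))
    warning(sprintf("map_peptides: %d peptide(s) matched no protein (e.g. %s)",
                    length(unmatched), unmatched[1]), call. = FALSE)
  out <- list(
    hits = hit_df,
    peptides = data.frame(peptide = peptides, n_accessions = unname(n_acc),
                          unique = unname(n_acc == 1L),
                          stringsAsFactors = FALSE),
    accessions = proteins$accession)
  class(out) <- "peptide_map"
  out
}

#' @export
print.peptide_map <- function(x, ...) {
  cat(sprintf("peptide_map: %d peptides, %d hits, %d unique, %d unmatched\n",
              nrow(x$peptides), nrow(x$hits), sum(x$peptides$unique),
              sum(x$peptides$n_accessions == 0L)))
  invisible(x)
}

# accession -> set of uniquely mapping peptides, as a named list
unique_peptides_by_protein <- function(map) {
  uniq <- map$peptides$peptide[map$peptides$unique]
  h <- map$hits[map$hits$peptide %in% uniq, c("peptide", "accession")]
  h <- unique(h)
  split(h$peptide, factor(h$accession, levels = map$accessions))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline. Peptides with up to `missed_cleavages` internal
#' retained sites are generated and filtered to `[min_len, max_len]`.
#' With `missed_cleavages = 0` and no length filter the returned peptides
#' partition the sequence exactly.
#'
#' @param sequence amino-acid string.
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len peptide length bounds (inclusive).
#' @return data.frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive spans), ordered by start then length.
#' @export
#' @examples
#' digest("AKRP")           # "AK" then "RP" (no cleavage before proline)
digest <- function(sequence, missed_cleavages = 0L, min_len = 1L,
                   max_len = Inf) {
  check_sequence(sequence)
  if (min_len > max_len)
    abort("min_len must not exceed max_len", "apms_value_error")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)            # segment i spans bounds[i]+1..bounds[i+1]
  nseg <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > nseg) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      len <- end - start + 1L
      if (len >= min_len && len <= max_len)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(sequence, start, end),
          start = start, end = end, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}
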