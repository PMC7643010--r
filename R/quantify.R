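# SI_GI quantification and sequence coverage.
#
# The spectral index normalized to global intensity (SI_GI) of protein p in
# sample s is the share of the sample's total assigned PSM intensity carried
# by PSMs whose peptide maps uniquely to p:
#
#   SI(p, s)    = sum of intensities of unique-peptide PSMs of p in s
#   SI_GI(p, s) = SI(p, s) / sum of intensities of ALL retained PSMs in s
#
# Shared (non-unique) peptides contribute to the denominator but to no
# protein's numerator, so the denominator stays a property of the sample
# while double counting is avoided. Proteins supported by fewer than two
# distinct peptides are zeroed (band-level by default).

#' Spectral index of one protein in one sample
#'
#' Sum of PSM intensities whose peptide maps uniquely to `accession`
#' (optionally restricted to one `sample_id`). PSMs whose peptide maps to
#' several proteins contribute to no protein's spectral index.
#'
#' @param psms a `psm_table` data frame.
#' @param accession protein accession (must be known to `map`).
#' @param map a `peptide_map` built on the same protein database.
#' @param sample_id optional sample restriction.
#' @return A non-negative number; 0 when the protein has no qualifying PSMs.
#' @export
spectral_index <- function(psms, accession, map, sample_id = NULL) {
  if (!accession %in% map$accessions)
    abort(sprintf("unknown accession: %s", accession), "apms_value_error")
  peps <- unique_peptides_by_protein(map)[[accession]]
  rows <- psms$peptide %in% peps
  if (!is.null(sample_id)) rows <- rows & psms$sample_id == sample_id
  sum(psms$intensity[rows])
}

#' SI_GI quantification matrix
#'
#' Builds the proteins-by-samples grid of SI_GI values and distinct-peptide
#' counts. The global-intensity denominator of a sample is the summed
#' intensity of every retained PSM in that sample, including shared-peptide
#' PSMs; numerators use uniquely mapping peptides only. Proteins supported
#' by fewer than `min_peptides` distinct unique peptides are set to zero and
#' flagged; with `min_peptide_scope = "band"` (default) the peptide count is
#' pooled over all samples of the band, with `"sample"` it is per sample.
#'
#' @param psms a `psm_table` covering one or more samples; `sample_id`,
#'   `band`, `condition`, `replicate` must be consistent per sample.
#' @param proteins `protein_db`; defines the row universe (absent proteins
#'   get 0, which downstream stages rely on as the zero-fill).
#' @param map optional precomputed `peptide_map`; built if missing.
#' @param min_peptides minimum distinct peptides per protein (default 2).
#' @param min_peptide_scope `"band"` or `"sample"`.
#' @return An object of class `quant_matrix`: list with `si_gi` and
#'   `peptide_counts` matrices (proteins x samples), `samples` data.frame
#'   (`sample_id, band, condition, replicate`), and logical `flagged`
#'   matrix marking sub-threshold zeroed cells.
#' @export
si_gi_matrix <- function(psms, proteins, map = NULL, min_peptides = 2L,
                         min_peptide_scope = c("band", "sample")) {
  min_peptide_scope <- match.arg(min_peptide_scope)
  if (!nrow(psms)) abort("PSM table is empty", "apms_value_error")
  if (is.null(map)) map <- map_peptides(psms, proteins)

  meta <- unique(psms[c("sample_id", "band", "condition", "replicate")])
  if (anyDuplicated(meta$sample_id))
    abort("inconsistent band/condition/replicate within a sample_id",
          "apms_value_error")
  meta <- meta[order(meta$band, meta$condition, meta$replicate), ,
               drop = FALSE]
  rownames(meta) <- NULL
  samples <- meta$sample_id
  accs <- proteins$accession

  total <- vapply(samples, function(s)
    sum(psms$intensity[psms$sample_id == s]), 0)
  if (any(total <= 0))
    abort(sprintf("sample '%s' has zero total intensity",
                  samples[which(total <= 0)[1]]), "apms_value_error")

  # peptide -> owning accession for uniquely mapping peptides
  upp <- unique_peptides_by_protein(map)
  pep2acc <- setNames(rep(names(upp), lengths(upp)), unlist(upp))

  owner <- pep2acc[psms$peptide]            # NA for shared / unmatched
  si <- matrix(0, nrow = length(accs), ncol = length(samples),
               dimnames = list(accs, samples))
  counts <- matrix(0L, nrow = length(accs), ncol = length(samples),
                   dimnames = list(accs, samples))
  keep <- !is.na(owner)
  if (any(keep)) {
    agg <- tapply(psms$intensity[keep],
                  list(factor(owner[keep], levels = accs),
                       factor(psms$sample_id[keep], levels = samples)),
                  sum)
    agg[is.na(agg)] <- 0
    si[, ] <- agg
    cnt <- tapply(psms$peptide[keep],
                  list(factor(owner[keep], levels = accs),
                       factor(psms$sample_id[keep], levels = samples)),
                  function(p) length(unique(p)))
    cnt[is.na(cnt)] <- 0L
    counts[, ] <- cnt
  }

  flagged <- matrix(FALSE, nrow = length(accs), ncol = length(samples),
                    dimnames = list(accs, samples))
  if (min_peptides > 0L) {
    if (min_peptide_scope == "sample") {
      flagged <- counts > 0L & counts < min_peptides
    } else {
      band_of <- setNames(meta$band, meta$sample_id)
      psm_band <- band_of[psms$sample_id]
      for (b in unique(meta$band)) {
        cols <- samples[meta$band == b]
        sel <- keep & psm_band == b
        band_peps <- tapply(psms$peptide[sel],
                            factor(owner[sel], levels = accs),
                            function(p) length(unique(p)))
        band_peps[is.na(band_peps)] <- 0L
        low <- band_peps < min_peptides
        flagged[low, cols] <- counts[low, cols, drop = FALSE] > 0L |
          flagged[low, cols, drop = FALSE]
        si[low, cols] <- 0
      }
    }
    si[flagged] <- 0
  }
  si_gi <- sweep(si, 2L, total, `/`)

  out <- list(si_gi = si_gi, peptide_counts = counts, samples = meta,
              flagged = flagged, global_intensity = setNames(total, samples))
  class(out) <- "quant_matrix"
  out
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples (%s)\n",
              nrow(x$si_gi), ncol(x$si_gi),
              paste(unique(x$samples$band), collapse = ", ")))
  invisible(x)
}

#' Write / read a quantification matrix as TSV
#'
#' Proteins as rows, samples as columns, 6 significant digits.
#'
#' @param quant a `quant_matrix` (or plain matrix for `write_quant_matrix`).
#' @param path file path.
#' @return `path` invisibly; `read_quant_matrix` returns a numeric matrix.
#' @export
write_quant_matrix <- function(quant, path) {
  m <- if (inherits(quant, "quant_matrix")) quant$si_gi else quant
  df <- data.frame(accession = rownames(m),
                   signif(m, 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Sequence coverage of a protein by detected peptides
#'
#' A residue is covered when it lies inside at least one mapped peptide
#' span. Overall and per-region percentages are reported to two decimals.
#'
#' @param peptides character vector of detected peptide sequences.
#' @param protein one-row `protein_db` slice (or list with `accession` and
#'   `sequence`).
#' @param regions optional data.frame `label, start, end` (1-based
#'   inclusive) of regions to report separately, e.g. soluble termini.
#' @return An object of class `coverage_report`: list with `accession`,
#'   `covered_mask` (logical per residue), `coverage_percent`, and
#'   `region_coverage` data.frame (`label, start, end, percent`).
#' @export
sequence_coverage <- function(peptides, protein, regions = NULL) {
  seqc <- protein$sequence
  acc <- protein$accession
  n <- nchar(seqc)
  mask <- rep(FALSE, n)
  for (pep in unique(peptides)) {
    m <- gregexpr(pep, seqc, fixed = TRUE)[[1]]
    if (m[1] != -1L)
      for (s in as.integer(m)) mask[s:(s + nchar(pep) - 1L)] <- TRUE
  }
  region_df <- data.frame(label = character(), start = integer(),
                          end = integer(), percent = numeric(),
                          stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    if (any(regions$start < 1L | regions$end > n | regions$start > regions$end))
      abort(sprintf("region outside sequence bounds of %s (length %d)",
                    acc, n), "apms_value_error")
    region_df <- data.frame(
      label = regions$label, start = regions$start, end = regions$end,
      percent = vapply(seq_len(nrow(regions)), function(i)
        round(100 * mean(mask[regions$start[i]:regions$end[i]]), 2), 0),
      stringsAsFactors = FALSE)
  }
  out <- list(accession = acc, covered_mask = mask,
              coverage_percent = round(100 * mean(mask), 2),
              region_coverage = region_df)
  class(out) <- "coverage_report"
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %s %.2f%% of %d residues\n",
              x$accession, x$coverage_percent, length(x$covered_mask)))
  if (nrow(x$region_coverage))
    for (i in seq_len(nrow(x$region_coverage)))
      cat(sprintf("  %s (%d-%d): %.2f%%\n", x$region_coverage$label[i],
                  x$region_coverage$start[i], x$region_coverage$end[i],
                  x$region_coverage$percent[i]))
  invisible(x)
}
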