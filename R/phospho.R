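# A-score phosphosite localization.
#
# The A-score quantifies how well a fragment spectrum discriminates between
# alternative placements of a phospho group on the same peptide. For each
# candidate isoform, singly protonated b/y ions are matched against the
# spectrum reduced to its d most intense peaks per 100 m/z window
# (d = 1..10); the chance of k of n theoretical ions matching by luck is the
# cumulative binomial tail P(X >= k) with success probability d/100, and
# -10*log10 of that tail is the peptide score at depth d. Isoforms are
# ranked by a fixed depth-weighted sum of these scores; the A-score of the
# winning placement is the score difference between the top two isoforms
# computed on their site-determining ions only, at the peak depth where the
# full peptide scores separate most.

# depth weights of the weighted peptide score (depths 1..10)
ASCORE_WEIGHTS <- c(0.5, 0.75, 1, 1, 1, 1, 0.75, 0.5, 0.25, 0.25)

# sentinel A-score for placements with no competing isoform
ASCORE_SENTINEL <- 1000

#' Theoretical b/y fragment ions of a (phospho)peptide isoform
#'
#' Computes singly protonated monoisotopic b- and y-ion m/z values for
#' fragment indices 1..len-1. Ions whose residue span covers a phosphosite
#' are shifted by +79.9663 Da.
#'
#' @param peptide amino-acid string.
#' @param phospho_positions integer vector of 1-based phosphosite positions;
#'   each must fall on S, T or Y.
#' @return object of class `site_isoform`: list with `peptide`,
#'   `phospho_positions` and `ions` (data.frame `series, index, mz`).
#' @export
theoretical_ions <- function(peptide, phospho_positions = integer()) {
  check_sequence(peptide)
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(res)
  phospho_positions <- as.integer(phospho_positions)
  if (length(phospho_positions)) {
    if (any(phospho_positions < 1L | phospho_positions > n))
      abort("phospho position outside peptide", "apms_value_error")
    if (any(!res[phospho_positions] %in% c("S", "T", "Y")))
      abort(sprintf("phospho position not on S/T/Y in '%s'", peptide),
            "apms_value_error")
  }
  masses <- AA_MONO[res]
  csum <- cumsum(masses)
  idx <- seq_len(n - 1L)
  n_phos_prefix <- vapply(idx, function(i)
    sum(phospho_positions <= i), 1L)
  b <- csum[idx] + MASS_PROTON + MASS_PHOSPHO * n_phos_prefix
  y <- (csum[n] - csum[n - idx]) + MASS_H2O + MASS_PROTON +
    MASS_PHOSPHO * (length(phospho_positions) - n_phos_prefix[n - idx])
  ions <- data.frame(
    series = rep(c("b", "y"), each = n - 1L),
    index = c(idx, idx),
    mz = c(b, y),
    stringsAsFactors = FALSE)
  out <- list(peptide = peptide,
              phospho_positions = sort(phospho_positions), ions = ions)
  class(out) <- "site_isoform"
  out
}

#' Reduce a spectrum to its d most intense peaks per 100 m/z window
#'
#' Windows are contiguous `[0,100), [100,200), ...` intervals. Within each
#' window the `depth` most intense peaks are kept; intensity ties are
#' broken in favour of the lower m/z.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @param depth integer in 1..10.
#' @return the reduced peak data.frame, sorted by m/z.
#' @export
reduce_to_depth <- function(peaks, depth) {
  depth <- as.integer(depth)
  if (depth < 1L || depth > 10L)
    abort("depth must be between 1 and 10", "apms_value_error")
  if (!nrow(peaks)) return(peaks)
  win <- floor(peaks$mz / 100)
  ord <- order(win, -peaks$intensity, peaks$mz)
  peaks <- peaks[ord, , drop = FALSE]
  win <- win[ord]
  rank_in_win <- stats::ave(seq_along(win), win, FUN = seq_along)
  out <- peaks[rank_in_win <= depth, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper tail of the binomial distribution
#'
#' P(X >= k) for X ~ Binomial(n, pi), evaluated in log space internally so
#' extremely small tails (many matched ions at low peak depth) do not
#' underflow inside the score computation.
#'
#' @param n_trials number of trials (theoretical ions considered).
#' @param k_success number of successes (matched ions).
#' @param pi per-trial success probability, in (0, 1).
#' @return P(X >= k).
#' @export
binomial_tail <- function(n_trials, k_success, pi) {
  if (k_success < 0 || k_success > n_trials)
    abort("k_success must lie in [0, n_trials]", "apms_value_error")
  if (pi <= 0 || pi >= 1)
    abort("pi must lie in (0, 1)", "apms_value_error")
  if (k_success == 0) return(1)
  pbinom(k_success - 1, n_trials, pi, lower.tail = FALSE)
}

# -10*log10 P(X >= k); log-space so pi^n never underflows to -Inf scores
binom_score <- function(n_trials, k_success, pi) {
  if (k_success == 0) return(0)
  lp <- pbinom(k_success - 1, n_trials, pi, lower.tail = FALSE, log.p = TRUE)
  -10 * lp / log(10)
}

# number of theoretical ions with at least one peak within +/- tolerance
count_matches <- function(ion_mz, peak_mz, tolerance) {
  if (!length(peak_mz)) return(0L)
  peak_mz <- sort(peak_mz)
  lo <- findInterval(ion_mz - tolerance, peak_mz)
  hi <- findInterval(ion_mz + tolerance, peak_mz)
  sum(hi > lo)
}

#' Depth-profiled peptide score of one isoform against a spectrum
#'
#' For every peak depth d = 1..10, matches the isoform's theoretical ions
#' against the depth-reduced spectrum and scores the match count with the
#' binomial tail at success probability d/100. The weighted score combines
#' the ten depth scores with fixed weights
#' (0.5, 0.75, 1, 1, 1, 1, 0.75, 0.5, 0.25, 0.25).
#'
#' @param peaks spectrum peak data.frame (`mz`, `intensity`).
#' @param isoform a `site_isoform` from [theoretical_ions()].
#' @param tolerance fragment match tolerance in Da (default 0.05).
#' @return list with `depth_scores` (length 10), `matched` (matched-ion
#'   counts per depth), `n_ions`, `weighted`.
#' @export
peptide_score <- function(peaks, isoform, tolerance = 0.05) {
  if (tolerance <= 0)
    abort("tolerance must be positive", "apms_value_error")
  n <- nrow(isoform$ions)
  depth_scores <- numeric(10)
  matched <- integer(10)
  if (nrow(peaks)) {
    for (d in 1:10) {
      reduced <- reduce_to_depth(peaks, d)
      k <- count_matches(isoform$ions$mz, reduced$mz, tolerance)
      matched[d] <- k
      depth_scores[d] <- binom_score(n, k, d / 100)
    }
  }
  list(depth_scores = depth_scores, matched = matched, n_ions = n,
       weighted = sum(ASCORE_WEIGHTS * depth_scores) / sum(ASCORE_WEIGHTS))
}

# site-determining ions between two isoforms: ions of `a` whose m/z has no
# counterpart (same series+index) of equal m/z in `b`
site_determining <- function(a, b) {
  key_a <- paste(a$ions$series, a$ions$index)
  key_b <- paste(b$ions$series, b$ions$index)
  mz_b <- setNames(b$ions$mz, key_b)
  differ <- abs(a$ions$mz - mz_b[key_a]) > 1e-6
  a$ions$mz[differ]
}

# pairwise A-score between two isoforms on their site-determining ions,
# evaluated at the depth where the full peptide scores separate most
# (ties -> lower depth); clamped at zero
pairwise_ascore <- function(peaks, best, other, tolerance,
                            ps_best = NULL, ps_other = NULL) {
  ps_best <- ps_best %||% peptide_score(peaks, best, tolerance)
  ps_other <- ps_other %||% peptide_score(peaks, other, tolerance)
  sep <- ps_best$depth_scores - ps_other$depth_scores
  d <- which.max(sep)                      # which.max takes the first (lowest)
  sd_best <- site_determining(best, other)
  sd_other <- site_determining(other, best)
  n_sd <- length(sd_best)
  if (!n_sd) return(list(A = 0, depth = as.integer(d)))
  reduced <- reduce_to_depth(peaks, d)
  k1 <- count_matches(sd_best, reduced$mz, tolerance)
  k2 <- count_matches(sd_other, reduced$mz, tolerance)
  A <- binom_score(n_sd, k1, d / 100) - binom_score(length(sd_other), k2, d / 100)
  list(A = max(A, 0), depth = as.integer(d))
}

#' A-score phosphosite localization for one spectrum
#'
#' Enumerates all placements of `n_phospho` phospho groups on the
#' peptide's S/T/Y residues, ranks them by weighted peptide score, and
#' computes for every site of the winning isoform an A-score against the
#' best-scoring competing isoform that does not carry that site. When the
#' nearest competitor places the phospho on an adjacent residue and the
#' A-score is low, downstream aggregation merges the pair into a composite
#' site; the score against the best isoform avoiding both residues is
#' therefore also reported (`A_composite`). Peptides with a single
#' candidate site are unambiguous and get the sentinel A-score 1000.
#'
#' @param peaks spectrum peak data.frame (`mz`, `intensity`).
#' @param peptide peptide sequence.
#' @param n_phospho number of phospho groups carried (default 1).
#' @param tolerance fragment match tolerance in Da.
#' @return object of class `ascore_outcome`: list with `peptide`,
#'   `best` / `second` (`site_isoform`s; `second` may be NULL),
#'   `weighted_scores` (named by isoform), `optimal_depth`, and `sites`,
#'   a data.frame with one row per site of the best isoform: `site`,
#'   `residue`, `A`, `alt_site`, `adjacent`, `A_composite`.
#' @export
ascore <- function(peaks, peptide, n_phospho = 1L, tolerance = 0.05) {
  check_sequence(peptide)
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  candidates <- which(res %in% c("S", "T", "Y"))
  if (n_phospho > length(candidates))
    abort(sprintf("peptide '%s' has %d candidate site(s), fewer than n_phospho = %d",
                  peptide, length(candidates), n_phospho),
          "apms_value_error")
  # index-based combn: a length-1 candidate vector must not be treated
  # as combn's scalar shorthand for 1:n
  combos <- lapply(combn(seq_along(candidates), n_phospho,
                         simplify = FALSE),
                   function(i) candidates[i])
  isoforms <- lapply(combos, function(p) theoretical_ions(peptide, p))
  labels <- vapply(combos, function(p) paste(p, collapse = "+"), "")
  pscores <- lapply(isoforms, peptide_score, peaks = peaks,
                    tolerance = tolerance)
  weighted <- vapply(pscores, `[[`, 0, "weighted")
  ord <- order(-weighted, labels)          # deterministic tie-break
  best <- isoforms[[ord[1]]]

  sites <- data.frame(site = best$phospho_positions,
                      residue = res[best$phospho_positions],
                      A = NA_real_, alt_site = NA_integer_,
                      adjacent = FALSE, A_composite = NA_real_,
                      stringsAsFactors = FALSE)
  second <- NULL
  optimal_depth <- NA_integer_
  if (length(isoforms) > 1L) {
    second <- isoforms[[ord[2]]]
    top_pair <- pairwise_ascore(peaks, best, second, tolerance,
                                pscores[[ord[1]]], pscores[[ord[2]]])
    optimal_depth <- top_pair$depth
  }
  for (i in seq_len(nrow(sites))) {
    s <- sites$site[i]
    alt_idx <- ord[vapply(ord, function(j)
      !s %in% isoforms[[j]]$phospho_positions, TRUE)]
    if (!length(alt_idx)) {
      sites$A[i] <- ASCORE_SENTINEL
      next
    }
    j <- alt_idx[1]
    alt <- isoforms[[j]]
    pa <- pairwise_ascore(peaks, best, alt, tolerance,
                          pscores[[ord[1]]], pscores[[j]])
    sites$A[i] <- pa$A
    gained <- setdiff(alt$phospho_positions, best$phospho_positions)
    if (length(gained)) {
      near <- gained[which.min(abs(gained - s))]
      sites$alt_site[i] <- near
      sites$adjacent[i] <- abs(near - s) == 1L
      if (sites$adjacent[i]) {
        away <- ord[vapply(ord, function(jj) {
          p <- isoforms[[jj]]$phospho_positions
          !s %in% p && !near %in% p
        }, TRUE)]
        sites$A_composite[i] <- if (!length(away)) ASCORE_SENTINEL else
          pairwise_ascore(peaks, best, isoforms[[away[1]]], tolerance,
                          pscores[[ord[1]]], pscores[[away[1]]])$A
      }
    }
  }
  out <- list(peptide = peptide, best = best, second = second,
              weighted_scores = setNames(weighted, labels)[ord],
              optimal_depth = optimal_depth, sites = sites)
  class(out) <- "ascore_outcome"
  out
}

#' Percent confidence implied by an A-score
#'
#' `confidence = 100 * (1 - 10^(-A/10))`: an A-score of 15 maps to about
#' 96.8% (the >90% band) and 20 to exactly 99% (the >99% band).
#'
#' @param A non-negative A-score (vectorized).
#' @return percent confidence in `[0, 100)`.
#' @export
confidence_from_ascore <- function(A) {
  if (any(A < 0)) abort("A-score must be non-negative", "apms_value_error")
  100 * (1 - 10^(-A / 10))
}

#' Aggregate per-spectrum site calls into a protein site table
#'
#' Converts peptide-level sites to protein coordinates (via the peptide
#' map, or a `protein_pos` column when `map` is NULL), subtracts the
#' mature-sequence offset, merges ambiguous adjacent placements into
#' composite labels ("S25/26" style), and counts detections per confidence
#' band: `n_detect_mid` for A in \[15, 19\], `n_detect_high` for A > 19.
#' Each input row is one detection (PSM-level counting), so counts across
#' replicates can exceed the number of experiments.
#'
#' For a composite site the banding uses the A-score against the best
#' isoform avoiding both adjacent residues (`A_composite`): the phospho
#' group is confidently localized to the residue pair even when the two
#' neighbours cannot be told apart.
#'
#' @param calls data.frame with one row per detected site: columns
#'   `accession, peptide, replicate, site, residue, A, alt_site, adjacent,
#'   A_composite` (see [ascore_site_table()]), plus `protein_pos` when no
#'   map is given.
#' @param map optional `peptide_map`; every peptide must map uniquely.
#' @param mature_offset signal-peptide length subtracted from protein
#'   coordinates (default 0).
#' @param ambiguity A-score below which an adjacent alternative triggers a
#'   composite label (default 15).
#' @return data.frame of class `phospho_site_table`: `accession,
#'   site_label, position, n_detect_mid, n_detect_high, max_ascore`,
#'   sorted by position. `position` is the (first) mature coordinate.
#' @export
aggregate_sites <- function(calls, map = NULL, mature_offset = 0L,
                            ambiguity = 15) {
  if (!nrow(calls))
    abort("no site calls to aggregate", "apms_value_error")
  if (is.null(map)) {
    if (!"protein_pos" %in% names(calls))
      abort("either a peptide map or a protein_pos column is required",
            "apms_value_error")
    pos <- calls$protein_pos
    alt_pos <- ifelse(is.na(calls$alt_site), NA_integer_,
                      calls$protein_pos - calls$site + calls$alt_site)
  } else {
    starts <- map$hits[!duplicated(map$hits$peptide), ]
    uniq <- map$peptides$peptide[map$peptides$unique]
    idx <- match(calls$peptide, starts$peptide)
    if (anyNA(idx) || !all(calls$peptide %in% uniq))
      abort(sprintf("peptide '%s' is not uniquely mapped",
                    calls$peptide[which(is.na(idx) |
                                          !calls$peptide %in% uniq)[1]]),
            "apms_value_error")
    pos <- starts$start[idx] + calls$site - 1L
    alt_pos <- starts$start[idx] + calls$alt_site - 1L
  }
  pos <- pos - mature_offset
  alt_pos <- alt_pos - mature_offset

  composite <- !is.na(calls$adjacent) & calls$adjacent & calls$A < ambiguity
  eff_A <- ifelse(composite,
                  ifelse(is.na(calls$A_composite), ASCORE_SENTINEL,
                         calls$A_composite),
                  calls$A)
  label <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (composite[i]) {
      p <- sort(c(pos[i], alt_pos[i]))
      label[i] <- paste0(calls$residue[i], p[1], "/", p[2])
    } else {
      label[i] <- paste0(calls$residue[i], pos[i])
    }
  }
  key <- paste(calls$accession, label, sep = "\r")
  agg <- lapply(split(seq_len(nrow(calls)), key), function(rows) {
    data.frame(accession = calls$accession[rows[1]],
               site_label = label[rows[1]],
               position = min(pos[rows]),
               n_detect_mid = sum(eff_A[rows] >= 15 & eff_A[rows] <= 19),
               n_detect_high = sum(eff_A[rows] > 19),
               max_ascore = max(eff_A[rows]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phospho_site_table", "data.frame")
  out
}

#' Score a batch of spectra and tabulate per-site calls
#'
#' Runs [ascore()] over assigned spectra and returns the flat per-detection
#' site table consumed by [aggregate_sites()].
#'
#' @param spectra list of spectra as returned by [read_mgf()].
#' @param assignments data.frame `spectrum_id, peptide, accession,
#'   replicate, n_phospho`.
#' @param tolerance fragment match tolerance in Da.
#' @return data.frame with one row per (spectrum, site): `spectrum_id,
#'   accession, peptide, replicate, site, residue, A, alt_site, adjacent,
#'   A_composite`.
#' @export
ascore_site_table <- function(spectra, assignments, tolerance = 0.05) {
  ids <- vapply(spectra, `[[`, "", "spectrum_id")
  rows <- list()
  for (i in seq_len(nrow(assignments))) {
    idx <- match(assignments$spectrum_id[i], ids)
    if (is.na(idx))
      abort(sprintf("spectrum '%s' not found in MGF input",
                    assignments$spectrum_id[i]), "apms_value_error")
    sp <- spectra[[idx]]
    out <- ascore(sp$peaks, assignments$peptide[i],
                  n_phospho = assignments$n_phospho[i] %||% 1L,
                  tolerance = tolerance)
    s <- out$sites
    s$spectrum_id <- assignments$spectrum_id[i]
    s$accession <- assignments$accession[i]
    s$peptide <- assignments$peptide[i]
    s$replicate <- assignments$replicate[i]
    rows[[length(rows) + 1L]] <- s
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df[c("spectrum_id", "accession", "peptide", "replicate", "site",
       "residue", "A", "alt_site", "adjacent", "A_composite")]
}
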