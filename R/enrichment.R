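# Bait-vs-IgG enrichment: Welch t-test, replicate-consistency filter,
# Venn-style overlap accounting.

#' Welch's unequal-variance t-test
#'
#' Two-sided test of mean difference with the Welch-Satterthwaite degrees of
#' freedom. Implemented directly (not via [stats::t.test()]) so that the
#' degenerate zero-variance case can be surfaced as a classed condition for
#' the caller to resolve.
#'
#' @param x,y numeric vectors of length >= 2.
#' @return list with elements `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3, 4), c(5, 6, 7, 8))  # t ~ -4.38, df = 6, p ~ 0.0047
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    abort("welch_t needs at least two observations per group",
          "apms_value_error")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0)
    abort("both sample variances are zero (degenerate input)",
          "apms_degenerate_error")
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1L) +
                   (vy / length(y))^2 / (length(y) - 1L))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Bait-vs-control enrichment for one band
#'
#' For every protein in the quantification matrix, tests bait against
#' control SI_GI values (missing detections enter as 0, the zero-fill
#' convention) with [welch_t()]. A protein is `significant` when its
#' (optionally BH-adjusted) p-value is below `alpha` AND its bait mean
#' exceeds its control mean; it is `consistent` when detected (SI_GI > 0)
#' in every bait replicate. Degenerate all-zero-variance proteins get
#' p = 1 when the means are identical, otherwise p = 0 with
#' `degenerate = TRUE`.
#'
#' @param quant a `quant_matrix`.
#' @param band band label present in `quant$samples$band`.
#' @param alpha significance level (default 0.05, uncorrected: the
#'   all-replicates filter is the de-facto error control; see `p_adjust`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `enrichment_result`, one row per protein,
#'   sorted by descending bait mean, with columns `accession, band,
#'   mean_bait, mean_control, t_stat, df, p_value, n_bait_detected,
#'   significant, consistent, degenerate`.
#' @export
enrich_band <- function(quant, band, alpha = 0.05,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  meta <- quant$samples
  if (!band %in% meta$band)
    abort(sprintf("band '%s' absent from quantification matrix", band),
          "apms_value_error")
  bait_cols <- meta$sample_id[meta$band == band & meta$condition == "bait"]
  ctrl_cols <- meta$sample_id[meta$band == band & meta$condition == "control"]
  if (length(bait_cols) < 2L || length(ctrl_cols) < 2L)
    abort(sprintf("band '%s' needs >= 2 bait and >= 2 control samples", band),
          "apms_value_error")
  X <- quant$si_gi[, bait_cols, drop = FALSE]
  Y <- quant$si_gi[, ctrl_cols, drop = FALSE]
  n <- nrow(X)
  t_stat <- df <- p <- rep(NA_real_, n)
  degenerate <- rep(FALSE, n)
  for (i in seq_len(n)) {
    res <- tryCatch(welch_t(X[i, ], Y[i, ]), apms_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      degenerate[i] <- TRUE
      if (isTRUE(all.equal(mean(X[i, ]), mean(Y[i, ])))) {
        t_stat[i] <- 0; p[i] <- 1
      } else {
        t_stat[i] <- sign(mean(X[i, ]) - mean(Y[i, ])) * Inf; p[i] <- 0
      }
    } else {
      t_stat[i] <- res$t; df[i] <- res$df; p[i] <- res$p
    }
  }
  p_used <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  mean_bait <- rowMeans(X)
  mean_control <- rowMeans(Y)
  out <- data.frame(
    accession = rownames(X), band = band,
    mean_bait = mean_bait, mean_control = mean_control,
    t_stat = t_stat, df = df, p_value = p,
    n_bait_detected = as.integer(rowSums(X > 0)),
    significant = p_used < alpha & mean_bait > mean_control,
    consistent = rowSums(X > 0) == length(bait_cols),
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_bait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Exclusive-region overlap counts for 2-4 named sets
#'
#' Computes the count of every exclusive Venn region. Regions are labelled
#' by the names of the sets that own them joined with an intersection sign,
#' e.g. `"300kDa∩600kDa"`; a single name labels elements exclusive to that
#' set. The counts over all regions sum to the size of the union.
#'
#' @param sets named list of 2-4 character vectors.
#' @return named integer vector over all 2^k - 1 regions.
#' @export
overlap_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L)
    abort("overlap_counts supports 2 to 4 named sets", "apms_value_error")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("sets must be named", "apms_value_error")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  out <- integer()
  for (size in seq_len(k)) {
    combos <- combn(names(sets), size, simplify = FALSE)
    for (cmb in combos) {
      inside <- if (length(universe))
        rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
          rowSums(member[, setdiff(names(sets), cmb), drop = FALSE]) == 0
      else logical(0)
      out[paste(cmb, collapse = "∩")] <- sum(inside)
    }
  }
  out
}
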