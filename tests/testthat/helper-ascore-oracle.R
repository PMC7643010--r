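# independent re-implementation of the full A-score definition with plain
# loops and explicit binomial sums, used as an oracle on noisy spectra
ascore_oracle <- function(peaks, pep, tolerance = 0.05) {
  res <- strsplit(pep, "")[[1]]
  cand <- which(res %in% c("S", "T", "Y"))
  w <- c(0.5, 0.75, 1, 1, 1, 1, 0.75, 0.5, 0.25, 0.25)
  tail_log10 <- function(n, k, pi) {
    if (k == 0) return(0)
    pbinom(k - 1, n, pi, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  reduce <- function(d) {
    kept <- NULL
    for (win in unique(floor(peaks$mz / 100))) {
      sub <- peaks[floor(peaks$mz / 100) == win, ]
      sub <- sub[order(-sub$intensity, sub$mz), ]
      kept <- rbind(kept, head(sub, d))
    }
    kept
  }
  nmatch <- function(mzs, kept)
    sum(vapply(mzs, function(m)
      any(abs(kept$mz - m) <= tolerance), TRUE))
  iso <- lapply(cand, function(p) theoretical_ions(pep, p))
  score <- matrix(0, length(iso), 10)
  for (d in 1:10) {
    kept <- reduce(d)
    for (i in seq_along(iso))
      score[i, d] <- -10 * tail_log10(nrow(iso[[i]]$ions),
                                      nmatch(iso[[i]]$ions$mz, kept),
                                      d / 100)
  }
  weighted <- as.numeric(score %*% w) / sum(w)
  ord <- order(-weighted, vapply(iso, function(x)
    paste(x$phospho_positions, collapse = "+"), ""))
  best <- iso[[ord[1]]]; second <- iso[[ord[2]]]
  d_opt <- which.max(score[ord[1], ] - score[ord[2], ])
  sd_best <- best$ions$mz[abs(best$ions$mz - second$ions$mz) > 1e-6]
  sd_second <- second$ions$mz[abs(second$ions$mz - best$ions$mz) > 1e-6]
  kept <- reduce(d_opt)
  A <- -10 * tail_log10(length(sd_best), nmatch(sd_best, kept), d_opt / 100) +
    10 * tail_log10(length(sd_second), nmatch(sd_second, kept), d_opt / 100)
  list(best_site = best$phospho_positions, A = max(A, 0),
       depth = as.integer(d_opt))
}
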