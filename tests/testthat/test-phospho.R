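# A-score phosphosite localization

test_that("theoretical ions match independent monoisotopic arithmetic", {
  gg <- theoretical_ions("GG")
  expect_equal(gg$ions$mz[gg$ions$series == "b"], 58.0287, tolerance = 1e-4)
  expect_equal(gg$ions$mz[gg$ions$series == "y"], 76.0393, tolerance = 1e-4)

  # length n -> 2(n-1) ions
  for (pep in c("ACDEK", "GG", "LSGGTVK"))
    expect_equal(nrow(theoretical_ions(pep)$ions), 2 * (nchar(pep) - 1))

  # phospho shifts exactly the ions whose span covers the site
  pep <- "ASATAK"
  plain <- theoretical_ions(pep)$ions
  phos <- theoretical_ions(pep, 2)$ions
  shift <- phos$mz - plain$mz
  covers <- ifelse(phos$series == "b", phos$index >= 2,
                   phos$index >= nchar(pep) - 2 + 1)
  expect_equal(shift[covers], rep(79.9663, sum(covers)))
  expect_equal(shift[!covers], rep(0, sum(!covers)))

  # independent oracle: b/y from an explicitly summed mass table
  masses <- c(A = 71.03711, S = 87.03203, T = 101.04768, K = 128.09496)
  b3 <- sum(masses[c("A", "S", "A")]) + 1.007276 + 79.9663
  expect_equal(phos$mz[phos$series == "b" & phos$index == 3], b3,
               tolerance = 1e-6)
  y2 <- sum(masses[c("A", "K")]) + 18.010565 + 1.007276
  expect_equal(phos$mz[phos$series == "y" & phos$index == 2], y2,
               tolerance = 1e-6)

  expect_error(theoretical_ions("ASATAK", 3), class = "apms_value_error")
  expect_error(theoretical_ions("ASATAK", 9), class = "apms_value_error")
})

test_that("reduce_to_depth keeps the d most intense peaks per 100 m/z window", {
  peaks <- data.frame(mz = c(10, 20, 30, 40, 50), intensity = c(5, 9, 7, 9, 1))
  r2 <- reduce_to_depth(peaks, 2)
  expect_equal(r2$mz, c(20, 40))          # intensity tie 9/9: both top-2
  r1 <- reduce_to_depth(peaks, 1)
  expect_equal(r1$mz, 20)                 # tie broken toward lower m/z

  # d = 10 with fewer than 10 peaks per window: identity
  expect_equal(reduce_to_depth(peaks, 10)$mz, peaks$mz)

  # peaks straddling a window boundary fall in different windows
  edge <- data.frame(mz = c(99.9, 100.1), intensity = c(1, 2))
  expect_equal(reduce_to_depth(edge, 1)$mz, c(99.9, 100.1))

  expect_error(reduce_to_depth(peaks, 0), class = "apms_value_error")
  expect_error(reduce_to_depth(peaks, 11), class = "apms_value_error")
})

test_that("binomial_tail matches brute-force enumeration for n <= 25", {
  brute <- function(n, k, pi)
    sum(vapply(k:n, function(j)
      choose(n, j) * pi^j * (1 - pi)^(n - j), 0))
  expect_equal(binomial_tail(2, 1, 0.5), 0.75)
  expect_equal(binomial_tail(5, 5, 0.1), 1e-5)
  expect_equal(binomial_tail(7, 0, 0.3), 1)
  set.seed(13)
  for (n in 1:25) {
    for (k in unique(c(0L, 1L, n %/% 2L, n))) {
      for (pi in c(0.01, 0.05, 0.1, 0.5, 0.9)) {
        expect_equal(binomial_tail(n, k, pi), brute(n, k, pi),
                     tolerance = 1e-12,
                     label = sprintf("n=%d k=%d pi=%g", n, k, pi))
      }
    }
  }
  expect_error(binomial_tail(5, 6, 0.5), class = "apms_value_error")
  expect_error(binomial_tail(5, 2, 0), class = "apms_value_error")
})

test_that("peptide_score reproduces the binomial arithmetic", {
  pep <- "ACDEK"                           # 8 theoretical ions
  iso <- theoretical_ions(pep)
  # spectrum = exactly the 8 theoretical peaks
  peaks <- data.frame(mz = iso$ions$mz, intensity = 100)
  ps <- peptide_score(peaks, iso)
  # at depth 5 every window (equal intensities, <= 5 ions per window)
  # retains all theoretical peaks
  expect_equal(ps$matched[5], 8L)
  # all n = 8 ions present at depth 5: -10 log10(0.05^8) ~ 104.1
  expect_equal(ps$depth_scores[5], -10 * log10(0.05^8), tolerance = 1e-10)
  expect_equal(ps$depth_scores[5], 104.08, tolerance = 0.01)
  w <- c(0.5, 0.75, 1, 1, 1, 1, 0.75, 0.5, 0.25, 0.25)
  expect_equal(ps$weighted, sum(w * ps$depth_scores) / sum(w))

  # spectrum with no theoretical ion: all-zero scores
  noise <- data.frame(mz = iso$ions$mz + 10, intensity = 100)
  expect_equal(peptide_score(noise, iso)$depth_scores, rep(0, 10))
  # empty spectrum: zero
  expect_equal(peptide_score(peaks[0, ], iso)$depth_scores, rep(0, 10))

  # deleting peaks never increases any depth score
  set.seed(23)
  for (i in 1:5) {
    keep <- sample(nrow(peaks), sample(2:7, 1))
    ps_sub <- peptide_score(peaks[keep, ], iso)
    expect_true(all(ps_sub$depth_scores <= ps$depth_scores + 1e-12))
  }
})

test_that("ascore localizes a clean planted site with the analytic score", {
  pep <- "ASATAK"                          # candidates S2 and T4, 4 SD ions
  true_iso <- theoretical_ions(pep, 2)
  peaks <- data.frame(mz = true_iso$ions$mz, intensity = 1000)
  out <- ascore(peaks, pep, n_phospho = 1)
  expect_s3_class(out, "ascore_outcome")
  expect_equal(out$best$phospho_positions, 2L)
  # noise-free: at the optimal depth all 4 site-determining ions of the
  # true isoform are matched and none of the alternative's, so
  # A = -10 log10(P(X >= 4 | n = 4, pi = d/100)) = -40 log10(d/100)
  s2 <- out$sites[out$sites$site == 2, ]
  expect_equal(s2$A, -40 * log10(out$optimal_depth / 100),
               tolerance = 1e-10)
  expect_gt(s2$A, 19)
  expect_equal(s2$alt_site, 4L)
  expect_false(s2$adjacent)
  # and the full outcome agrees with the independent oracle
  ref <- ascore_oracle(peaks, pep)
  expect_equal(s2$A, ref$A, tolerance = 1e-10)
  expect_equal(out$optimal_depth, ref$depth)

  # spectrum with no site-determining ions for either isoform -> A = 0
  shared <- theoretical_ions(pep, 2)$ions
  alt <- theoretical_ions(pep, 4)$ions
  shared_mz <- shared$mz[abs(shared$mz - alt$mz) < 1e-9]
  out0 <- ascore(data.frame(mz = shared_mz, intensity = 10), pep)
  expect_equal(out0$sites$A[1], 0)

  # single-candidate peptide: sentinel A, site assigned
  out1 <- ascore(peaks, "AASAAK", n_phospho = 1)
  expect_equal(out1$sites$site, 3L)
  expect_equal(out1$sites$A, 1000)

  expect_error(ascore(peaks, "AAGGK", n_phospho = 1),
               class = "apms_value_error")
})


test_that("ascore agrees with an independent oracle on noisy spectra", {
  set.seed(33)
  peptides <- c("ASATAK", "LSGGTVK", "GSAGTGK", "AYAAASAK")
  for (rep in 1:8) {
    pep <- peptides[(rep - 1) %% length(peptides) + 1]
    cand <- which(strsplit(pep, "")[[1]] %in% c("S", "T", "Y"))
    site <- cand[sample.int(length(cand), 1)]
    iso <- theoretical_ions(pep, site)
    n_win <- ceiling(max(iso$ions$mz) / 100)
    noise <- data.frame(
      mz = runif(n_win * 8, 0, 100) + rep(100 * (seq_len(n_win) - 1),
                                          each = 8),
      intensity = runif(n_win * 8, 1, 500))
    # random subset of true ions present
    present <- sample(nrow(iso$ions), sample(3:nrow(iso$ions), 1))
    peaks <- rbind(data.frame(mz = iso$ions$mz[present],
                              intensity = runif(length(present), 600, 1000)),
                   noise)
    got <- ascore(peaks, pep)
    ref <- ascore_oracle(peaks, pep)
    expect_equal(got$best$phospho_positions, ref$best_site)
    expect_equal(got$optimal_depth, ref$depth)
    pairwise <- got$sites$A[got$sites$site == ref$best_site[1]]
    # oracle computes best-vs-second; equal when the nearest competitor
    # excluding the site IS the second-ranked isoform (single phospho)
    expect_equal(pairwise, ref$A, tolerance = 1e-10)
  }
})

test_that("ascore is invariant to peak order and intensity rescaling", {
  set.seed(43)
  pep <- "LSGGTVK"
  iso <- theoretical_ions(pep, 2)
  peaks <- rbind(data.frame(mz = iso$ions$mz, intensity = runif(12, 500, 900)),
                 data.frame(mz = runif(40, 100, 800),
                            intensity = runif(40, 1, 400)))
  out <- ascore(peaks, pep)
  out_sh <- ascore(peaks[sample(nrow(peaks)), ], pep)
  expect_equal(out_sh$sites, out$sites)
  peaks2 <- peaks; peaks2$intensity <- peaks2$intensity * 1e3
  out_sc <- ascore(peaks2, pep)
  expect_equal(out_sc$sites, out$sites)
})

test_that("decreasing tolerance never increases matched-ion counts", {
  set.seed(53)
  iso <- theoretical_ions("LSGGTVK", 2)
  peaks <- data.frame(mz = iso$ions$mz + runif(12, -0.06, 0.06),
                      intensity = 100)
  tols <- c(0.2, 0.1, 0.05, 0.02, 0.01)
  counts <- vapply(tols, function(tl)
    peptide_score(peaks, iso, tolerance = tl)$matched[10], 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("confidence mapping matches the closed form", {
  expect_equal(confidence_from_ascore(0), 0)
  expect_equal(confidence_from_ascore(20), 99)
  expect_equal(confidence_from_ascore(15), 96.8377, tolerance = 1e-4)
  expect_gt(confidence_from_ascore(15), 90)
  expect_error(confidence_from_ascore(-1), class = "apms_value_error")
})

test_that("aggregate_sites counts confidence bands and merges adjacent pairs", {
  calls <- data.frame(
    accession = "P1", peptide = "X", replicate = rep(1:4, 3),
    site = 5L, residue = "S", A = rep(25, 12), alt_site = NA_integer_,
    adjacent = FALSE, A_composite = NA_real_, protein_pos = 940L,
    stringsAsFactors = FALSE)
  # 4 replicates x A = 25 at site 940, plus 17s at another site
  calls$A[5:8] <- 17
  calls$protein_pos[5:8] <- 902L
  calls$residue[5:8] <- "T"
  calls$A[9:12] <- 12                      # sub-threshold detections
  calls$protein_pos[9:12] <- 1007L
  calls$residue[9:12] <- "T"
  tab <- aggregate_sites(calls, mature_offset = 0)
  expect_s3_class(tab, "phospho_site_table")
  s940 <- tab[tab$site_label == "S940", ]
  expect_equal(s940$n_detect_high, 4L)
  expect_equal(s940$max_ascore, 25)
  t902 <- tab[tab$site_label == "T902", ]
  expect_equal(t902$n_detect_mid, 4L)      # A = 17: mid band only
  expect_equal(t902$n_detect_high, 0L)
  t1007 <- tab[tab$site_label == "T1007", ]
  expect_equal(t1007$n_detect_mid + t1007$n_detect_high, 0L)

  # adjacent, never-separated serines merge into a composite label
  comp <- data.frame(
    accession = "P1", peptide = "X", replicate = 1:2, site = 3L,
    residue = "S", A = 0, alt_site = 4L, adjacent = TRUE,
    A_composite = 1000, protein_pos = 25L, stringsAsFactors = FALSE)
  ctab <- aggregate_sites(comp)
  expect_equal(ctab$site_label, "S25/26")
  expect_equal(ctab$n_detect_high, 2L)     # banding uses A_composite

  # mature offset shifts coordinates
  tab_off <- aggregate_sites(calls, mature_offset = 10L)
  expect_true("S930" %in% tab_off$site_label)
})

test_that("aggregate_sites maps peptide coordinates through the protein", {
  db <- make_proteins(c(P1 = paste0(random_protein(20, seed = 63),
                                    "ASATAK", random_protein(20))))
  m <- map_peptides("ASATAK", db)
  calls <- data.frame(accession = "P1", peptide = "ASATAK", replicate = 1L,
                      site = 2L, residue = "S", A = 30,
                      alt_site = 4L, adjacent = FALSE,
                      A_composite = NA_real_, stringsAsFactors = FALSE)
  tab <- aggregate_sites(calls, m)
  expect_equal(tab$position, 22L)
  expect_equal(tab$site_label, "S22")

  expect_error(aggregate_sites(
    data.frame(accession = "P1", peptide = "NOTTHERE", replicate = 1L,
               site = 1L, residue = "S", A = 30, alt_site = NA_integer_,
               adjacent = FALSE, A_composite = NA_real_),
    m), class = "apms_value_error")
})

test_that("MGF files round-trip and are byte-stable", {
  spectra <- list(
    list(spectrum_id = "sp1", precursor_mz = 500.25, charge = 2L,
         peaks = data.frame(mz = c(100.5, 200.25), intensity = c(10, 20))),
    list(spectrum_id = "sp2", precursor_mz = 700.125, charge = 3L,
         peaks = data.frame(mz = 350.75, intensity = 5)))
  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, p1)
  back <- read_mgf(p1)
  expect_length(back, 2L)
  expect_equal(back[[1]]$spectrum_id, "sp1")
  expect_equal(back[[1]]$precursor_mz, 500.25)
  expect_equal(back[[2]]$charge, 3L)
  expect_equal(back[[1]]$peaks$mz, c(100.5, 200.25))
  write_mgf(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
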