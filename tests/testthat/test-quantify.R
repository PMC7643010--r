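# SI_GI quantification and coverage

# two proteins with two unique peptides each; ACDK/GGWK belong to PA,
# LMNPEK/TTTTTTK to PB
quant_fixture <- function() {
  db <- make_proteins(c(PA = "ACDKGGWK", PB = "LMNPEKTTTTTTK"))
  psms <- make_psms(c("ACDK", "GGWK", "LMNPEK", "TTTTTTK"),
                    c(100, 300, 500, 100))
  list(db = db, psms = psms)
}

test_that("spectral_index sums unique-peptide intensities", {
  fx <- quant_fixture()
  m <- map_peptides(fx$psms, fx$db)
  expect_equal(spectral_index(fx$psms, "PA", m), 400)
  expect_equal(spectral_index(fx$psms, "PB", m), 600)
  expect_error(spectral_index(fx$psms, "NOPE", m), class = "apms_value_error")

  # shared peptide contributes to neither protein
  db2 <- make_proteins(c(PA = "ACDKGGWK", PB = "ACDKLMNPEK"))
  m2 <- suppressWarnings(map_peptides(fx$psms, db2))  # TTTTTTK unmatched
  expect_equal(spectral_index(fx$psms, "PA", m2), 300)   # GGWK only
  expect_equal(spectral_index(fx$psms, "PB", m2), 500)   # LMNPEK only
})

test_that("si_gi_matrix computes within-sample shares", {
  fx <- quant_fixture()
  q <- si_gi_matrix(fx$psms, fx$db)
  expect_equal(unname(q$si_gi["PA", "s1"]), 0.4)
  expect_equal(unname(q$si_gi["PB", "s1"]), 0.6)
  expect_equal(unname(q$peptide_counts[, "s1"]), c(2L, 2L))

  # single-protein sample with >= 2 unique peptides -> exactly 1
  db1 <- make_proteins(c(PA = "ACDKGGWK"))
  psms1 <- make_psms(c("ACDK", "GGWK"), c(10, 30))
  q1 <- si_gi_matrix(psms1, db1)
  expect_equal(unname(q1$si_gi["PA", "s1"]), 1)
})

test_that("sub-threshold proteins are zeroed and flagged", {
  db <- make_proteins(c(PA = "ACDKGGWK", PB = "LMNPEKTTTTTTK"))
  # PB seen through one peptide only
  psms <- make_psms(c("ACDK", "GGWK", "LMNPEK"), c(100, 300, 600))
  q <- si_gi_matrix(psms, db)
  expect_equal(unname(q$si_gi["PB", "s1"]), 0)
  expect_true(q$flagged["PB", "s1"])
  # denominator still includes the zeroed protein's intensity
  expect_equal(unname(q$si_gi["PA", "s1"]), 400 / 1000)

  # band scope pools peptides across replicates: one peptide in each of
  # two samples still counts as two distinct peptides for the band
  psms2 <- rbind(make_psms(c("ACDK", "GGWK", "LMNPEK"), c(100, 300, 600),
                           sample_id = "s1", replicate = 1L),
                 make_psms(c("ACDK", "GGWK", "TTTTTTK"), c(100, 300, 600),
                           sample_id = "s2", replicate = 2L))
  q2 <- si_gi_matrix(psms2, db, min_peptide_scope = "band")
  expect_gt(q2$si_gi["PB", "s1"], 0)
  q3 <- si_gi_matrix(psms2, db, min_peptide_scope = "sample")
  expect_equal(unname(q3$si_gi["PB", ]), c(0, 0))
})

test_that("shared peptides inflate the denominator but no numerator", {
  # ACDK is shared between PA and PB; each protein keeps two unique
  # peptides so the minimum-two-peptides rule does not zero them
  db <- make_proteins(c(PA = "ACDKGGWKFFFR", PB = "ACDKLMNPEKTTTTTTK"))
  psms <- make_psms(c("ACDK", "GGWK", "FFFR", "LMNPEK", "TTTTTTK"),
                    c(250, 100, 300, 500, 100))
  q <- si_gi_matrix(psms, db)
  expect_equal(unname(q$si_gi["PA", "s1"]), 400 / 1250)
  expect_equal(unname(q$si_gi["PB", "s1"]), 600 / 1250)
  expect_lt(sum(q$si_gi[, "s1"]), 1)
})

test_that("SI_GI conservation, scale invariance and monotonicity", {
  set.seed(41)
  # conservation: all unique, all proteins >= 2 peptides -> sums to 1
  fx <- quant_fixture()
  for (rep in 1:5) {
    psms <- make_psms(c("ACDK", "GGWK", "LMNPEK", "TTTTTTK"),
                      rlnorm(4, 10, 1))
    q <- si_gi_matrix(psms, fx$db)
    expect_equal(sum(q$si_gi[, "s1"]), 1)

    # scale invariance
    psms2 <- psms; psms2$intensity <- psms2$intensity * 1734.5
    q2 <- si_gi_matrix(psms2, fx$db)
    expect_equal(q2$si_gi, q$si_gi)

    # monotonicity: doubling PA's PSMs raises PA, lowers PB
    psms3 <- psms
    pa <- psms3$peptide %in% c("ACDK", "GGWK")
    psms3$intensity[pa] <- psms3$intensity[pa] * 2
    q3 <- si_gi_matrix(psms3, fx$db)
    expect_gt(q3$si_gi["PA", "s1"], q$si_gi["PA", "s1"])
    expect_lt(q3$si_gi["PB", "s1"], q$si_gi["PB", "s1"])
  }
})

test_that("si_gi_matrix validates samples", {
  fx <- quant_fixture()
  psms <- fx$psms
  psms$intensity <- 0
  expect_error(si_gi_matrix(psms, fx$db), class = "apms_value_error")

  # inconsistent metadata for one sample_id
  psms2 <- fx$psms
  psms2$band[2] <- "600kDa"
  expect_error(si_gi_matrix(psms2, fx$db), class = "apms_value_error")
})

test_that("quant matrix TSV round-trips at 6 significant digits", {
  fx <- quant_fixture()
  q <- si_gi_matrix(fx$psms, fx$db)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_matrix(q, path)
  back <- read_quant_matrix(path)
  expect_equal(back, signif(q$si_gi, 6))
})

test_that("sequence coverage matches the worked example and brute force", {
  prot <- list(accession = "P1", sequence = random_protein(10, seed = 51))
  pep15 <- substr(prot$sequence, 1, 5)
  pep48 <- substr(prot$sequence, 4, 8)
  # guard: the two peptides must occur only at their intended positions
  cov <- sequence_coverage(c(pep15, pep48), prot)
  brute <- rep(FALSE, 10)
  for (p in c(pep15, pep48)) {
    for (s in seq_len(10 - nchar(p) + 1L))
      if (substr(prot$sequence, s, s + nchar(p) - 1L) == p)
        brute[s:(s + nchar(p) - 1L)] <- TRUE
  }
  expect_equal(cov$covered_mask, brute)
  expect_equal(cov$coverage_percent, round(100 * mean(brute), 2))

  expect_equal(sequence_coverage(character(), prot)$coverage_percent, 0)

  reg <- data.frame(label = "Cterm", start = 7L, end = 10L)
  covr <- sequence_coverage(c(pep15, pep48), prot, regions = reg)
  expect_equal(covr$region_coverage$percent,
               round(100 * mean(brute[7:10]), 2))
  bad <- data.frame(label = "x", start = 5L, end = 11L)
  expect_error(sequence_coverage(pep15, prot, regions = bad),
               class = "apms_value_error")
})

test_that("coverage equals brute force on random fixtures", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(80:200, 1)
    seqc <- random_protein(n)
    prot <- list(accession = "R", sequence = seqc)
    peps <- vapply(1:8, function(j) {
      s <- sample(seq_len(n - 12), 1)
      substr(seqc, s, s + sample(5:12, 1))
    }, "")
    mask <- rep(FALSE, n)
    for (p in peps) {
      for (s in seq_len(n - nchar(p) + 1L))
        if (substr(seqc, s, s + nchar(p) - 1L) == p)
          mask[s:(s + nchar(p) - 1L)] <- TRUE
    }
    cov <- sequence_coverage(peps, prot)
    expect_equal(cov$covered_mask, mask)
  }
})
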