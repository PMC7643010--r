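# Synthetic AP-MS world with planted ground truth.
#
# The generator emulates the structure of a blue-native-PAGE AP-MS study:
# three gel bands, four bait and four IgG-control replicates per band, one
# dominant bait protein, planted true partners enriched in bait samples,
# shared background binders present at equal expectation in both
# conditions, per-peptide detection dropout, and phosphopeptide fragment
# spectra whose b/y ion content encodes a planted site. Intensities are
# log-normal; a protein's expected total signal is independent of its
# length (total abundance is divided across its observable peptides), so
# relative SI_GI reflects planted abundance, not sequence length.

# run code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# approximate vertebrate residue frequencies with K+R ~ 11% so tryptic
# peptides fall mostly in the 6-40 aa search window
AA_FREQ <- c(
  A = 0.074, C = 0.018, D = 0.054, E = 0.068, F = 0.038, G = 0.066,
  H = 0.026, I = 0.047, K = 0.055, L = 0.096, M = 0.022, N = 0.039,
  P = 0.059, Q = 0.047, R = 0.055, S = 0.081, T = 0.055, V = 0.062,
  W = 0.012, Y = 0.026)

#' Describe a synthetic AP-MS experiment
#'
#' Collects every tunable of the generator in one validated object. The
#' defaults state the simulated world: three bands with four bait and four
#' IgG replicates each, a bait about tenfold above its most abundant
#' partner, an eightfold bait-condition enrichment of bait and planted
#' partners, log-normal peptide intensities (meanlog 12, sdlog 1 in
#' natural-log units), and 10% per-peptide dropout.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @param n_background number of shared background binders.
#' @param n_partners number of planted true partners (across bands).
#' @param bands band labels.
#' @param n_replicates bait (and control) replicates per band.
#' @param bait_abundance_fold bait abundance relative to a partner.
#' @param bait_enrichment_fold multiplier applied to bait and planted
#'   partners in bait-condition samples only.
#' @param intensity_logmean,intensity_logsd log-normal intensity
#'   parameters (natural log). `intensity_logsd` is the spread of peptide
#'   response factors across peptides (drawn once per peptide): different
#'   peptides of one protein ionize with very different efficiencies, but
#'   a given peptide's response is stable across replicates.
#' @param replicate_logsd log-scale standard deviation of the per-sample
#'   replicate noise of a peptide (default 0.3, i.e. roughly 30%
#'   replicate-to-replicate CV, typical for label-free quantification).
#' @param dropout_prob per-peptide per-sample detection dropout.
#' @param max_peptides_per_protein cap on observable peptides per protein.
#' @param phospho list: `n_spectra`, `noise_peaks_per_window`, `n_sites`,
#'   `true_sites` (optional data.frame `accession, position`).
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(seed = 1L,
                              n_background = 60L,
                              n_partners = 24L,
                              bands = c("300kDa", "600kDa", "800kDa"),
                              n_replicates = 4L,
                              bait_abundance_fold = 10,
                              bait_enrichment_fold = 8,
                              intensity_logmean = 12,
                              intensity_logsd = 1,
                              replicate_logsd = 0.3,
                              dropout_prob = 0.1,
                              max_peptides_per_protein = 30L,
                              phospho = list()) {
  phospho <- modifyList(list(n_spectra = 200L, noise_peaks_per_window = 20L,
                             n_sites = 10L, true_sites = NULL), phospho)
  design <- list(seed = as.integer(seed), n_background = as.integer(n_background),
                 n_partners = as.integer(n_partners), bands = bands,
                 n_replicates = as.integer(n_replicates),
                 bait_abundance_fold = bait_abundance_fold,
                 bait_enrichment_fold = bait_enrichment_fold,
                 intensity_logmean = intensity_logmean,
                 intensity_logsd = intensity_logsd,
                 replicate_logsd = replicate_logsd,
                 dropout_prob = dropout_prob,
                 max_peptides_per_protein = as.integer(max_peptides_per_protein),
                 phospho = phospho)
  if (design$n_background < 1L || design$n_partners < 1L ||
      design$n_replicates < 2L)
    abort("counts must be positive (>= 2 replicates)", "apms_value_error")
  if (design$dropout_prob < 0 || design$dropout_prob >= 1)
    abort("dropout_prob must lie in [0, 1)", "apms_value_error")
  if (design$bait_enrichment_fold <= 0 || design$bait_abundance_fold <= 0)
    abort("fold parameters must be positive", "apms_value_error")
  class(design) <- "simulation_design"
  design
}

random_sequence <- function(len) {
  paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

# sequence guaranteed to yield at least one fully tryptic 6-40 aa peptide
random_digestible_sequence <- function(len) {
  repeat {
    s <- random_sequence(len)
    d <- digest(s, 0L, 6L, 40L)
    if (nrow(d)) return(s)
  }
}

#' Generate the synthetic proteome and ground-truth scaffold
#'
#' Random sequences (bait 1100 aa, partners and background 100-1200 aa)
#' over the 20 canonical residues, every one digestible into at least one
#' 6-40 aa tryptic peptide. Partners are assigned to one, two or three
#' bands (with overlaps) so Venn-style band accounting is exercisable.
#' Deterministic given the design seed.
#'
#' @param design a `simulation_design`.
#' @return list with `proteins` (a `protein_db`) and `truth` (list:
#'   `bait`, `partners`, `partners_by_band`, `background`).
#' @export
generate_proteome <- function(design) {
  with_seed(design$seed, {
    n_p <- design$n_partners
    n_b <- design$n_background
    acc <- c("BAIT001",
             sprintf("PTN%03d", seq_len(n_p)),
             sprintf("BKG%03d", seq_len(n_b)))
    lens <- c(1100L, sample(100:1200, n_p + n_b, replace = TRUE))
    seqs <- vapply(lens, random_digestible_sequence, "")
    role <- c("synthetic bait protein",
              rep("synthetic planted partner", n_p),
              rep("synthetic background binder", n_b))
    proteins <- data.frame(accession = acc, description = role,
                           sequence = seqs, stringsAsFactors = FALSE)
    class(proteins) <- c("protein_db", "data.frame")
    partners <- acc[2:(n_p + 1L)]
    n_bands_each <- sample(seq_along(design$bands), n_p, replace = TRUE,
                           prob = c(0.5, 0.3, 0.2)[seq_along(design$bands)])
    partners_by_band <- setNames(
      lapply(design$bands, function(b) character()), design$bands)
    for (i in seq_len(n_p)) {
      in_bands <- sample(design$bands, n_bands_each[i])
      for (b in in_bands)
        partners_by_band[[b]] <- c(partners_by_band[[b]], partners[i])
    }
    # every band keeps at least two partners so per-band statistics exist
    for (b in design$bands)
      if (length(partners_by_band[[b]]) < 2L)
        partners_by_band[[b]] <- unique(c(partners_by_band[[b]],
                                          partners[seq_len(2L)]))
    truth <- list(bait = "BAIT001", partners = partners,
                  partners_by_band = partners_by_band,
                  background = acc[(n_p + 2L):length(acc)])
    list(proteins = proteins, truth = truth)
  })
}

#' Generate the synthetic AP-MS PSM tables
#'
#' Draws per-peptide log-normal intensities for every band, condition and
#' replicate. The bait (always) and the band's planted partners (in bait
#' samples only) are multiplied by the design's fold parameters; a
#' protein's expected total signal does not depend on its peptide count.
#' Per-peptide dropout removes detections at random. Also plants an
#' interaction-evidence table among band-sharing partners plus low-score
#' decoy rows, and a toy functional-annotation table.
#'
#' @param design a `simulation_design`.
#' @param proteome result of [generate_proteome()].
#' @return list with `psms` (a `psm_table` over all samples), `evidence`
#'   (data.frame in `protein_a/protein_b` layout, planted edges only),
#'   `decoy_evidence` (rows that must not survive the experimental-score
#'   filter), `annotations` and `truth`.
#' @export
generate_apms <- function(design, proteome) {
  with_seed(design$seed + 1L, {
    proteins <- proteome$proteins
    truth <- proteome$truth
    peptides <- lapply(seq_len(nrow(proteins)), function(i) {
      d <- digest(proteins$sequence[i], 0L, 6L, 40L)
      if (nrow(d) > design$max_peptides_per_protein)
        d <- d[sort(sample.int(nrow(d), design$max_peptides_per_protein)), ]
      d$accession <- proteins$accession[i]
      d
    })
    pep_tab <- do.call(rbind, peptides)
    n_pep <- table(pep_tab$accession)[pep_tab$accession]
    # peptide response factor: drawn once, stable across all samples
    response <- stats::rnorm(nrow(pep_tab), 0, design$intensity_logsd)

    rows <- list()
    scan <- 0L
    for (b in design$bands) {
      for (cond in c("bait", "control")) {
        for (r in seq_len(design$n_replicates)) {
          abund <- rep(1, nrow(pep_tab))
          is_bait <- pep_tab$accession == truth$bait
          abund[is_bait] <- design$bait_abundance_fold
          if (cond == "bait") {
            enriched <- is_bait |
              pep_tab$accession %in% truth$partners_by_band[[b]]
            abund[enriched] <- abund[enriched] * design$bait_enrichment_fold
          }
          meanlog <- design$intensity_logmean + log(abund) -
            log(as.numeric(n_pep)) + response
          intensity <- rlnorm(nrow(pep_tab), meanlog,
                              design$replicate_logsd)
          keep <- runif(nrow(pep_tab)) >= design$dropout_prob
          idx <- which(keep)
          scan_ids <- scan + seq_along(idx)
          scan <- scan + length(idx)
          rows[[length(rows) + 1L]] <- data.frame(
            spectrum_id = sprintf("scan%07d", scan_ids),
            peptide = pep_tab$peptide[idx],
            modifications = "",
            charge = sample(2:5, length(idx), replace = TRUE),
            intensity = intensity[idx],
            sample_id = sprintf("%s_%s_%d", b, cond, r),
            band = b, condition = cond, replicate = r,
            q_value = 0.001, e_value = 1e-9,
            stringsAsFactors = FALSE)
        }
      }
    }
    psms <- do.call(rbind, rows)
    rownames(psms) <- NULL
    class(psms) <- c("psm_table", "data.frame")

    # planted evidence: partners sharing a band interact with prob 0.4
    edges <- list()
    for (b in design$bands) {
      p <- truth$partners_by_band[[b]]
      if (length(p) >= 2L) {
        pairs <- combn(sort(p), 2L)
        pick <- runif(ncol(pairs)) < 0.4
        if (any(pick))
          edges[[length(edges) + 1L]] <- data.frame(
            protein_a = pairs[1, pick], protein_b = pairs[2, pick],
            experimental_score = sample(750:990, sum(pick), replace = TRUE),
            combined_score = sample(900:999, sum(pick), replace = TRUE),
            stringsAsFactors = FALSE)
      }
    }
    evidence <- unique(do.call(rbind, c(edges, list(make.row.names = FALSE))))
    bkg <- truth$background
    n_decoy <- min(20L, length(bkg) %/% 2L)
    decoy <- data.frame(
      protein_a = bkg[seq_len(n_decoy)],
      protein_b = bkg[seq_len(n_decoy) + n_decoy],
      experimental_score = sample(100:400, n_decoy, replace = TRUE),
      combined_score = sample(850:950, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)

    terms <- c("ion transport", "cytoskeleton organization",
               "signal transduction", "innate immune response",
               "synaptic signaling", "protein phosphorylation")
    annotations <- data.frame(
      accession = proteome$proteins$accession,
      term = sample(terms, nrow(proteome$proteins), replace = TRUE),
      score = round(runif(nrow(proteome$proteins), 0.5, 1), 3),
      stringsAsFactors = FALSE)

    truth$evidence <- evidence
    list(psms = psms, evidence = evidence, decoy_evidence = decoy,
         annotations = annotations, truth = truth)
  })
}

#' Generate synthetic phosphopeptide fragment spectra
#'
#' Plants `n_sites` phosphosites on S/T/Y residues of the bait's fully
#' tryptic 6-40 aa peptides (preferring peptides that also carry a
#' non-adjacent alternative acceptor, so localization is non-trivial) and
#' emits `n_spectra` spectra cycling over (site, replicate 1..4). Each
#' spectrum contains every singly charged b/y ion of the true
#' phospho-isoform at high intensity plus `noise_peaks_per_window`
#' uniform-random low-intensity peaks per 100 m/z window. Deterministic
#' given the design seed.
#'
#' @param design a `simulation_design`.
#' @param proteome result of [generate_proteome()].
#' @return list with `spectra` (MGF-ready list), `assignments`
#'   (data.frame `spectrum_id, peptide, accession, replicate, n_phospho`)
#'   and `truth_sites` (data.frame `accession, position, peptide,
#'   site_pep, spectrum_ids`).
#' @export
generate_phospho_spectra <- function(design, proteome) {
  with_seed(design$seed + 2L, {
    cfg <- design$phospho
    bait <- proteome$truth$bait
    bait_seq <- proteome$proteins$sequence[
      proteome$proteins$accession == bait]
    peps <- digest(bait_seq, 0L, 6L, 40L)

    site_rows <- list()
    if (!is.null(cfg$true_sites)) {
      for (i in seq_len(nrow(cfg$true_sites))) {
        p <- cfg$true_sites$position[i]
        hit <- peps[peps$start <= p & peps$end >= p, , drop = FALSE]
        if (!nrow(hit))
          abort(sprintf(
            "planted site %s:%d is not covered by any 6-40 aa tryptic peptide",
            cfg$true_sites$accession[i], p), "apms_value_error")
        site_rows[[i]] <- data.frame(
          accession = cfg$true_sites$accession[i], position = p,
          peptide = hit$peptide[1], site_pep = p - hit$start[1] + 1L,
          stringsAsFactors = FALSE)
      }
    } else {
      sty <- lapply(seq_len(nrow(peps)), function(i) {
        res <- strsplit(peps$peptide[i], "")[[1]]
        which(res %in% c("S", "T", "Y"))
      })
      # prefer peptides with >= 2 acceptors including a non-adjacent pair
      good <- which(vapply(sty, function(s)
        length(s) >= 2L && max(diff(sort(s))) >= 2L, TRUE))
      fallback <- setdiff(which(lengths(sty) >= 1L), good)
      order_pref <- c(good[sample.int(length(good))],
                      fallback[sample.int(length(fallback))])
      chosen <- head(order_pref, cfg$n_sites)
      if (length(chosen) < cfg$n_sites)
        abort("bait has too few phospho-acceptor peptides for n_sites",
              "apms_value_error")
      for (i in chosen) {
        s <- sty[[i]]
        pick <- if (length(s) >= 2L && max(diff(sort(s))) >= 2L) {
          far <- s[vapply(s, function(x) any(abs(s - x) >= 2L), TRUE)]
          far[sample.int(length(far), 1L)]
        } else s[sample.int(length(s), 1L)]
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          accession = bait, position = peps$start[i] + pick - 1L,
          peptide = peps$peptide[i], site_pep = pick,
          stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, c(site_rows, list(make.row.names = FALSE)))

    spectra <- vector("list", cfg$n_spectra)
    assign_rows <- vector("list", cfg$n_spectra)
    spectrum_ids_by_site <- vector("list", nrow(sites))
    for (k in seq_len(cfg$n_spectra)) {
      si <- ((k - 1L) %% nrow(sites)) + 1L
      rep_k <- (((k - 1L) %/% nrow(sites)) %% 4L) + 1L
      iso <- theoretical_ions(sites$peptide[si], sites$site_pep[si])
      true_peaks <- data.frame(mz = iso$ions$mz,
                               intensity = runif(nrow(iso$ions), 800, 1000))
      max_mz <- max(iso$ions$mz) + 100
      n_win <- ceiling(max_mz / 100)
      noise <- data.frame(
        mz = runif(n_win * cfg$noise_peaks_per_window, 0, 100) +
          rep(100 * (seq_len(n_win) - 1L),
              each = cfg$noise_peaks_per_window),
        intensity = runif(n_win * cfg$noise_peaks_per_window, 1, 100))
      peaks <- rbind(true_peaks, noise)
      peaks <- peaks[order(peaks$mz), , drop = FALSE]
      rownames(peaks) <- NULL
      pep_mass <- sequence_mass(sites$peptide[si]) + MASS_PHOSPHO
      sid <- sprintf("PHOS%04d", k)
      spectra[[k]] <- list(spectrum_id = sid,
                           precursor_mz = (pep_mass + 2 * MASS_PROTON) / 2,
                           charge = 2L, peaks = peaks)
      assign_rows[[k]] <- data.frame(
        spectrum_id = sid, peptide = sites$peptide[si],
        accession = sites$accession[si], replicate = rep_k,
        n_phospho = 1L, stringsAsFactors = FALSE)
      spectrum_ids_by_site[[si]] <- c(spectrum_ids_by_site[[si]], sid)
    }
    sites$spectrum_ids <- vapply(spectrum_ids_by_site,
                                 paste, "", collapse = ";")
    list(spectra = spectra,
         assignments = do.call(rbind, c(assign_rows,
                                        list(make.row.names = FALSE))),
         truth_sites = sites)
  })
}

#' Write a full synthetic experiment to disk
#'
#' Emits FASTA, one PSM TSV per band x condition x replicate, the planted
#' evidence table (with decoy rows mixed in) in STRING dialect, the
#' annotation table, the phospho MGF plus assignment TSV, and a
#' ground-truth JSON. The directory contents are a ready-made input set
#' for [run_all()].
#'
#' @param design a `simulation_design`.
#' @param dir output directory (created if needed).
#' @return list with the generated in-memory objects, invisibly.
#' @export
write_simulation <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(design)
  apms <- generate_apms(design, proteome)
  phos <- generate_phospho_spectra(design, proteome)

  write_fasta(proteome$proteins, file.path(dir, "proteome.fasta"))
  psm_dir <- file.path(dir, "psm")
  dir.create(psm_dir, showWarnings = FALSE)
  for (s in unique(apms$psms$sample_id))
    write_psm_table(apms$psms[apms$psms$sample_id == s, ],
                    file.path(psm_dir, paste0(s, ".tsv")))
  all_ev <- rbind(apms$evidence, apms$decoy_evidence)
  write_evidence(all_ev, file.path(dir, "evidence.txt"))
  write.table(apms$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_mgf(phos$spectra, file.path(dir, "phospho.mgf"))
  write.table(phos$assignments, file.path(dir, "phospho_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(bait = apms$truth$bait,
                partners_by_band = apms$truth$partners_by_band,
                background = apms$truth$background,
                phospho_sites = phos$truth_sites[
                  c("accession", "position", "peptide", "site_pep")])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, proteome = proteome, apms = apms,
                 phospho = phos))
}
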