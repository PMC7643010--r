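# in-code fixture builders shared across test files

# minimal protein database
make_proteins <- function(seqs) {
  df <- data.frame(accession = names(seqs), description = "",
                   sequence = unname(seqs), stringsAsFactors = FALSE)
  class(df) <- c("protein_db", "data.frame")
  df
}

# one PSM row per element of `peptide`, recycling scalar fields
make_psms <- function(peptide, intensity, sample_id = "s1",
                      band = "300kDa", condition = "bait", replicate = 1L,
                      modifications = "", q_value = 0.001) {
  n <- length(peptide)
  df <- data.frame(
    spectrum_id = sprintf("spec%03d", seq_len(n)),
    peptide = peptide, modifications = modifications,
    charge = 2L, intensity = intensity, sample_id = sample_id,
    band = band, condition = condition, replicate = replicate,
    q_value = q_value, e_value = 1e-9, stringsAsFactors = FALSE)
  class(df) <- c("psm_table", "data.frame")
  df
}

# small quant matrix built straight from per-sample PSM sets
make_quant <- function(...) {
  psms <- do.call(rbind, list(...))
  class(psms) <- c("psm_table", "data.frame")
  psms
}

# random peptide-free protein sequence (tests' own generator, independent
# of the package's synthetic module)
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# shared default-design simulation, generated once per test run and
# reused by the synthetic/pipeline/acceptance suites (generation is the
# expensive step)
sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(sim_cache[[key]])) {
    design <- simulation_design(seed = seed)
    proteome <- generate_proteome(design)
    apms <- generate_apms(design, proteome)
    map <- suppressWarnings(map_peptides(apms$psms, proteome$proteins))
    quant <- si_gi_matrix(apms$psms, proteome$proteins, map)
    sim_cache[[key]] <- list(design = design, proteome = proteome,
                             apms = apms, map = map, quant = quant)
  }
  sim_cache[[key]]
}
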