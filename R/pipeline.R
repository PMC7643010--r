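# End-to-end orchestration: config handling, stage execution, run report.

#' Default run configuration
#'
#' Central registry of every tunable with its default. Paths are NULL
#' until supplied by the user (or by [write_simulation()] output layout).
#'
#' @return nested list with `paths` and `parameters`.
#' @export
default_config <- function() {
  list(
    paths = list(
      psm_dir = NULL,          # directory of per-sample PSM TSVs
      fasta = NULL,
      evidence = NULL,         # STRING detailed-links dialect; enables network
      annotations = NULL,      # optional accession/term/score TSV
      mgf = NULL,              # enables the phospho stage
      phospho_assignments = NULL,
      output_dir = NULL),
    parameters = list(
      q_value_cutoff = 0.01,
      bait = NULL,
      alpha = 0.05,
      p_adjust = "none",
      min_peptides = 2L,
      min_peptide_scope = "band",
      trace_fraction = 0.02,   # = the 50-fold bait-relative cutoff
      trace_inclusive = TRUE,
      evidence_min_score = 700L,
      ascore_tolerance_da = 0.05,
      ascore_ambiguity = 15,
      mature_offset = 0L,
      pca_protein_set = "union",  # union of per-band significant sets
      seed = 1L))
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "apms_io_error")
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  for (section in names(user)) {
    if (!section %in% names(defaults))
      abort(sprintf("unknown config section: '%s'", section),
            "apms_config_error")
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown))
      abort(sprintf("unknown config key(s) in '%s': %s", section,
                    paste(unknown, collapse = ", ")), "apms_config_error")
  }
  modifyList(defaults, user)
}

validate_config <- function(config) {
  p <- config$paths
  if (is.null(p$psm_dir) || is.null(p$fasta) || is.null(p$output_dir))
    abort("config must set paths: psm_dir, fasta, output_dir",
          "apms_config_error")
  for (key in c("psm_dir", "fasta", "evidence", "annotations", "mgf",
                "phospho_assignments"))
    if (!is.null(p[[key]]) && !file.exists(p[[key]]))
      abort(sprintf("configured path '%s' does not exist: %s", key, p[[key]]),
            "apms_config_error")
  if (!is.null(p$mgf) && is.null(p$phospho_assignments))
    abort("phospho stage needs both mgf and phospho_assignments",
          "apms_config_error")
  if (is.null(config$parameters$bait))
    abort("config must set parameters: bait accession", "apms_config_error")
  invisible(config)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes PSM input, SI_GI quantification, bait-vs-control enrichment,
#' overlap accounting, z-transform + PCA, trace filtering + network
#' assembly (when an evidence file is configured) and A-score phosphosite
#' calling (when spectra are configured), writing all artifact tables and
#' a machine-readable JSON run report to the output directory. Identical
#' config and inputs produce byte-identical outputs.
#'
#' @param config a config list (see [default_config()]) or the path to a
#'   YAML file for [load_run_config()].
#' @return the run report, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  config <- validate_config(config)
  paths <- config$paths
  prm <- config$parameters
  dir.create(paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(software = "apmsquant",
                 version = as.character(packageVersion("apmsquant")),
                 seed = prm$seed, parameters = prm, stages = list())

  # --- psm_io ---------------------------------------------------------
  proteins <- read_fasta(paths$fasta)
  psm_files <- sort(list.files(paths$psm_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
  if (!length(psm_files))
    abort(sprintf("no PSM tables (*.tsv) in %s", paths$psm_dir),
          "apms_config_error")
  tables <- lapply(psm_files, read_psm_table, q_cutoff = prm$q_value_cutoff)
  n_excluded <- sum(vapply(tables, attr, 0L, "n_excluded"))
  psms <- do.call(rbind, tables)
  class(psms) <- c("psm_table", "data.frame")
  log_stage("psm_io", "%d PSMs from %d tables (%d q-value exclusions)",
            nrow(psms), length(tables), n_excluded)
  report$stages$psm_io <- list(tables = length(tables),
                               rows_in = nrow(psms) + n_excluded,
                               rows_out = nrow(psms),
                               q_value_excluded = n_excluded)

  # --- quantify -------------------------------------------------------
  map <- suppressWarnings(map_peptides(psms, proteins))
  quant <- si_gi_matrix(psms, proteins, map,
                        min_peptides = prm$min_peptides,
                        min_peptide_scope = prm$min_peptide_scope)
  write_quant_matrix(quant, file.path(paths$output_dir, "si_gi_matrix.tsv"))
  log_stage("quantify", "%d proteins x %d samples",
            nrow(quant$si_gi), ncol(quant$si_gi))
  report$stages$quantify <- list(
    proteins = nrow(quant$si_gi), samples = ncol(quant$si_gi),
    zeroed_low_peptide_cells = sum(quant$flagged))

  # --- enrichment -----------------------------------------------------
  bands <- unique(quant$samples$band)
  enriched <- list()
  sig_sets <- list()
  for (b in bands) {
    res <- enrich_band(quant, b, alpha = prm$alpha, p_adjust = prm$p_adjust)
    write.table(res, file.path(paths$output_dir,
                               sprintf("enrichment_%s.tsv", b)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    enriched[[b]] <- res
    sig_sets[[b]] <- res$accession[res$significant & res$consistent]
    log_stage("enrichment", "%s: %d/%d significant+consistent", b,
              length(sig_sets[[b]]), nrow(res))
  }
  report$stages$enrichment <- lapply(enriched, function(res)
    list(tested = nrow(res), significant = sum(res$significant),
         significant_consistent = sum(res$significant & res$consistent)))
  if (length(sig_sets) >= 2L) {
    venn <- overlap_counts(sig_sets)
    jsonlite::write_json(as.list(venn),
                         file.path(paths$output_dir, "venn_counts.json"),
                         auto_unbox = TRUE)
    report$stages$overlap <- as.list(venn)
  }

  # --- multivariate ---------------------------------------------------
  pca_proteins <- sort(unique(unlist(sig_sets)))
  report$stages$multivariate <- list(proteins_in = length(pca_proteins))
  if (length(pca_proteins) >= 2L && ncol(quant$si_gi) >= 2L) {
    zt <- z_transform(quant$si_gi[pca_proteins, , drop = FALSE])
    pca <- pca_samples(zt)
    write.table(data.frame(sample = rownames(pca$scores),
                           signif(pca$scores, 6), check.names = FALSE),
                file.path(paths$output_dir, "pca_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(accession = rownames(pca$loadings),
                           signif(pca$loadings, 6), check.names = FALSE),
                file.path(paths$output_dir, "pca_loadings.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(component = names(pca$variance_explained),
                           percent = signif(pca$variance_explained, 6)),
                file.path(paths$output_dir, "pca_variance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("multivariate", "PC1 %.2f%%, PC2 %.2f%% over %d proteins",
              pca$variance_explained[1],
              ifelse(length(pca$variance_explained) > 1,
                     pca$variance_explained[2], NA),
              nrow(pca$loadings))
    report$stages$multivariate$dropped_zero_variance <-
      length(pca$dropped_proteins)
    report$stages$multivariate$variance_explained <-
      unname(pca$variance_explained)
  }

  # --- network --------------------------------------------------------
  if (!is.null(paths$evidence)) {
    evidence <- load_evidence(paths$evidence,
                              min_score = prm$evidence_min_score)
    annotations <- NULL
    if (!is.null(paths$annotations))
      annotations <- read.delim(paths$annotations, sep = "\t",
                                stringsAsFactors = FALSE)
    report$stages$network <- list(evidence_edges = nrow(evidence))
    for (b in bands) {
      res <- enriched[[b]]
      keep <- res$significant & res$consistent |
        res$accession == prm$bait
      si <- setNames(res$mean_bait, res$accession)[res$accession[keep]]
      retained <- trace_filter(si, prm$bait,
                               fraction = prm$trace_fraction,
                               inclusive = prm$trace_inclusive)
      g <- build_network(retained, si, evidence, prm$bait, annotations)
      write_network(g, file.path(paths$output_dir,
                                 sprintf("network_%s", b)))
      log_stage("network", "%s: %d candidates -> %d nodes, %d edges", b,
                sum(keep), igraph::vcount(g), igraph::ecount(g))
      report$stages$network[[b]] <- list(
        candidates = sum(keep), trace_survivors = length(retained),
        edges = igraph::ecount(g))
    }
  }

  # --- phospho --------------------------------------------------------
  if (!is.null(paths$mgf)) {
    spectra <- read_mgf(paths$mgf)
    assignments <- read.delim(paths$phospho_assignments, sep = "\t",
                              stringsAsFactors = FALSE)
    calls <- ascore_site_table(spectra, assignments,
                               tolerance = prm$ascore_tolerance_da)
    site_map <- suppressWarnings(
      map_peptides(unique(assignments$peptide), proteins))
    sites <- aggregate_sites(calls, site_map,
                             mature_offset = prm$mature_offset,
                             ambiguity = prm$ascore_ambiguity)
    write.table(sites, file.path(paths$output_dir, "phospho_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("phospho", "%d spectra -> %d sites (%d at A>19)",
              length(spectra), nrow(sites), sum(sites$n_detect_high > 0))
    report$stages$phospho <- list(
      spectra = length(spectra), sites = nrow(sites),
      sites_high = sum(sites$n_detect_high > 0))
  }

  jsonlite::write_json(report,
                       file.path(paths$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
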