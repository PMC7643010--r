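# Trace filtering and abundance-scaled network assembly from offline
# interaction-evidence tables (STRING protein.links.detailed dialect).

#' Remove trace binding proteins relative to the bait
#'
#' Retains protein p iff SI_GI(p) >= fraction * SI_GI(bait). The default
#' fraction 0.02 is the 2% / 50-fold cutoff (1 / 0.02 = 50): proteins more
#' than 50-fold below the bait are considered trace binders. The boundary
#' is inclusive by default (a protein at exactly 2% is retained); the bait
#' itself is always retained.
#'
#' @param si_gi named numeric vector of SI_GI values (one band).
#' @param bait bait accession, must be present in `si_gi`.
#' @param fraction cutoff as a fraction of the bait's SI_GI, in (0, 1).
#' @param inclusive retain proteins at exactly the cutoff (default TRUE).
#' @return character vector of retained accessions, sorted by descending
#'   SI_GI (bait first).
#' @export
trace_filter <- function(si_gi, bait, fraction = 0.02, inclusive = TRUE) {
  if (!bait %in% names(si_gi))
    abort(sprintf("bait '%s' absent from SI_GI vector", bait),
          "apms_value_error")
  if (fraction <= 0 || fraction >= 1)
    abort("fraction must be in (0, 1)", "apms_value_error")
  cutoff <- fraction * si_gi[[bait]]
  keep <- if (inclusive) si_gi >= cutoff else si_gi > cutoff
  keep[bait] <- TRUE
  retained <- names(si_gi)[keep]
  retained[order(-si_gi[retained], retained)]
}

#' Load an offline interaction-evidence table
#'
#' Reads the STRING `protein.links.detailed` dialect (whitespace-separated,
#' header with at least `protein1 protein2 experimental combined_score`).
#' Only rows whose experimental-channel score reaches `min_score` are kept
#' (default 700, the conventional high-confidence threshold); pairs are
#' deduplicated as undirected edges keeping the maximum score.
#'
#' @param path path to the evidence file.
#' @param min_score minimum experimental score (0-1000 scale).
#' @return data.frame of class `evidence_table` with columns `protein_a,
#'   protein_b, experimental_score, combined_score`.
#' @export
load_evidence <- function(path, min_score = 700L) {
  if (!file.exists(path))
    abort(sprintf("evidence file not found: %s", path), "apms_io_error")
  df <- tryCatch(
    read.table(path, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed evidence file '%s': %s",
                                      path, conditionMessage(e)),
                              "apms_parse_error"))
  need <- c("protein1", "protein2", "experimental", "combined_score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort(sprintf("evidence file '%s' missing column(s): %s", path,
                  paste(missing, collapse = ", ")), "apms_schema_error")
  for (col in c("experimental", "combined_score")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v > 1000)
    if (length(bad))
      abort(sprintf("evidence file '%s': invalid '%s' at line %d",
                    path, col, bad[1] + 1L), "apms_parse_error")
    df[[col]] <- as.integer(v)
  }
  df <- df[df$experimental >= min_score, , drop = FALSE]
  if (!nrow(df))
    return(structure(data.frame(protein_a = character(),
                                protein_b = character(),
                                experimental_score = integer(),
                                combined_score = integer(),
                                stringsAsFactors = FALSE),
                     class = c("evidence_table", "data.frame")))
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -df$experimental, -df$combined_score)
  df <- df[ord, ]; a <- a[ord]; b <- b[ord]; key <- key[ord]
  first <- !duplicated(key)
  out <- data.frame(protein_a = a[first], protein_b = b[first],
                    experimental_score = df$experimental[first],
                    combined_score = df$combined_score[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Write an evidence table in the STRING detailed-links dialect
#'
#' @param edges data.frame with columns `protein_a, protein_b,
#'   experimental_score, combined_score` (or STRING-named equivalents).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(edges, path) {
  if (all(c("protein_a", "protein_b") %in% names(edges)))
    edges <- data.frame(protein1 = edges$protein_a,
                        protein2 = edges$protein_b,
                        experimental = edges$experimental_score,
                        combined_score = edges$combined_score)
  out <- data.frame(protein1 = edges$protein1, protein2 = edges$protein2,
                    neighborhood = 0L, fusion = 0L, cooccurence = 0L,
                    coexpression = 0L, experimental = edges$experimental,
                    database = 0L, textmining = 0L,
                    combined_score = edges$combined_score)
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the abundance-scaled complex network for one band
#'
#' Nodes are the trace-filter survivors, carrying the band's SI_GI and a
#' node size scaled linearly between `size_range` so the most abundant
#' protein gets the maximum diameter. Edges are the evidence pairs among
#' retained proteins plus one imputed bait edge per non-bait node (the
#' bait interaction discovered by the purification itself). When an
#' annotation table is supplied, the top-scoring term per protein is
#' attached as a node attribute.
#'
#' @param retained character vector of retained accessions (bait included).
#' @param si_gi named SI_GI vector for the band (covers `retained`).
#' @param evidence an `evidence_table` (may be empty).
#' @param bait bait accession.
#' @param annotations optional data.frame `accession, term, score`.
#' @param size_range numeric length-2, min and max node size.
#' @return an `igraph` object (undirected) with vertex attributes `si_gi`,
#'   `annotation`, `node_size` and edge attributes `source`
#'   (`"evidence"` or `"bait_imputed"`) and `score`; graph attribute
#'   `bait`.
#' @export
build_network <- function(retained, si_gi, evidence, bait,
                          annotations = NULL, size_range = c(10, 40)) {
  if (!length(retained))
    abort("no retained proteins to build a network from", "apms_value_error")
  if (!bait %in% retained)
    abort(sprintf("bait '%s' not among retained proteins", bait),
          "apms_value_error")
  vals <- si_gi[retained]
  vals[is.na(vals)] <- 0
  node_size <- size_range[1] +
    (size_range[2] - size_range[1]) * vals / max(vals)
  ann <- rep("", length(retained))
  if (!is.null(annotations) && nrow(annotations)) {
    top <- annotations[order(annotations$accession, -annotations$score), ]
    top <- top[!duplicated(top$accession), ]
    idx <- match(retained, top$accession)
    ann[!is.na(idx)] <- top$term[idx[!is.na(idx)]]
  }
  vertices <- data.frame(name = retained, si_gi = unname(vals),
                         annotation = ann, node_size = unname(node_size),
                         stringsAsFactors = FALSE)
  ev <- evidence[evidence$protein_a %in% retained &
                   evidence$protein_b %in% retained &
                   evidence$protein_a != evidence$protein_b, , drop = FALSE]
  edges <- data.frame(
    from = c(ev$protein_a, rep(bait, sum(retained != bait))),
    to = c(ev$protein_b, setdiff(retained, bait)),
    source = c(rep("evidence", nrow(ev)),
               rep("bait_imputed", sum(retained != bait))),
    score = c(ev$experimental_score, rep(NA_integer_,
                                         sum(retained != bait))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "bait", bait)
  g
}

#' Write network artifacts: GraphML plus node/edge TSV tables
#'
#' @param g network from [build_network()].
#' @param prefix path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return character vector of written paths, invisibly.
#' @export
write_network <- function(g, prefix) {
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  nodes <- data.frame(accession = igraph::V(g)$name,
                      si_gi = signif(igraph::V(g)$si_gi, 6),
                      annotation = igraph::V(g)$annotation,
                      node_size = signif(igraph::V(g)$node_size, 6))
  ends <- igraph::as_edgelist(g)
  edges <- data.frame(protein_a = ends[, 1], protein_b = ends[, 2],
                      source = igraph::E(g)$source,
                      score = igraph::E(g)$score)
  npath <- paste0(prefix, "_nodes.tsv")
  epath <- paste0(prefix, "_edges.tsv")
  write.table(nodes, npath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edges, epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml, npath, epath))
}
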