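# shared internal helpers and constants

#: the 20 canonical residues; anything else in a sequence is rejected
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# monoisotopic residue masses (Da); peptide mass = sum(residues) + H2O
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_PROTON <- 1.007276
MASS_H2O <- 18.010565

# phosphorylation mass delta on S/T/Y (Da)
MASS_PHOSPHO <- 79.9663

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "apms_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("'%s' must be a single finite number", name),
          "apms_value_error")
  invisible(x)
}

check_sequence <- function(sequence, accession = "<sequence>") {
  if (!nzchar(sequence))
    abort(sprintf("record '%s' has an empty sequence", accession),
          "apms_parse_error")
  letters <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters, AA_CANONICAL)
  if (length(bad))
    abort(sprintf(
      "record '%s' contains non-canonical residue(s): %s (only the 20 canonical amino acids are accepted)",
      accession, paste(bad, collapse = ", ")), "apms_parse_error")
  invisible(sequence)
}

# monoisotopic mass of an unmodified peptide/protein sequence
sequence_mass <- function(sequence) {
  check_sequence(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(AA_MONO[res]) + MASS_H2O
}

# numeric formatting used by all table writers so that identical inputs
# produce byte-identical files and values round-trip exactly
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to the shortest representation that still round-trips
  for (i in seq_along(x)) {
    for (digits in 1:16) {
      s <- sprintf("%.*g", digits, x[i])
      if (as.numeric(s) == x[i]) {
        out[i] <- s
        break
      }
    }
  }
  out
}
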