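#' Scan an RNA sequence for functional motifs
#'
#' Exact substring matching on the sense strand against the NSR
#' characteristic domain, the three dipeptide gene motifs (MSPG, NSPG,
#' control peptide gene), and the control RNA motif. A single substitution
#' destroys function; a complement copy is a replication intermediate and
#' carries no label until it is copied back. Concatemers can carry several
#' labels (and several copies of one motif).
#'
#' @param seq Character vector of RNA sequences over `{A,C,G,U}`.
#' @param seq_defs Sequence definitions ([default_sequence_defs()]).
#' @return For a single sequence, a named integer vector of non-overlapping
#'   occurrence counts (`MSPG`, `NSPG`, `NSR`, `control_gene`,
#'   `control_rna`); for several sequences, a matrix with one row each.
#' @export
#' @examples
#' sd <- default_sequence_defs()
#' scan_motifs(sd$nsr_motif, sd)
scan_motifs <- function(seq, seq_defs) {
  sdl <- unclass(seq_defs)
  res <- do.call(rbind, lapply(seq, cpp_scan_motifs, seqdefs = sdl))
  rownames(res) <- NULL
  if (length(seq) == 1) res[1, ] else res
}

#' Functional labels present in a sequence
#'
#' @inheritParams scan_motifs
#' @return Character vector of labels with at least one motif occurrence.
#' @export
motif_labels <- function(seq, seq_defs) {
  counts <- scan_motifs(seq, seq_defs)
  names(counts)[counts > 0]
}

#' Locate amino-acid-binding sites on an RNA
#'
#' Non-overlapping left-to-right scan for codebook 5-mers, the site
#' inventory used by the DRT mechanism. A dipeptide gene motif yields two
#' contiguous sites (offsets 0 and `L_AABS`).
#'
#' @inheritParams scan_motifs
#' @param L_AABS Binding-site length.
#' @return A tibble with columns `offset` (0-based) and `type` (amino-acid
#'   letter).
#' @export
find_binding_sites <- function(seq, seq_defs, L_AABS = 5) {
  res <- cpp_find_binding_sites(seq, unclass(seq_defs), as.integer(L_AABS))
  tibble::tibble(offset = res$offset, type = res$type)
}

#' Classify a dipeptide by its ordered residue pair
#'
#' Peptide identity is the ordered pair of residues as laid down by the
#' template; the reversed pair is a different (non-functional) molecule.
#'
#' @param residues Character of length 1 like `"PQ"`, or a vector of two
#'   single letters.
#' @param seq_defs Sequence definitions.
#' @return One of `"MSP"`, `"NSP"`, `"control"`, `"none"`.
#' @export
classify_peptide <- function(residues, seq_defs) {
  if (length(residues) == 2) residues <- paste(residues, collapse = "")
  key <- function(pr) paste(pr, collapse = "")
  if (identical(residues, key(seq_defs$msp_pair))) return("MSP")
  if (identical(residues, key(seq_defs$nsp_pair))) return("NSP")
  if (identical(residues, key(seq_defs$control_pair))) return("control")
  "none"
}
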