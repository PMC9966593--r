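#' @keywords internal
.revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

.rand_mer <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

.contains_any <- function(s, motifs) {
  any(vapply(motifs, function(m) grepl(m, s, fixed = TRUE), logical(1)))
}

#' Default sequence definitions (codebook and functional motifs)
#'
#' The model fixes motif *lengths* (binding sites of `L_AABS = 5`
#' nucleotides, dipeptide gene templates and the NSR domain of 10), but
#' actual sequences are arbitrary labels. This generator draws a concrete,
#' reproducible assignment: one 5-mer binding site per amino-acid type
#' (P, Q, R, S, T, L), gene motifs formed by concatenating the two sites of
#' each encoded dipeptide, a 10-mer NSR characteristic domain, and a 10-mer
#' control RNA motif that encodes nothing. Constraints enforced: all sites
#' pairwise distinct; neither the NSR domain nor the control motif contains
#' a binding site; all 10-mer motifs are pairwise distinct and none equals
#' its own reverse complement (so a single copy event cannot restore
#' function). The package-wide default is `default_sequence_defs(1)`.
#'
#' @param seed Integer seed; the result is a deterministic function of it.
#' @return An object of class `drt_seqdefs`: list with `codebook` (named
#'   character vector of six 5-mers), `msp_pair`, `nsp_pair`, `control_pair`
#'   (ordered amino-acid pairs), `nsr_motif`, `control_rna_motif`, and the
#'   derived gene motifs `mspg`, `nspg`, `control_gene`.
#' @export
#' @examples
#' sd <- default_sequence_defs()
#' nchar(sd$mspg)  # 10: five nucleotides per encoded amino acid
default_sequence_defs <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    # six distinct binding-site 5-mers
    sites <- character(0)
    while (length(sites) < 6) {
      s <- .rand_mer(5)
      if (!(s %in% sites)) sites <- c(sites, s)
    }
    names(sites) <- c("P", "Q", "R", "S", "T", "L")
    msp_pair <- c("P", "Q")
    nsp_pair <- c("R", "S")
    control_pair <- c("T", "L")
    genes <- c(
      paste0(sites["P"], sites["Q"]),
      paste0(sites["R"], sites["S"]),
      paste0(sites["T"], sites["L"])
    )
    ok10 <- function(m, taken) {
      !(m %in% taken) &&
        m != .revcomp(m) &&
        !.contains_any(m, sites)
    }
    repeat {
      nsr <- .rand_mer(10)
      if (ok10(nsr, genes)) break
    }
    repeat {
      ctr <- .rand_mer(10)
      if (ok10(ctr, c(genes, nsr))) break
    }
    sd <- list(
      codebook = sites,
      msp_pair = msp_pair,
      nsp_pair = nsp_pair,
      control_pair = control_pair,
      nsr_motif = nsr,
      control_rna_motif = ctr,
      mspg = unname(genes[1]),
      nspg = unname(genes[2]),
      control_gene = unname(genes[3])
    )
    class(sd) <- "drt_seqdefs"
    validate_sequence_defs(sd)
  })
}

#' Validate sequence definitions
#'
#' @param sd A `drt_seqdefs`-like list.
#' @param L_AABS Binding-site length the codebook must match.
#' @param L_NSR Required NSR-domain length.
#' @return The validated object.
#' @export
validate_sequence_defs <- function(sd, L_AABS = 5, L_NSR = 10) {
  cb <- sd$codebook
  if (length(cb) != 6 || !setequal(names(cb), c("P", "Q", "R", "S", "T", "L")))
    stop("codebook must map the six amino-acid types", call. = FALSE)
  if (any(nchar(cb) != L_AABS))
    stop("all binding sites must have length ", L_AABS, call. = FALSE)
  if (anyDuplicated(cb)) stop("binding sites must be distinct", call. = FALSE)
  if (any(!grepl("^[ACGU]+$", c(cb, sd$nsr_motif, sd$control_rna_motif))))
    stop("sequences must be over {A,C,G,U}", call. = FALSE)
  genes <- c(
    paste0(cb[sd$msp_pair[1]], cb[sd$msp_pair[2]]),
    paste0(cb[sd$nsp_pair[1]], cb[sd$nsp_pair[2]]),
    paste0(cb[sd$control_pair[1]], cb[sd$control_pair[2]])
  )
  motifs <- c(genes, sd$nsr_motif, sd$control_rna_motif)
  if (any(nchar(sd$nsr_motif) != L_NSR, nchar(sd$control_rna_motif) != L_NSR))
    stop("10-mer motifs must have length ", L_NSR, call. = FALSE)
  if (anyDuplicated(motifs))
    stop("gene motifs, NSR motif, and control motif must be pairwise distinct",
         call. = FALSE)
  for (m in motifs) {
    if (m == .revcomp(m))
      stop("motif ", m, " is its own reverse complement", call. = FALSE)
  }
  for (m in c(sd$nsr_motif, sd$control_rna_motif)) {
    if (.contains_any(m, cb))
      stop("motif ", m, " contains an amino-acid-binding site", call. = FALSE)
  }
  sd$mspg <- unname(genes[1])
  sd$nspg <- unname(genes[2])
  sd$control_gene <- unname(genes[3])
  class(sd) <- "drt_seqdefs"
  sd
}

#' Resolve a symbolic gene/RNA name to its sequence
#'
#' Known names: `"MSPG"`, `"NSPG"`, `"NSR"`, `"CTPG"` (control peptide
#' gene), `"CTR"` (control RNA).
#'
#' @param name Character vector of symbolic names.
#' @param seq_defs Sequence definitions.
#' @return Character vector of sequences.
#' @export
gene_sequence <- function(name, seq_defs) {
  tab <- c(
    MSPG = seq_defs$mspg,
    NSPG = seq_defs$nspg,
    NSR = seq_defs$nsr_motif,
    CTPG = seq_defs$control_gene,
    CTR = seq_defs$control_rna_motif
  )
  bad <- setdiff(name, names(tab))
  if (length(bad) > 0)
    stop("unknown gene name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unname(tab[name])
}
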