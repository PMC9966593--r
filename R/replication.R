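#' Copy one RNA template in isolation and return the daughter sequence
#'
#' A fidelity probe: a single template strand is placed in a one-room world
#' with a supply of free nucleotides and no degradation, random ligation,
#' or amino-acid events; the engine runs until template-directed synthesis
#' releases the first free full-length complementary copy, which is
#' returned. A daughter differing from the exact reverse complement of the
#' template carries at least one mutation (false base-pairing, probability
#' `P_FP` per recruited monomer), so the expected mutant fraction over many
#' calls is `1 - (1 - P_FP)^L` for a template of length `L`.
#'
#' @param template RNA sequence to copy.
#' @param params Parameter set (`P_AT`, `P_TL`, `P_SP`, `P_FP` drive the
#'   copy cycle).
#' @param seq_defs Sequence definitions.
#' @param seed Seed for this copy's world.
#' @param nt_each Free nucleotides of each base supplied.
#' @param max_steps Give up after this many steps.
#' @return The daughter sequence (5'->3'), or `NA` if none was completed.
#' @export
#' @examples
#' sd <- default_sequence_defs()
#' d <- replicate_template_once(sd$mspg, seed = 1)
#' identical(d, reverse_complement(sd$mspg))  # TRUE unless a rare mutation
replicate_template_once <- function(template,
                                    params = default_params(),
                                    seq_defs = default_sequence_defs(),
                                    seed = 1L, nt_each = 20L,
                                    max_steps = 500L) {
  p <- validate_params(modifyList(unclass(params), list(
    N = 1, T_NPB = 0, T_APB = 0, T_AAPB = 0,
    P_RL = 0, P_BB = 0, P_NDE = 0, P_AABR = 0, P_MF = 0, P_ND = 0,
    P_NF = 0, P_MV = 0
  )))
  w <- init_world(p, seq_defs, seed, scatter = FALSE)
  cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, template, 0L, "")
  cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                      c(nt_A = as.integer(nt_each),
                        nt_C = as.integer(nt_each),
                        nt_G = as.integer(nt_each),
                        nt_U = as.integer(nt_each)))
  for (k in seq_len(max_steps)) {
    cpp_world_step(w$ptr, 1L)
    d <- cpp_world_first_free_copy(w$ptr, template)
    if (nzchar(d)) return(d)
  }
  NA_character_
}

#' Reverse complement of an RNA sequence
#'
#' @param seq Character vector over `{A,C,G,U}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, .revcomp, character(1), USE.NAMES = FALSE)
}
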