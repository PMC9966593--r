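#' Probability kernels
#'
#' Closed-form per-step probabilities used by the engine. Each function is
#' the single implementation of its formula; the Monte Carlo engine calls
#' the same compiled code.
#'
#' @name kernels
#' @param params A `drt_params` object (defaults to [default_params()]).
NULL

#' @describeIn kernels Membrane formation from `a` free amphiphiles:
#'   `1 - (1 - P_MF)^x` with `x = a - L_AM + 1`; 0 below the threshold
#'   `L_AM`. At `a = L_AM` the value is exactly `P_MF`.
#' @param a Free amphiphile count in the room.
#' @export
membrane_formation_probability <- function(a, params = default_params()) {
  stopifnot(a >= 0)
  cpp_membrane_formation_probability(a, params$P_MF, params$L_AM)
}

#' @describeIn kernels Separation of a duplex with `n` base pairs:
#'   `P_SP ^ sqrt(n)`. Strictly decreasing in `n` for `P_SP < 1`.
#' @param n Number of base pairs in the paired segment.
#' @export
separation_probability <- function(n, params = default_params()) {
  if (any(n < 1)) stop("paired length n must be >= 1", call. = FALSE)
  vapply(n, cpp_separation_probability, numeric(1), P_SP = params$P_SP)
}

#' @describeIn kernels Phosphodiester bond breaking. Single-strand regions
#'   break with `P_BB` (times `F_DO` outside protocells, capped at 1);
#'   double-strand regions require both parallel bonds to break, squaring
#'   the single-strand value.
#' @param region `"single"` or `"double"`.
#' @param outside Logical: is the RNA outside any protocell?
#' @export
bond_break_probability <- function(region = c("single", "double"),
                                   outside = FALSE,
                                   params = default_params()) {
  region <- match.arg(region)
  cpp_bond_break_probability(region == "double", outside,
                             params$P_BB, params$F_DO)
}

#' @describeIn kernels Protocell division:
#'   `max(0, P_CD * (1 - 2 * L_AM / b))`. Zero for `b <= 2 * L_AM`.
#' @param b Membrane amphiphile count.
#' @export
division_probability <- function(b, params = default_params()) {
  if (any(b < 1)) stop("membrane size b must be >= 1", call. = FALSE)
  vapply(b, cpp_division_probability, numeric(1),
         P_CD = params$P_CD, L_AM = params$L_AM)
}

#' @describeIn kernels Amphiphile desorption from the membrane:
#'   `P_ALM / (y * z)` with osmotic factor `y = 1 + i / (b/2)^(3/2)` and
#'   MSP factor `z = 1 + F_MSP * p`.
#' @param i Inner impermeable-ion quantity (free nucleotides plus all RNA
#'   nucleotide residues inside the protocell).
#' @param p Membrane-embedded MSP count.
#' @export
amphiphile_leave_probability <- function(b, i, p,
                                         params = default_params()) {
  if (any(b < 2)) stop("membrane size b must be >= 2", call. = FALSE)
  stopifnot(i >= 0, p >= 0)
  cpp_amphiphile_leave_probability(b, i, p, params$P_ALM, params$F_MSP)
}

#' @describeIn kernels Precursor permeation through the membrane. For
#'   nucleotide precursors `P_NPP * (b / L_AM) / y` (the divisor models
#'   Donnan suppression by charged impermeable species); for amphiphile and
#'   amino-acid precursors `P_APP * (b / L_AM)` and `P_AAPP * (b / L_AM)`.
#'   Values are capped at 1.
#' @param species `"Np"`, `"Ap"`, or `"Aap"`.
#' @export
permeation_probability <- function(species = c("Np", "Ap", "Aap"), b, i = 0,
                                   params = default_params()) {
  species <- match.arg(species)
  if (any(b < 2)) stop("membrane size b must be >= 2", call. = FALSE)
  code <- match(species, c("Np", "Ap", "Aap")) - 1L
  cpp_permeation_probability(code, b, i, unclass(validate_params(params)))
}

#' @describeIn kernels Movement of a polymer or complex of relative mass
#'   `m`: `P_MV / sqrt(m)` (Zimm scaling of the diffusion coefficient).
#'   Monomers and precursors have `m = 1`. Bound amino acids, peptides, and
#'   complement strands count toward the mass of the complex.
#' @param m Relative mass (>= 1).
#' @export
polymer_move_probability <- function(m, params = default_params()) {
  if (any(m < 1)) stop("relative mass m must be >= 1", call. = FALSE)
  vapply(m, cpp_polymer_move_probability, numeric(1), P_MV = params$P_MV)
}

#' @describeIn kernels Nucleotide formation from a precursor, depending on
#'   which catalyst is co-resident: none (`P_NF`), a nucleotide synthetase
#'   ribozyme (`P_NFR`), a nucleotide synthetase peptide (`P_NFP`), or both
#'   (the more efficient of the two; the catalysts act as alternatives and
#'   copies do not stack).
#' @param catalyst `"none"`, `"NSR"`, `"NSP"`, or `"both"`.
#' @export
nucleotide_formation_probability <- function(catalyst = c("none", "NSR",
                                                          "NSP", "both"),
                                             params = default_params()) {
  catalyst <- match.arg(catalyst)
  switch(catalyst,
    none = params$P_NF,
    NSR = params$P_NFR,
    NSP = params$P_NFP,
    both = max(params$P_NFR, params$P_NFP)
  )
}
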