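#' Default simulation parameters
#'
#' Returns the full parameter set of the protocell model with its published
#' default values: per-step event probabilities for molecules, RNA, peptides,
#' membranes, and protocells, together with the structural constants (grid
#' side `N`, initial precursor totals `T_NPB`/`T_APB`/`T_AAPB`, degradation
#' factors `F_DO` (outside protocells) and `F_DW` (within the membrane), the
#' MSP-effect factor `F_MSP`, the membrane-formation threshold `L_AM`, and
#' the characteristic lengths `L_NSR` and `L_AABS`).
#'
#' @return An object of class `drt_params`: a validated named list.
#' @export
#' @examples
#' p <- default_params()
#' p$P_BB
default_params <- function() {
  p <- list(
    # protocell / RNA events
    P_AD  = 0.01,    # amphiphile decays into its precursor
    P_AF  = 0.02,    # amphiphile forms from its precursor
    P_AJM = 0.2,     # amphiphile joins the membrane
    P_ALM = 0.001,   # amphiphile leaves the membrane
    P_APP = 0.9,     # amphiphile precursor permeates the membrane
    P_AT  = 0.9,     # template attracts a substrate by base-pairing
    P_BB  = 1e-5,    # phosphodiester bond breaks within an RNA chain
    P_CB  = 2e-4,    # protocell breaks
    P_CD  = 0.05,    # protocell divides
    P_CF  = 0.001,   # two adjacent protocells fuse
    P_FP  = 1e-4,    # false base-pairing during substrate attraction
    P_MC  = 0.1,     # protocell moves
    P_MF  = 0.1,     # membrane forms
    P_MV  = 0.9,     # monomer or precursor moves
    P_ND  = 0.05,    # nucleotide decays into its precursor
    P_NDE = 0.001,   # chain-end nucleotide residue decays
    P_NF  = 0.02,    # nucleotide forms (non-enzymatic)
    P_NFR = 0.5,     # nucleotide forms, catalyzed by NSR
    P_NPP = 0.5,     # nucleotide precursor permeates the membrane
    P_RL  = 1e-6,    # random ligation of nucleotides and RNA
    P_SP  = 0.5,     # separation of one base pair
    P_TL  = 0.5,     # template-directed ligation
    # amino-acid / peptide / DRT events
    P_AABR = 0.9,    # amino acid binds onto an RNA binding site
    P_AAD  = 0.2,    # amino acid decays into its precursor
    P_AADE = 0.1,    # chain-end amino-acid residue of a peptide decays
    P_AAF  = 0.1,    # amino acid forms from its precursor
    P_AAPP = 0.9,    # amino acid precursor permeates the membrane
    P_AATL = 0.5,    # amino-acid ligation on the template (DRT mechanism)
    P_NFP  = 0.5,    # nucleotide forms, catalyzed by NSP
    P_PBB  = 0.01,   # peptide bond breaks
    P_PJM  = 0.9,    # MSP joins the membrane
    P_PLM  = 0.1,    # MSP leaves the membrane
    P_PLR  = 0.2,    # amino acid or peptide leaves the RNA template
    # structural constants
    N      = 30,     # grid side length
    T_NPB  = 50000,  # total nucleotide precursors introduced at start
    T_APB  = 50000,  # total amphiphile precursors introduced at start
    T_AAPB = 50000,  # total amino-acid precursors introduced at start
    F_DO   = 20,     # degradation factor outside protocells (>= 1)
    F_DW   = 0.1,    # degradation factor within the membrane (in (0, 1])
    F_MSP  = 1,      # strength of the MSP membrane-stabilizing effect
    L_AM   = 200,    # lower limit of amphiphiles to form a membrane
    L_NSR  = 10,     # length of the NSR characteristic domain (nt)
    L_AABS = 5       # length of an amino-acid-binding site (nt)
  )
  class(p) <- "drt_params"
  p
}

.prob_fields <- function() {
  c("P_AD", "P_AF", "P_AJM", "P_ALM", "P_APP", "P_AT", "P_BB", "P_CB",
    "P_CD", "P_CF", "P_FP", "P_MC", "P_MF", "P_MV", "P_ND", "P_NDE",
    "P_NF", "P_NFR", "P_NPP", "P_RL", "P_SP", "P_TL", "P_AABR", "P_AAD",
    "P_AADE", "P_AAF", "P_AAPP", "P_AATL", "P_NFP", "P_PBB", "P_PJM",
    "P_PLM", "P_PLR")
}

#' Validate a parameter set
#'
#' Checks field names, probability ranges, and the structural constraints
#' (`F_DO >= 1`, `0 < F_DW <= 1`, `F_MSP >= 0`, positive lengths and
#' non-negative totals). Errors name the offending field.
#'
#' @param params A named list or `drt_params` object.
#' @return The validated `drt_params` object (invisibly usable).
#' @export
validate_params <- function(params) {
  defaults <- default_params()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- modifyList(unclass(defaults), unclass(params))
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (f in .prob_fields()) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop("parameter '", f, "' is a probability and must lie in [0, 1]; ",
           "got ", p[[f]], call. = FALSE)
    }
  }
  if (p$N < 1 || p$N != round(p$N)) stop("'N' must be a positive integer",
                                         call. = FALSE)
  for (f in c("T_NPB", "T_APB", "T_AAPB")) {
    if (p[[f]] < 0) stop("'", f, "' must be non-negative", call. = FALSE)
  }
  if (p$F_DO < 1) stop("'F_DO' must be >= 1", call. = FALSE)
  if (p$F_DW <= 0 || p$F_DW > 1) stop("'F_DW' must lie in (0, 1]",
                                      call. = FALSE)
  if (p$F_MSP < 0) stop("'F_MSP' must be >= 0", call. = FALSE)
  for (f in c("L_AM", "L_NSR", "L_AABS")) {
    if (p[[f]] < 1) stop("'", f, "' must be >= 1", call. = FALSE)
  }
  class(p) <- "drt_params"
  p
}

#' Construct a parameter set with selective overrides
#'
#' @param ... Named parameter values overriding the defaults of
#'   [default_params()].
#' @return A validated `drt_params` object.
#' @export
#' @examples
#' sim_params(F_MSP = 0, N = 10)
sim_params <- function(...) {
  validate_params(modifyList(unclass(default_params()), list(...)))
}

#' Load parameters from a YAML file with optional overrides
#'
#' Unspecified fields take their default values; `overrides` win over file
#' values (mirroring command-line `--set NAME=VALUE` semantics).
#'
#' @param path Path to a YAML file of `name: value` pairs, or `NULL` for
#'   defaults only.
#' @param overrides Named list applied after the file.
#' @return A validated `drt_params` object.
#' @export
load_params <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  validate_params(modifyList(modifyList(unclass(default_params()), vals),
                             overrides))
}

#' Save parameters to a YAML file
#'
#' `load_params(save_params(p, f))` reproduces `p` exactly.
#'
#' @param params A `drt_params` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  yaml::write_yaml(unclass(validate_params(params)), path)
  invisible(path)
}
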