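#' Construct a scenario
#'
#' A scenario describes one computational experiment: the run length and
#' reporting cadence, parameter overrides applied at step 0, timed
#' inoculation events (new protocells with gene copies, or single gene
#' copies inserted into existing protocells of a given class), and a timed
#' parameter schedule (values turned up or down mid-run).
#'
#' @param total_steps Number of Monte Carlo steps to run.
#' @param report_every Census cadence (steps).
#' @param params_overrides Named list of parameter values applied before
#'   the run starts.
#' @param inoculations List of events. A *cells* event is
#'   `list(step =, n_cells =, genes = c("MSPG", ...), b = NA, every = NA)`
#'   (each element of `genes` is one copy; `b` defaults to `2 * L_AM`).
#'   A *gene* event is
#'   `list(step =, gene = "MSPG", required = c("NSR"), every = NA)`;
#'   `required = "empty"` targets protocells with no RNA. A finite `every`
#'   repeats the event up to `total_steps`.
#' @param schedule List of `list(step =, param =, value =)` changes applied
#'   immediately before the phases of `step`.
#' @param name Optional label.
#' @return A `drt_scenario` object.
#' @export
scenario <- function(total_steps, report_every = 100,
                     params_overrides = list(), inoculations = list(),
                     schedule = list(), name = NULL) {
  sc <- list(name = name, total_steps = as.double(total_steps),
             report_every = as.double(report_every),
             params_overrides = params_overrides,
             inoculations = lapply(inoculations, .norm_inoc),
             schedule = lapply(schedule, .norm_sched))
  class(sc) <- "drt_scenario"
  validate_scenario(sc)
}

.norm_inoc <- function(ev) {
  out <- list(step = as.double(ev$step),
              every = if (is.null(ev$every) || is.na(ev$every)) NA_real_
                      else as.double(ev$every))
  if (!is.null(ev[["gene"]])) {
    out$gene <- as.character(ev[["gene"]])
    out$required <- as.character(unlist(ev$required))
  } else {
    out$n_cells <- as.double(ev$n_cells)
    out$genes <- as.character(unlist(ev$genes))
    out$b <- if (is.null(ev$b) || is.na(ev$b)) NA_real_ else as.double(ev$b)
  }
  out
}

.norm_sched <- function(ev) {
  list(step = as.double(ev$step), param = as.character(ev$param),
       value = as.double(ev$value))
}

#' Validate a scenario
#' @param sc A `drt_scenario`.
#' @return The validated scenario.
#' @export
validate_scenario <- function(sc) {
  stopifnot(sc$total_steps >= 0, sc$report_every >= 1)
  known_genes <- c("MSPG", "NSPG", "NSR", "CTPG", "CTR")
  steps <- vapply(sc$inoculations, function(e) e$step, numeric(1))
  if (length(steps) > 1 && any(diff(steps) < 0))
    stop("inoculation steps must be non-decreasing", call. = FALSE)
  for (e in sc$inoculations) {
    gg <- if (!is.null(e[["gene"]])) c(e[["gene"]], setdiff(e$required, "empty"))
          else e$genes
    bad <- setdiff(gg, known_genes)
    if (length(bad) > 0)
      stop("unknown gene name(s) in scenario: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ssteps <- vapply(sc$schedule, function(e) e$step, numeric(1))
  if (length(ssteps) > 1 && any(diff(ssteps) < 0))
    stop("schedule steps must be strictly non-decreasing", call. = FALSE)
  if (length(sc$params_overrides) > 0)
    validate_params(sc$params_overrides)
  for (e in sc$schedule)
    validate_params(stats::setNames(list(e$value), e$param))
  sc
}

#' Save and load scenarios (YAML)
#'
#' `load_scenario(save_scenario(sc, f))` reproduces `sc`.
#'
#' @param sc A `drt_scenario`.
#' @param path File path.
#' @return `save_scenario`: `path` invisibly; `load_scenario`: a
#'   `drt_scenario`.
#' @export
save_scenario <- function(sc, path) {
  yaml::write_yaml(unclass(validate_scenario(sc)), path)
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  scenario(total_steps = raw$total_steps,
           report_every = raw$report_every,
           params_overrides = if (is.null(raw$params_overrides)) list()
                              else raw$params_overrides,
           inoculations = if (is.null(raw$inoculations)) list()
                          else raw$inoculations,
           schedule = if (is.null(raw$schedule)) list() else raw$schedule,
           name = raw$name)
}

# canonical run lengths for the shipped presets (the published figures do
# not print axis limits; these lengths let every preset reach its reported
# qualitative endpoint and scale proportionally when total_steps is given)
.preset_canonical_steps <- c(
  fig2a = 3e5, fig2b = 3e5, fig4a = 5e5, fig4b = 1e6, fig5a = 5e5,
  fig5b = 1e6, competition_nsr_vs_nspg = 1e6
)

# fig3 parameter-turning values (three turns, up or down)
.fig3_turns <- list(
  F_MSP = list(up = c(5, 20, 100), down = c(0.2, 0.05, 0.01)),
  P_AABR = list(up = c(0.95, 0.98, 0.99), down = c(0.2, 0.05, 0.01)),
  P_AATL = list(up = c(0.9, 0.95, 0.98), down = c(0.05, 0.005, 5e-4)),
  P_AADE = list(up = c(0.2, 0.5, 0.9), down = c(0.05, 0.02, 0.01))
)

#' Shipped scenario presets
#'
#' Named presets encoding the package's reference experiments:
#' \describe{
#'   \item{`fig2a`}{Spread of MSPG protocells: at step 1e4, ten protocells
#'     each carrying 5 MSPG and 5 control-peptide-gene copies.}
#'   \item{`fig2b`}{De novo emergence: an empty vesicle at step 1000; at
#'     step 1e4 one MSPG copy into an empty protocell and one control gene
#'     copy into another.}
#'   \item{`fig3_<param>_<up|down>`}{`fig2a` plus a three-stage parameter
#'     turn of `F_MSP`, `P_AABR`, `P_AATL`, or `P_AADE` at 1/4, 1/2, and
#'     3/4 of the run.}
#'   \item{`fig4a`}{Cooperation: ten protocells with 5 copies each of MSPG,
#'     control peptide gene, NSR, and control RNA at step 1e4.}
#'   \item{`fig4b`}{Emergence in a ribozyme world: NSR protocells at step
#'     1e4; from step 2e5 every 1e4 steps, one MSPG copy into a random NSR
#'     protocell and one control gene copy into another.}
#'   \item{`fig5a`}{MSPG + NSPG cooperation (with `P_NF = 0.01`,
#'     `P_NFR = 0.2`, `P_NFP = 0.9`).}
#'   \item{`fig5b`}{Functional takeover of NSR by NSPG (same overrides as
#'     `fig5a`): MSPG+NSR protocells at step 1e4; from step 2e5 every 1e4
#'     steps, one NSPG copy into a random MSPG+NSR protocell and one
#'     control gene copy into another.}
#'   \item{`competition_nsr_vs_nspg`}{Head-to-head spread of NSR vs NSPG
#'     from shared protocells, `P_NFR = 0.5` and `P_NFP` set by `p_nfp`
#'     (published decision boundary lies between 0.25 and 0.275).}
#' }
#'
#' When `total_steps`, `n_grid`, or `totals` are supplied, the run is
#' rescaled: event steps and repeat intervals scale proportionally with
#' `total_steps` (the preset's shape is preserved), `n_grid` overrides the
#' grid side, and `totals` overrides all three initial precursor totals
#' (preserving the per-room material density when the area shrinks).
#'
#' @param name Preset name.
#' @param total_steps,n_grid,totals Optional rescaling, see above.
#' @param report_every Census cadence.
#' @param p_nfp NSP catalytic efficiency for the competition preset.
#' @return A `drt_scenario`.
#' @export
#' @examples
#' sc <- preset("fig2a", total_steps = 5e4, n_grid = 10, totals = 5000)
preset <- function(name, total_steps = NULL, n_grid = NULL, totals = NULL,
                   report_every = 500, p_nfp = 0.3) {
  fig3 <- grepl("^fig3_", name)
  if (!fig3 && !(name %in% names(.preset_canonical_steps)))
    stop("unknown preset '", name, "'", call. = FALSE)
  canonical <- if (fig3) 3e5 else .preset_canonical_steps[[name]]
  total <- if (is.null(total_steps)) canonical else as.double(total_steps)
  f <- total / canonical
  sstep <- function(s) max(1, round(s * f))

  overrides <- list()
  if (!is.null(n_grid)) overrides$N <- n_grid
  if (!is.null(totals)) {
    overrides$T_NPB <- totals
    overrides$T_APB <- totals
    overrides$T_AAPB <- totals
  }

  inoc <- list()
  sched <- list()
  base <- if (fig3) "fig3" else name

  if (name %in% c("fig2a") || fig3) {
    inoc <- list(list(step = sstep(1e4), n_cells = 10,
                      genes = rep(c("MSPG", "CTPG"), each = 5)))
  }
  if (fig3) {
    parts <- strsplit(sub("^fig3_", "", name), "_(?=up$|down$)",
                      perl = TRUE)[[1]]
    par_nm <- parts[1]
    dir <- parts[2]
    vals <- .fig3_turns[[par_nm]][[dir]]
    if (is.null(vals)) stop("unknown preset '", name, "'", call. = FALSE)
    turn_steps <- round(total * c(0.25, 0.5, 0.75))
    sched <- Map(function(s, v) list(step = s, param = par_nm, value = v),
                 turn_steps, vals)
  }
  if (name == "fig2b") {
    inoc <- list(
      list(step = sstep(1000), n_cells = 1, genes = character(0)),
      list(step = sstep(1e4), gene = "MSPG", required = "empty"),
      list(step = sstep(1e4), gene = "CTPG", required = "empty")
    )
  }
  if (name == "fig4a") {
    inoc <- list(list(step = sstep(1e4), n_cells = 10,
                      genes = rep(c("MSPG", "CTPG", "NSR", "CTR"),
                                  each = 5)))
  }
  if (name == "fig4b") {
    inoc <- list(
      list(step = sstep(1e4), n_cells = 10,
           genes = rep(c("NSR", "CTR"), each = 5)),
      list(step = sstep(2e5), every = sstep(1e4), gene = "MSPG",
           required = "NSR"),
      list(step = sstep(2e5), every = sstep(1e4), gene = "CTPG",
           required = "NSR")
    )
  }
  if (name == "fig5a") {
    overrides <- c(overrides, list(P_NF = 0.01, P_NFR = 0.2, P_NFP = 0.9))
    inoc <- list(list(step = sstep(1e4), n_cells = 10,
                      genes = rep(c("MSPG", "NSPG", "CTPG"), each = 5)))
  }
  if (name == "fig5b") {
    overrides <- c(overrides, list(P_NF = 0.01, P_NFR = 0.2, P_NFP = 0.9))
    inoc <- list(
      list(step = sstep(1e4), n_cells = 10,
           genes = rep(c("MSPG", "CTPG", "NSR", "CTR"), each = 5)),
      list(step = sstep(2e5), every = sstep(1e4), gene = "NSPG",
           required = c("MSPG", "NSR")),
      list(step = sstep(2e5), every = sstep(1e4), gene = "CTPG",
           required = c("MSPG", "NSR"))
    )
  }
  if (name == "competition_nsr_vs_nspg") {
    overrides <- c(overrides, list(P_NFR = 0.5, P_NFP = p_nfp))
    inoc <- list(list(step = sstep(1e4), n_cells = 10,
                      genes = rep(c("NSR", "NSPG"), each = 5)))
  }
  if (!fig3 && !(name %in% c("fig2a", "fig2b", "fig4a", "fig4b", "fig5a",
                             "fig5b", "competition_nsr_vs_nspg")))
    stop("unknown preset '", name, "'", call. = FALSE)

  scenario(total_steps = total, report_every = report_every,
           params_overrides = overrides, inoculations = inoc,
           schedule = sched, name = name)
}
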