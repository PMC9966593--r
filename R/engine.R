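#' Run a scenario and collect the census time series
#'
#' Creates a world from `params` (with the scenario's overrides applied),
#' then executes the Monte Carlo loop to `total_steps`. Inoculations and
#' parameter-schedule changes are applied at their exact steps, before that
#' step's event phases. A census is recorded at step 0 and every
#' `report_every` steps. With `audit = TRUE` the exact conservation audit
#' runs at every reporting step and its outcome is stored per row.
#'
#' @param scenario A `drt_scenario` (see [scenario()] and [preset()]).
#' @param params Base parameter set.
#' @param seq_defs Sequence definitions.
#' @param seed Integer seed; fully determines the run.
#' @param audit Logical; record exact ledger audits at reporting steps.
#' @return A tibble of class `drt_series`, one row per census: protocell
#'   totals, exact gene-content class counts (list column `classes`), gene
#'   copy counts, peptide counts, and raw material totals. Attributes:
#'   `params`, `scenario`, `seed`, and `events` (a log of applied and
#'   skipped inoculations and schedule changes).
#' @export
#' @examples
#' sc <- preset("fig2a", total_steps = 2000, n_grid = 5, totals = 500,
#'              report_every = 1000)
#' run_scenario(sc, seed = 1)
run_scenario <- function(scenario, params = default_params(),
                         seq_defs = default_sequence_defs(), seed = 1L,
                         audit = FALSE) {
  scenario <- validate_scenario(scenario)
  params <- validate_params(modifyList(unclass(params),
                                       scenario$params_overrides))
  w <- init_world(params, seq_defs, seed)
  total <- scenario$total_steps
  re <- scenario$report_every

  # expand events into per-step action lists
  actions <- list()
  push <- function(step, act) {
    key <- as.character(step)
    actions[[key]] <<- c(actions[[key]], list(act))
  }
  for (e in scenario$schedule) {
    if (e$step <= total) push(e$step, c(list(kind = "schedule"), e))
  }
  for (e in scenario$inoculations) {
    if (e$step > total) next  # event lies beyond a truncated run
    steps <- if (is.na(e$every)) e$step else seq(e$step, total, by = e$every)
    for (s in steps) push(s, c(list(kind = "inoculate"), e))
  }
  event_steps <- sort(unique(as.numeric(names(actions))))
  report_steps <- unique(c(seq_len(floor(total / re)) * re, total))
  report_steps <- report_steps[report_steps >= 1]
  breaks <- sort(unique(c(event_steps, report_steps)))

  censuses <- list()
  audits <- logical(0)
  events_log <- list()
  record <- function() {
    cen <- cpp_world_census(w$ptr)
    censuses[[length(censuses) + 1L]] <<- cen
    if (audit) {
      a <- cpp_world_audit(w$ptr)
      audits[length(audits) + 1L] <<- all(a$expected == a$observed)
    }
  }
  record()  # step 0

  cur <- 0
  for (s in breaks) {
    if (s - 1 > cur) {
      cpp_world_step(w$ptr, as.integer(s - 1 - cur))
      cur <- s - 1
    }
    key <- as.character(s)
    if (!is.null(actions[[key]])) {
      for (act in actions[[key]]) {
        if (act$kind == "schedule") {
          set_world_param(w, act$param, act$value)
          events_log[[length(events_log) + 1L]] <-
            list(step = s, event = "schedule", param = act$param,
                 value = act$value)
        } else if (!is.null(act[["gene"]])) {
          idx <- insert_gene(w, act[["gene"]], act$required)
          events_log[[length(events_log) + 1L]] <-
            list(step = s, event = "insert_gene", gene = act$gene,
                 room = idx, skipped = is.na(idx))
        } else {
          b <- if (is.na(act$b)) 2 * params$L_AM else act$b
          idx <- inoculate_cells(w, act$n_cells, act$genes, b)
          events_log[[length(events_log) + 1L]] <-
            list(step = s, event = "inoculate_cells",
                 n_cells = act$n_cells, placed = length(idx))
        }
      }
    }
    cpp_world_step(w$ptr, 1L)
    cur <- s
    if (s %in% report_steps) record()
  }

  out <- .series_from_censuses(censuses)
  if (audit) out$audit_ok <- audits
  attr(out, "params") <- params
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- as.integer(seed)
  attr(out, "events") <- events_log
  class(out) <- c("drt_series", class(out))
  out
}

.series_from_censuses <- function(censuses) {
  one <- function(cen) {
    g <- cen$genes
    pep <- cen$peptides
    m <- cen$materials
    tibble::tibble(
      step = cen$step, protocells = cen$protocells,
      mspg = g[["mspg"]], nspg = g[["nspg"]], nsr = g[["nsr"]],
      ctpg = g[["ctpg"]], ctr = g[["ctr"]],
      msp = pep[["msp"]], nsp = pep[["nsp"]], ctp = pep[["ctp"]],
      np = m[["np"]], ap = m[["ap"]], aap = m[["aap"]],
      nt = m[["nt"]], aa = m[["aa"]],
      am_free = m[["am_free"]], am_membrane = m[["am_membrane"]],
      rna_strands = m[["rna_strands"]], rna_residues = m[["rna_residues"]],
      peptides_free = m[["peptides_free"]],
      classes = list(cen$classes)
    )
  }
  do.call(rbind, lapply(censuses, one))
}

#' Count protocells whose gene content includes a motif
#'
#' Census classes are exact gene-content signatures (a protocell carrying
#' both MSPG and NSR counts once, in the joint class `"MSPG+NSR"`). This
#' helper sums every class containing the requested motif, i.e. the
#' "protocells containing X" reading used in time-series figures.
#'
#' @param series A `drt_series` (or its `classes` list column).
#' @param motif One of `"MSPG"`, `"NSPG"`, `"NSR"`, `"CTPG"`, `"CTR"`, or
#'   `"empty"` for protocells carrying no recognizable gene.
#' @return Numeric vector, one value per census row.
#' @export
cells_containing <- function(series, motif) {
  classes <- if (is.data.frame(series)) series$classes else series
  vapply(classes, function(cl) {
    if (length(cl) == 0) return(0)
    keys <- strsplit(names(cl), "+", fixed = TRUE)
    sum(cl[vapply(keys, function(k) motif %in% k, logical(1))])
  }, numeric(1))
}
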