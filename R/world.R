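#' Create a simulation world
#'
#' Builds an `N x N` lattice of rooms and scatters the initial precursor
#' totals (`T_NPB`, `T_APB`, `T_AAPB`) uniformly at random over the rooms.
#' No polymers and no protocells exist initially. All randomness of the
#' world (initialization and every subsequent event) flows from one
#' generator seeded here, so identical `(params, seq_defs, seed)` give
#' bitwise-identical runs.
#'
#' @param params A `drt_params` object.
#' @param seq_defs Sequence definitions.
#' @param seed Integer seed for the world's RNG stream.
#' @param scatter Logical; set `FALSE` for an empty world (used by
#'   fixtures that place material explicitly).
#' @return An object of class `drt_world`.
#' @export
#' @examples
#' w <- init_world(sim_params(N = 5, T_NPB = 100, T_APB = 100, T_AAPB = 100),
#'                 seed = 1)
#' audit_conservation(w)
init_world <- function(params = default_params(),
                       seq_defs = default_sequence_defs(),
                       seed = 1L, scatter = TRUE) {
  params <- validate_params(params)
  seq_defs <- validate_sequence_defs(seq_defs, params$L_AABS, params$L_NSR)
  ptr <- cpp_world_new(unclass(params), unclass(seq_defs), as.double(seed))
  if (scatter) {
    cpp_world_scatter_precursors(ptr, params$T_NPB, params$T_APB,
                                 params$T_AAPB)
  }
  structure(list(ptr = ptr, params = params, seq_defs = seq_defs,
                 seed = as.integer(seed)),
            class = "drt_world")
}

#' @export
print.drt_world <- function(x, ...) {
  cen <- cpp_world_census(x$ptr)
  cat("<drt_world> ", x$params$N, "x", x$params$N,
      " grid, step ", format(cen$step, big.mark = ","),
      ", ", cen$protocells, " protocell(s)\n", sep = "")
  invisible(x)
}

#' Advance a world by whole Monte Carlo steps
#'
#' Each step applies the five event phases in fixed order: protocell events
#' (break, divide, fuse, move), membrane and transport events (formation,
#' amphiphile exchange, MSP exchange, permeation), polymer events (RNA
#' degradation, random ligation, template-directed replication, DRT
#' binding/ligation/release, peptide degradation), monomer chemistry, and
#' movement of free entities. Within each phase entities are visited in
#' randomized order and each entity undergoes at most one event per phase.
#'
#' @param world A `drt_world`.
#' @param n Number of steps.
#' @return The world, invisibly (state is modified in place).
#' @export
world_step <- function(world, n = 1) {
  cpp_world_step(world$ptr, as.integer(n))
  invisible(world)
}

#' Run a single named phase once (for event-level testing)
#'
#' @param world A `drt_world`.
#' @param phase One of `"protocell"`, `"membrane"`, `"polymer"`,
#'   `"chemistry"`, `"movement"`.
#' @return The world, invisibly.
#' @export
world_run_phase <- function(world, phase) {
  cpp_world_run_phase(world$ptr, phase)
  invisible(world)
}

#' Current step counter of a world
#' @param world A `drt_world`.
#' @return Integer step number.
#' @export
world_step_no <- function(world) cpp_world_step_no(world$ptr)

#' Change one parameter of a running world
#'
#' Used by the scenario parameter schedule (e.g. turning `F_MSP` down
#' mid-run); kernels use the new value from the next executed step onward.
#'
#' @param world A `drt_world`.
#' @param name Parameter name.
#' @param value New value.
#' @return The world, invisibly.
#' @export
set_world_param <- function(world, name, value) {
  validate_params(stats::setNames(list(value), name))
  cpp_world_set_param(world$ptr, name, as.double(value))
  invisible(world)
}

#' @rdname set_world_param
#' @export
get_world_param <- function(world, name) cpp_world_get_param(world$ptr, name)

#' Toggle randomized phase order (robustness experiments)
#'
#' The default fixed phase order is a documented implementation choice;
#' randomizing it per step lets users check that conclusions do not depend
#' on it.
#'
#' @param world A `drt_world`.
#' @param on Logical.
#' @return The world, invisibly.
#' @export
world_randomize_phases <- function(world, on = TRUE) {
  cpp_world_set_phase_randomization(world$ptr, isTRUE(on))
  invisible(world)
}

#' Audit exact material conservation
#'
#' Sums every nucleotide, amphiphile, and amino-acid equivalent in the
#' system (precursors, monomers, polymer residues, bound residues, free
#' peptides, membranes) and compares with the ledger of initial plus
#' inoculated totals. The identity is exact and integer-valued; any
#' discrepancy indicates an accounting bug in an event implementation.
#'
#' @param world A `drt_world`.
#' @return A tibble with columns `class`, `expected`, `observed`, `ok`.
#' @export
audit_conservation <- function(world) {
  a <- cpp_world_audit(world$ptr)
  tibble::tibble(class = a$class, expected = a$expected,
                 observed = a$observed, ok = a$expected == a$observed)
}

#' Full structural snapshot of a world
#'
#' @param world A `drt_world`.
#' @return Nested list: grid size, step, rooms (with exterior/interior
#'   compartment contents, strands with complement segments and bound
#'   residues, peptides, membrane `b` and `p`), conservation ledger, and
#'   the serialized RNG state.
#' @export
world_state <- function(world) cpp_world_state(world$ptr)

#' Checkpoint a world to a JSON file and restore it
#'
#' The dump contains the complete mutable state including the RNG stream,
#' so a restored world continues the original trajectory exactly.
#'
#' @param world A `drt_world`.
#' @param path File path.
#' @return `world_checkpoint`: `path` invisibly. `world_restore`: a
#'   `drt_world`.
#' @export
world_checkpoint <- function(world, path) {
  st <- world_state(world)
  st$ledger <- as.list(st$ledger)  # keep names through JSON
  payload <- list(params = unclass(world$params),
                  seq_defs = lapply(unclass(world$seq_defs), function(x) {
                    if (is.null(names(x))) x else as.list(x)
                  }),
                  state = st)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname world_checkpoint
#' @export
world_restore <- function(path) {
  pay <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- validate_params(lapply(pay$params, function(x) x))
  sdl <- pay$seq_defs
  sd <- list(
    codebook = unlist(sdl$codebook),
    msp_pair = unlist(sdl$msp_pair),
    nsp_pair = unlist(sdl$nsp_pair),
    control_pair = unlist(sdl$control_pair),
    nsr_motif = sdl$nsr_motif,
    control_rna_motif = sdl$control_rna_motif
  )
  sd <- validate_sequence_defs(sd, params$L_AABS, params$L_NSR)
  w <- init_world(params, sd, seed = 0L, scatter = FALSE)
  st <- pay$state
  for (i in seq_along(st$rooms)) {
    room <- .room_from_json(st$rooms[[i]])
    cpp_world_restore_room(w$ptr, i - 1L, room)
  }
  cpp_world_set_ledger(w$ptr, unlist(st$ledger))
  cpp_world_set_step_no(w$ptr, st$step)
  cpp_world_set_rng_state(w$ptr, st$rng_state)
  w
}

.room_from_json <- function(rj) {
  fix_comp <- function(cj) {
    list(
      np = as.double(cj$np), ap = as.double(cj$ap),
      aap = as.double(cj$aap), am = as.double(cj$am),
      nt = as.double(unlist(cj$nt)),
      aa = as.double(unlist(cj$aa)),
      rnas = lapply(cj$rnas, function(r) {
        list(seq = r$seq,
             segs = lapply(r$segs, function(s)
               list(start = as.integer(s$start), bases = s$bases,
                    locked = isTRUE(s$locked))),
             occ = as.integer(unlist(r$occ)),
             lig = as.integer(unlist(r$lig)))
      }),
      peptides = as.character(unlist(cj$peptides))
    )
  }
  list(cell = isTRUE(rj$cell), b = as.double(rj$b), p = as.double(rj$p),
       out = fix_comp(rj$out), `in` = fix_comp(rj$`in`))
}

#' Inoculate protocells carrying gene copies
#'
#' Places `n_cells` new protocells into uniformly chosen rooms currently
#' without one. Each carries a two-layer membrane of `b` amphiphiles
#' (default `2 * L_AM`: viable, but below the division threshold) and the
#' given gene copies as 10-mer RNAs in its interior. All added material is
#' recorded in the conservation ledger.
#'
#' @param world A `drt_world`.
#' @param n_cells Number of protocells to place.
#' @param genes Character vector of symbolic gene names (each element one
#'   copy), e.g. `rep(c("MSPG", "CTPG"), each = 5)`; empty for a bare
#'   vesicle.
#' @param b Membrane amphiphile count.
#' @return Integer vector of room indices used (0-based), invisibly.
#' @export
inoculate_cells <- function(world, n_cells, genes = character(0),
                            b = 2 * world$params$L_AM) {
  seqs <- if (length(genes) > 0) {
    gene_sequence(genes, world$seq_defs)
  } else {
    character(0)
  }
  idx <- cpp_world_inoculate_cells(world$ptr, as.integer(n_cells),
                                   as.integer(b), seqs)
  invisible(idx)
}

#' Insert one gene copy into an existing protocell
#'
#' The target is chosen uniformly among protocells whose interior contains
#' all `required` motifs (`required = "empty"` targets protocells carrying
#' no RNA at all, as in the de novo emergence scenario). When no protocell
#' qualifies the inoculation is skipped and `NA` is returned.
#'
#' @param world A `drt_world`.
#' @param gene Symbolic gene name.
#' @param required Character vector of symbolic motif names the target must
#'   already contain, or `"empty"`.
#' @return Room index (0-based) or `NA` if skipped.
#' @export
insert_gene <- function(world, gene, required = character(0)) {
  seq <- gene_sequence(gene, world$seq_defs)
  if (length(required) == 1 && identical(required, "empty")) {
    idx <- cpp_world_insert_gene_empty_cell(world$ptr, seq)
  } else {
    req <- if (length(required) > 0) {
      gene_sequence(required, world$seq_defs)
    } else {
      character(0)
    }
    idx <- cpp_world_insert_gene(world$ptr, seq, req)
  }
  if (idx < 0) NA_integer_ else idx
}
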