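#' Deterministic miniature worlds for event-level testing
#'
#' Builds tiny, exactly specified worlds that bypass the random initial
#' scatter, so single events can be tested in milliseconds. All fixtures
#' are seed-deterministic and ledger-consistent (placed material is booked
#' as inoculated).
#'
#' Cases:
#' \describe{
#'   \item{`one_room_monomers`}{`N = 1`, only counts: `np`, `ap`, `aap`
#'     precursors (and optionally monomers) in the single room.}
#'   \item{`single_cell_msp`}{One protocell with membrane size `b`,
#'     embedded MSP count `p`, and `i` free nucleotides inside (the inner
#'     impermeable ions).}
#'   \item{`duplex`}{One RNA template of length `len` with a complement
#'     segment of `n` paired bases starting at offset 0.}
#'   \item{`drt_ready`}{One protocell containing a single MSPG copy and an
#'     ample supply of the amino acids it binds.}
#'   \item{`competition_micro`}{`N = 5`; one protocell with NSR copies and
#'     one with NSPG copies, plus scattered precursors.}
#' }
#'
#' @param case Fixture name.
#' @param params Parameter set (fixtures override `N` and totals).
#' @param seq_defs Sequence definitions.
#' @param seed RNG seed for the world stream.
#' @param ... Case-specific knobs, see Details above: `np`, `ap`, `aap`,
#'   `nt`, `aa` (`one_room_monomers`); `b`, `p`, `i` (`single_cell_msp`);
#'   `n`, `len` (`duplex`); `b`, `aa_each` (`drt_ready`); `copies`,
#'   `precursors` (`competition_micro`).
#' @return A `drt_world`.
#' @export
#' @examples
#' w <- tiny_world("single_cell_msp", b = 200, i = 1000, p = 0)
tiny_world <- function(case, params = default_params(),
                       seq_defs = default_sequence_defs(), seed = 1L, ...) {
  args <- list(...)
  arg <- function(nm, default) if (!is.null(args[[nm]])) args[[nm]] else default

  build <- function(n_grid) {
    p <- validate_params(modifyList(unclass(params),
                                    list(N = n_grid, T_NPB = 0, T_APB = 0,
                                         T_AAPB = 0)))
    init_world(p, seq_defs, seed, scatter = FALSE)
  }

  switch(case,
    one_room_monomers = {
      w <- build(1)
      counts <- c(np = arg("np", 1000), ap = arg("ap", 0),
                  aap = arg("aap", 0))
      nt <- arg("nt", 0)
      aa <- arg("aa", 0)
      if (nt > 0) counts <- c(counts, nt_A = nt)
      if (aa > 0) counts <- c(counts, aa_P = aa)
      cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                          stats::setNames(as.integer(counts), names(counts)))
      w
    },
    single_cell_msp = {
      w <- build(1)
      cpp_room_add_cell(w$ptr, 0L, 0L, as.integer(arg("b", 200)),
                        as.integer(arg("p", 0)))
      i <- arg("i", 0)
      if (i > 0) {
        cpp_room_set_counts(w$ptr, 0L, 0L, TRUE, c(nt_A = as.integer(i)))
      }
      w
    },
    duplex = {
      w <- build(1)
      len <- arg("len", 10)
      n <- arg("n", 1)
      stopifnot(n >= 1, n <= len)
      template <- arg("template",
                      paste(rep(c("A", "C", "G", "U"), length.out = len),
                            collapse = ""))
      comp <- chartr("ACGU", "UGCA",
                     substr(template, 1, n))  # position-aligned complement
      cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, template, 0L, comp)
      w
    },
    drt_ready = {
      w <- build(1)
      cpp_room_add_cell(w$ptr, 0L, 0L, as.integer(arg("b", 400)), 0L)
      cpp_room_add_rna(w$ptr, 0L, 0L, TRUE, seq_defs$mspg, 0L, "")
      aa_each <- as.integer(arg("aa_each", 50))
      counts <- stats::setNames(
        rep(aa_each, 2L),
        paste0("aa_", seq_defs$msp_pair)
      )
      cpp_room_set_counts(w$ptr, 0L, 0L, TRUE, counts)
      w
    },
    competition_micro = {
      w <- build(5)
      pre <- as.integer(arg("precursors", 500))
      if (pre > 0) cpp_world_scatter_precursors(w$ptr, pre, pre, pre)
      copies <- as.integer(arg("copies", 3))
      cpp_room_add_cell(w$ptr, 1L, 1L, 400L, 0L)
      cpp_room_add_cell(w$ptr, 3L, 3L, 400L, 0L)
      for (k in seq_len(copies)) {
        cpp_room_add_rna(w$ptr, 1L, 1L, TRUE, seq_defs$nsr_motif, 0L, "")
        cpp_room_add_rna(w$ptr, 3L, 3L, TRUE, seq_defs$nspg, 0L, "")
      }
      w
    },
    stop("unknown fixture case '", case, "'", call. = FALSE)
  )
}
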