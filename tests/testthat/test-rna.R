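# RNA polymer events: ligation, replication, separation, degradation, motifs

test_that("random ligation of two nucleotides forces a dimer at P_RL = 1", {
  w <- tiny_world("one_room_monomers", np = 0, seed = 2,
                  params = sim_params(P_RL = 1, P_ND = 0, P_MV = 0))
  drtsim:::cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                               c(nt_A = 1L, nt_U = 1L))
  world_run_phase(w, "polymer")
  cen <- take_census(w)
  expect_identical(cen$rna_strands, 1)
  expect_identical(cen$rna_residues, 2)
  expect_identical(cen$nt, 0)
})

test_that("random ligation is silent at P_RL = 0", {
  w <- tiny_world("one_room_monomers", np = 0, seed = 2,
                  params = sim_params(P_RL = 0, P_ND = 0, P_MV = 0))
  drtsim:::cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                               c(nt_A = 50L, nt_U = 50L))
  world_step(w, 50)
  expect_identical(take_census(w)$rna_strands, 0)
})

test_that("random ligation counts match the pairwise binomial rate", {
  # 100 free nucleotides: C(100,2) candidate pairs per sweep, each
  # ligating with P_RL; dimer count over replicate sweeps is binomial
  prl <- 1e-4
  reps <- 300
  pars <- sim_params(P_RL = prl, P_ND = 0, P_MV = 0, P_AT = 0,
                     P_BB = 0, P_NDE = 0, P_TL = 0, P_SP = 0)
  dimers <- 0
  for (s in seq_len(reps)) {
    w <- tiny_world("one_room_monomers", np = 0, seed = s, params = pars)
    drtsim:::cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                                 c(nt_A = 50L, nt_C = 50L))
    world_run_phase(w, "polymer")
    dimers <- dimers + take_census(w)$rna_strands
  }
  n <- reps * choose(100, 2)
  expect_lt(abs(dimers - n * prl), 4 * sqrt(n * prl * (1 - prl)))
})

test_that("substrate attraction is blocked at P_AT = 0", {
  w <- tiny_world("duplex", n = 1, len = 10, seed = 1,
                  params = sim_params(P_AT = 0, P_BB = 0, P_NDE = 0,
                                      P_SP = 0, P_MV = 0, P_ND = 0))
  drtsim:::cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                               c(nt_A = 20L, nt_C = 20L, nt_G = 20L,
                                 nt_U = 20L))
  world_step(w, 30)
  st <- world_state(w)
  expect_identical(length(st$rooms[[1]]$out$rnas[[1]]$segs), 1L)
})

test_that("with perfect fidelity a recruited monomer is the Watson-Crick partner", {
  # template base at the growth position is G; the recruited base must be C
  w <- tiny_world("one_room_monomers", np = 0, seed = 3,
                  params = sim_params(P_AT = 1, P_FP = 0, P_RL = 0,
                                      P_BB = 0, P_NDE = 0, P_SP = 0,
                                      P_ND = 0, P_MV = 0))
  drtsim:::cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, "GGGGGGGGGG", 0L, "")
  drtsim:::cpp_room_set_counts(w$ptr, 0L, 0L, FALSE,
                               c(nt_A = 5L, nt_C = 5L, nt_G = 5L,
                                 nt_U = 5L))
  world_run_phase(w, "polymer")
  st <- world_state(w)
  segs <- st$rooms[[1]]$out$rnas[[1]]$segs
  expect_identical(length(segs), 1L)
  expect_identical(segs[[1]]$bases, "C")
})

test_that("template-directed ligation merges adjacent aligned segments", {
  w <- tiny_world("one_room_monomers", np = 0, seed = 4,
                  params = sim_params(P_AT = 0, P_TL = 1, P_SP = 0,
                                      P_BB = 0, P_NDE = 0, P_MV = 0))
  # two adjacent 1-mer substrates on a 4-mer template
  drtsim:::cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, "AUGC", 0L, "U")
  st0 <- world_state(w)
  r <- st0$rooms[[1]]$out$rnas[[1]]
  expect_identical(length(r$segs), 1L)
  # add the second segment by hand through restore
  r$segs[[2]] <- list(start = 1L, bases = "A", locked = FALSE)
  room <- st0$rooms[[1]]
  room$out$rnas[[1]] <- r
  room <- drtsim:::.room_from_json(room)
  drtsim:::cpp_world_restore_room(w$ptr, 0L, room)
  world_run_phase(w, "polymer")
  st <- world_state(w)
  segs <- st$rooms[[1]]$out$rnas[[1]]$segs
  expect_identical(length(segs), 1L)
  expect_identical(segs[[1]]$bases, "UA")
  expect_true(segs[[1]]$locked)  # now part of the growing chain
})

test_that("separation frees the complement strand with the right kinetics", {
  # a full-length complement separates with P_SP^sqrt(n)
  reps <- 400
  n <- 4
  seps <- 0
  for (s in 1:reps) {
    w <- tiny_world("duplex", n = n, len = n, seed = s,
                    params = sim_params(P_AT = 0, P_BB = 0, P_NDE = 0,
                                        P_MV = 0, P_RL = 0))
    world_run_phase(w, "polymer")
    if (take_census(w)$rna_strands == 2) seps <- seps + 1
  }
  q <- 0.5^sqrt(n)
  expect_lt(abs(seps - reps * q), 4 * sqrt(reps * q * (1 - q)))
})

test_that("a released complement reads as the reverse complement", {
  w <- tiny_world("duplex", n = 10, len = 10, template = sd_default$mspg,
                  seed = 1,
                  params = sim_params(P_AT = 0, P_SP = 1, P_BB = 0,
                                      P_NDE = 0, P_MV = 0, P_RL = 0))
  world_run_phase(w, "polymer")
  st <- world_state(w)
  seqs <- vapply(st$rooms[[1]]$out$rnas, `[[`, character(1), "seq")
  expect_setequal(seqs, c(sd_default$mspg, rc(sd_default$mspg)))
})

test_that("degradation is silent when its probabilities are zero", {
  w <- tiny_world("duplex", n = 2, len = 10, seed = 1,
                  params = sim_params(P_BB = 0, P_NDE = 0, P_AT = 0,
                                      P_SP = 0, P_MV = 0))
  world_step(w, 50)
  cen <- take_census(w)
  expect_identical(cen$rna_residues, 12)
})

test_that("chain-end decay converts exactly one residue to a precursor", {
  w <- tiny_world("one_room_monomers", np = 0, seed = 2,
                  params = sim_params(P_NDE = 1, P_BB = 0, P_AT = 0,
                                      P_MV = 0, P_NF = 0, F_DO = 1))
  drtsim:::cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, "AUGCC", 0L, "")
  world_run_phase(w, "polymer")
  cen <- take_census(w)
  # both unpaired ends decay in one sweep: 5 residues -> 3 + 2 precursors
  expect_identical(cen$np, 2)
  expect_identical(cen$rna_residues, 3)
  expect_true(all(audit_conservation(w)$ok))
})

test_that("strand breaks occur at the per-bond rate", {
  # a 10-mer outside protocells: 9 bonds, each P_BB * F_DO per step
  pbb <- 1e-3
  reps <- 300
  breaks <- 0
  for (s in 1:reps) {
    w <- tiny_world("one_room_monomers", np = 0, seed = s,
                    params = sim_params(P_BB = pbb, F_DO = 20, P_NDE = 0,
                                        P_AT = 0, P_MV = 0, P_RL = 0))
    drtsim:::cpp_room_add_rna(w$ptr, 0L, 0L, FALSE, "AUGCAUGCAU", 0L, "")
    world_run_phase(w, "polymer")
    if (take_census(w)$rna_strands > 1) breaks <- breaks + 1
  }
  q <- 1 - (1 - pbb * 20)^9
  expect_lt(abs(breaks - reps * q), 4 * sqrt(reps * q * (1 - q)))
})

test_that("motif scanning is exact-match, sense-strand, and loses function on mutation", {
  sd <- sd_default
  expect_identical(unname(scan_motifs(sd$nsr_motif, sd)["NSR"]), 1L)
  mut <- sd$nsr_motif
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "U"), substr(mut, 3, 3))[1]
  expect_identical(sum(scan_motifs(mut, sd)), 0L)
  # embedded in a 20-mer
  emb <- paste0("AAAAA", sd$mspg, "UUUUU")
  expect_identical(unname(scan_motifs(emb, sd)["MSPG"]), 1L)
  # the antisense copy carries no label
  expect_identical(sum(scan_motifs(rc(sd$mspg), sd)), 0L)
  # concatemer counts both occurrences
  expect_identical(unname(scan_motifs(strrep(sd$mspg, 2), sd)["MSPG"]), 2L)
  expect_setequal(motif_labels(paste0(sd$mspg, sd$nsr_motif), sd),
                  c("MSPG", "NSR"))
})

test_that("replication fidelity follows 1 - (1 - P_FP)^L", {
  pfp <- 0.02
  L <- 10
  reps <- 200
  tmpl <- sd_default$nsr_motif
  ds <- vapply(seq_len(reps), function(s)
    replicate_template_once(tmpl, params = sim_params(P_FP = pfp),
                            seed = s), character(1))
  expect_true(all(!is.na(ds)))
  mut <- sum(ds != rc(tmpl))
  q <- 1 - (1 - pfp)^L
  expect_lt(abs(mut - reps * q), 4 * sqrt(reps * q * (1 - q)))
})
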