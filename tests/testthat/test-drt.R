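# the direct RNA template mechanism

test_that("binding sites of a dipeptide gene are two contiguous 5-mers", {
  sites <- find_binding_sites(sd_default$mspg, sd_default)
  expect_identical(sites$offset, c(0L, 5L))
  expect_identical(sites$type, sd_default$msp_pair)
  # concatemer of two gene motifs carries four sites
  sites4 <- find_binding_sites(paste0(sd_default$mspg, sd_default$nspg),
                               sd_default)
  expect_identical(nrow(sites4), 4L)
  expect_identical(sites4$offset, c(0L, 5L, 10L, 15L))
  # no binding sites in the control RNA
  expect_identical(nrow(find_binding_sites(sd_default$control_rna_motif,
                                           sd_default)), 0L)
})

test_that("amino-acid binding consumes one free amino acid and folds the RNA", {
  w <- tiny_world("drt_ready", aa_each = 10, seed = 2,
                  params = sim_params(P_AABR = 1, P_AATL = 0, P_PLR = 0,
                                      P_AAD = 0, P_AAF = 0))
  a0 <- take_census(w)$aa
  world_run_phase(w, "polymer")
  cen <- take_census(w)
  expect_identical(a0 - cen$aa, 2)  # both sites fill in one sweep
  st <- world_state(w)
  occ <- st$rooms[[1]]$`in`$rnas[[1]]$occ
  expect_true(all(occ >= 0))
  expect_true(all(audit_conservation(w)$ok))
})

test_that("binding never happens at P_AABR = 0", {
  w <- tiny_world("drt_ready", seed = 2,
                  params = sim_params(P_AABR = 0))
  world_step(w, 30)
  st <- world_state(w)
  expect_true(all(st$rooms[[1]]$`in`$rnas[[1]]$occ == -1))
})

test_that("the forced DRT chain takes bind, ligate, release on successive steps", {
  # with P_AABR = P_AATL = P_PLR = 1 each stage claims the template's one
  # polymer event per step: the first free MSP appears after three steps
  w <- tiny_world("drt_ready", seed = 1,
                  params = sim_params(P_AABR = 1, P_AATL = 1, P_PLR = 1,
                                      P_AAD = 0, P_AAF = 0, P_PBB = 0,
                                      P_AADE = 0, P_PJM = 0))
  for (k in 1:2) {
    world_step(w, 1)
    expect_identical(take_census(w)$peptides_free, 0)
  }
  world_step(w, 1)
  expect_identical(take_census(w)$peptides_free, 1)
  expect_identical(take_census(w)$msp, 1)
})

test_that("released dipeptide identity is the ordered site pair", {
  w <- tiny_world("drt_ready", seed = 1,
                  params = sim_params(P_AABR = 1, P_AATL = 1, P_PLR = 1,
                                      P_AAD = 0, P_AAF = 0, P_PBB = 0,
                                      P_AADE = 0, P_PJM = 0))
  world_step(w, 3)
  st <- world_state(w)
  pep <- st$rooms[[1]]$`in`$peptides
  expect_identical(pep, paste(sd_default$msp_pair, collapse = ""))
  expect_identical(classify_peptide(pep, sd_default), "MSP")
  # the reversed pair is a different, functionless molecule
  expect_identical(
    classify_peptide(paste(rev(sd_default$msp_pair), collapse = ""),
                     sd_default), "none")
  expect_identical(
    classify_peptide(paste(sd_default$nsp_pair, collapse = ""), sd_default),
    "NSP")
})

test_that("a folded RNA is protected from degradation", {
  # extreme degradation probabilities cannot touch an RNA with bound cargo
  w <- tiny_world("drt_ready", seed = 3,
                  params = sim_params(P_AABR = 1, P_AATL = 0, P_PLR = 0,
                                      P_BB = 1, P_NDE = 1, P_AAD = 0,
                                      P_AAF = 0))
  world_step(w, 1)   # binds and folds
  res0 <- take_census(w)$rna_residues
  world_step(w, 30)
  expect_identical(take_census(w)$rna_residues, res0)
})

test_that("peptide bond breaking returns two usable amino acids", {
  w <- empty_room_world(seed = 1, P_PBB = 1, P_AADE = 0, P_AAD = 0,
                        P_AAF = 0, P_MV = 0)
  drtsim:::cpp_room_add_peptide(w$ptr, 0L, 0L, FALSE, "PQ")
  world_run_phase(w, "polymer")
  cen <- take_census(w)
  expect_identical(cen$peptides_free, 0)
  expect_identical(cen$aa, 2)
  expect_identical(cen$aap, 0)
})

test_that("chain-end residue decay yields one amino acid and one precursor", {
  reps <- 200
  aa_tot <- aap_tot <- 0
  for (s in seq_len(reps)) {
    w <- empty_room_world(seed = s, P_PBB = 0, P_AADE = 0.5, P_AAD = 0,
                          P_AAF = 0, P_MV = 0)
    drtsim:::cpp_room_add_peptide(w$ptr, 0L, 0L, FALSE, "PQ")
    world_run_phase(w, "polymer")
    cen <- take_census(w)
    aa_tot <- aa_tot + cen$aa
    aap_tot <- aap_tot + cen$aap
    expect_true(all(audit_conservation(w)$ok))
  }
  # each end decays with 0.5: single decay gives 1 aa + 1 precursor,
  # double decay gives 2 precursors; E[aap] = 2 * 0.5 * reps
  expect_lt(abs(aap_tot - reps), 4 * sqrt(reps * 0.5))
  expect_gt(aa_tot, 0)
})

test_that("time to first MSP matches the absorbing Markov chain oracle", {
  # states: 0/1/2 bound single residues, D = bound dipeptide; absorption =
  # release of the dipeptide.  Engine semantics: one DRT event per
  # template per step, tried in the order bind -> ligate -> release.
  q <- 0.9   # P_AABR
  a <- 0.5   # P_AATL
  r <- 0.2   # P_PLR
  Q <- matrix(0, 4, 4, dimnames = list(c("0", "1", "2", "D"),
                                       c("0", "1", "2", "D")))
  Q["0", "2"] <- q^2
  Q["0", "1"] <- 2 * q * (1 - q)
  Q["0", "0"] <- (1 - q)^2
  Q["1", "2"] <- q
  Q["1", "0"] <- (1 - q) * r
  Q["1", "1"] <- (1 - q) * (1 - r)
  Q["2", "D"] <- a
  Q["2", "0"] <- (1 - a) * r^2
  Q["2", "1"] <- (1 - a) * 2 * r * (1 - r)
  Q["2", "2"] <- (1 - a) * (1 - r)^2
  Q["D", "D"] <- 1 - r
  Nmat <- solve(diag(4) - Q)
  expected_mean <- sum(Nmat["0", ])

  reps <- 120
  times <- numeric(reps)
  pars <- sim_params(P_AAD = 0, P_AAF = 0, P_PBB = 0, P_AADE = 0,
                     P_PJM = 0, P_BB = 0, P_NDE = 0, P_RL = 0)
  for (s in seq_len(reps)) {
    w <- tiny_world("drt_ready", aa_each = 100, seed = s, params = pars)
    k <- 0
    repeat {
      world_step(w, 1)
      k <- k + 1
      if (take_census(w)$peptides_free >= 1) break
      if (k > 500) break
    }
    times[s] <- k
  }
  se <- sd(times) / sqrt(reps)
  expect_lt(abs(mean(times) - expected_mean), 4 * se)
})

test_that("bound-dipeptide dwell time is geometric with mean 1/P_PLR", {
  reps <- 150
  pars <- sim_params(P_AABR = 1, P_AATL = 1, P_PLR = 0.2, P_AAD = 0,
                     P_AAF = 0, P_PBB = 0, P_AADE = 0, P_PJM = 0)
  times <- numeric(reps)
  for (s in seq_len(reps)) {
    w <- tiny_world("drt_ready", aa_each = 10, seed = s, params = pars)
    world_step(w, 2)  # bind, then ligate: dipeptide attached
    k <- 0
    repeat {
      world_step(w, 1)
      k <- k + 1
      if (take_census(w)$peptides_free >= 1) break
      if (k > 300) break
    }
    times[s] <- k
  }
  se <- sd(times) / sqrt(reps)
  expect_lt(abs(mean(times) - 1 / 0.2), 4 * se)
})
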