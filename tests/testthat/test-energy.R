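# two 3-residue chains whose middle residues form one lateral hydrogen bond
two_strand_pair <- function(d2 = c(0, 0, 1), states = TRUE) {
  st <- if (states) c("coil", "strand", "coil") else "coil"
  lattice_system(list(
    lattice_chain("AAA", rbind(c(5, 5, 5), c(6, 5, 5), c(7, 5, 5)),
                  rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 1)), st),
    lattice_chain("AAA", rbind(c(5, 6, 5), c(6, 6, 5), c(7, 6, 5)),
                  rbind(c(0, 0, 1), d2, c(0, 0, 1)), st)),
    box = 20, check = FALSE)
}
zero_matrix <- function() {
  matrix(0, 21, 21, dimnames = list(amino_acids(), amino_acids()))
}

test_that("hydrogen-bond indicator needs contact, strand states and aligned side chains", {
  sys <- two_strand_pair(d2 = c(0, 0, -1))
  expect_equal(hb_indicator(sys, c(1, 2), c(2, 2)), 1L)
  expect_equal(hb_indicator(sys, c(2, 2), c(1, 2)), 1L)  # symmetric
  # one residue coil
  syc <- sys
  syc$chains[[2]]$state[2] <- "coil"
  expect_equal(hb_indicator(syc, c(1, 2), c(2, 2)), 0L)
  # antiparallel side chains
  sya <- two_strand_pair(d2 = c(0, 0, 1))
  expect_equal(hb_indicator(sya, c(1, 2), c(2, 2)), 0L)
  # strict perpendicular geometry: side chains along the contact vector
  syp <- sys
  syp$chains[[1]]$side[2, ] <- c(0, 1, 0)
  syp$chains[[2]]$side[2, ] <- c(0, 1, 0)
  expect_equal(hb_indicator(syp, c(1, 2), c(2, 2)), 0L)
  expect_equal(hb_indicator(syp, c(1, 2), c(2, 2),
                            energy_params(hb_strict_perpendicular = FALSE)),
               1L)
})

test_that("direction gate: facing or lateral-parallel side chains interact", {
  sys <- two_strand_pair()
  # facing along the contact vector (+y / -y)
  sys$chains[[1]]$side[2, ] <- c(0, 1, 0)
  sys$chains[[2]]$side[2, ] <- c(0, -1, 0)
  expect_equal(direction_interaction(sys, c(1, 2), c(2, 2)), 1L)
  # lateral parallel
  sys$chains[[1]]$side[2, ] <- c(0, 0, -1)
  sys$chains[[2]]$side[2, ] <- c(0, 0, -1)
  expect_equal(direction_interaction(sys, c(1, 2), c(2, 2)), 1L)
  # pointing away from each other
  sys$chains[[1]]$side[2, ] <- c(0, -1, 0)
  sys$chains[[2]]$side[2, ] <- c(0, 1, 0)
  expect_equal(direction_interaction(sys, c(1, 2), c(2, 2)), 0L)
})

test_that("steric and solvent indicators match their definitions", {
  ch <- lattice_chain("AAA", rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2)),
                      rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, -1)))
  sys <- lattice_system(ch, box = 10)
  expect_equal(steric_indicator(sys, 1, 1), 1L)
  expect_equal(steric_indicator(sys, 1, 2), 0L)
  expect_error(steric_indicator(sys, 1, 3), "1 <= i")
  expect_equal(solvent_indicator(sys, c(1, 1)), 1L)

  # side chain pointing at a residue of another chain is not solvated
  two <- lattice_system(list(
    lattice_chain("AA", rbind(c(2, 2, 2), c(3, 2, 2)),
                  rbind(c(0, 1, 0), c(0, 0, 1))),
    lattice_chain("AA", rbind(c(2, 3, 2), c(3, 3, 2)))), box = 10)
  expect_equal(solvent_indicator(two, c(1, 1)), 0L)

  # buried residues of the compact cuboid: side chains point into the block
  cub <- compact_cuboid_structure(3, 3, 4, strand_runs = FALSE)
  buried <- sum(vapply(seq_len(36), function(i)
    solvent_indicator(cub, c(1, i)) == 0L, logical(1)))
  expect_gt(buried, 0)
})

test_that("unit hydrogen-bond and steric energies match the defaults", {
  sys <- two_strand_pair(d2 = c(0, 0, -1))
  e <- total_energy(sys, zero_matrix())
  expect_identical(e$e_hb, -50)
  expect_identical(e$total, -50)
  expect_identical(as.integer(e$n_hb), 1L)

  st <- lattice_system(
    lattice_chain("AAA", rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2)),
                  rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, -1))), box = 10)
  es <- total_energy(st, zero_matrix())
  expect_identical(es$e_steric, 55)
  expect_identical(es$total, 55)
})

test_that("a 2-residue chain has no internal contacts", {
  sys <- lattice_system(
    lattice_chain("AA", rbind(c(2, 2, 2), c(3, 2, 2)),
                  rbind(c(0, 0, 1), c(0, 0, -1))), box = 10)
  e <- total_energy(sys, zero_matrix())
  expect_identical(e$total, 0)
})

test_that("unknown amino-acid codes are rejected with position information", {
  expect_error(lattice_chain("AXB", rbind(c(1, 1, 1), c(2, 1, 1),
                                          c(3, 1, 1))),
               "unknown amino-acid code 'X' at position 2")
})

test_that("total energy equals the brute-force oracle on random systems", {
  set.seed(99)
  params_list <- list(energy_params(),
                      energy_params(eps_state = 7,
                                    hb_strict_perpendicular = FALSE))
  for (rep in 1:40) {
    sys <- random_system()
    M <- random_matrix()
    for (params in params_list) {
      got <- total_energy(sys, M, params)
      want <- oracle_energy(sys, M, params)
      expect_identical(got$total, want$total)
      expect_identical(got$e_hb, want$e_hb)
      expect_identical(got$e_aa, want$e_aa)
      expect_identical(got$e_solvent, want$e_solvent)
      expect_identical(got$e_steric, want$e_steric)
      expect_identical(got$e_state, want$e_state)
    }
  }
})

test_that("energy is invariant under translation, rotation and relabelling", {
  set.seed(7)
  M <- default_interaction_matrix()
  for (rep in 1:5) {
    sys <- random_system(n_chains = 2, max_len = 8, box = 12)
    e0 <- total_energy(sys, M)$total
    # global translation (both chains, wrapped)
    tr <- sys
    for (c in 1:2) tr$chains[[c]]$pos <- (tr$chains[[c]]$pos + 5L) %% 12L
    expect_identical(total_energy(tr, M)$total, e0)
    # chain relabelling
    sw <- sys
    sw$chains <- rev(sw$chains)
    expect_identical(total_energy(sw, M)$total, e0)
    # global lattice rotation about z through the origin (x,y,z)->(-y,x,z)
    rot <- sys
    for (c in 1:2) {
      p <- rot$chains[[c]]$pos
      rot$chains[[c]]$pos <- cbind((-p[, 2]) %% 12L, p[, 1], p[, 3])
      s <- rot$chains[[c]]$side
      rot$chains[[c]]$side <- cbind(-s[, 2], s[, 1], s[, 3])
    }
    expect_identical(total_energy(rot, M)$total, e0)
  }
})

test_that("state energies only matter where residues are strand", {
  # with eps_state = 0 the energy ignores states of residues that form no
  # hydrogen bonds
  set.seed(31)
  M <- random_matrix()
  sys <- lattice_system(
    lattice_chain("AFCKLY", cbind(2L + 0:5, 4L, 4L)), box = 12)
  e_coil <- total_energy(sys, M)$total
  for (i in 2:5) {
    cand <- sys
    cand$chains[[1]]$state[i] <- "strand"
    expect_equal(nrow(validate_system(cand)), 0L)
    expect_identical(as.integer(total_energy(cand, M)$n_hb), 0L)
    expect_identical(total_energy(cand, M)$total, e_coil)
  }
})

test_that("interaction matrix files round-trip and are validated", {
  M <- default_interaction_matrix()
  f <- tempfile(fileext = ".mat")
  write_interaction_matrix(M, f)
  back <- read_interaction_matrix(f)
  expect_equal(back, M)
  unlink(f)
  bad <- M
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(write_interaction_matrix(bad, f), "symmetric")
  bad2 <- M
  bad2[21, 21] <- 1
  expect_error(write_interaction_matrix(bad2, f), "solvent-solvent")
})
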