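test_that("lattice neighbours wrap and enumerate correctly", {
  nb <- lattice_neighbors(c(0, 0, 0), box = 10, periodic = TRUE)
  expect_equal(nrow(nb), 6L)
  expect_equal(nrow(unique(nb)), 6L)
  expect_true(any(apply(nb, 1, function(p) all(p == c(9, 0, 0)))))
  expect_true(any(apply(nb, 1, function(p) all(p == c(1, 0, 0)))))

  nb2 <- lattice_neighbors(c(5, 5, 5), box = 10, periodic = FALSE)
  want <- rbind(c(4, 5, 5), c(6, 5, 5), c(5, 4, 5),
                c(5, 6, 5), c(5, 5, 4), c(5, 5, 6))
  expect_equal(nrow(nb2), 6L)
  for (k in 1:6)
    expect_true(any(apply(nb2, 1, function(p) all(p == want[k, ]))))

  # boundary site of a walled box loses the off-wall neighbour
  expect_equal(nrow(lattice_neighbors(c(0, 5, 5), box = 10,
                                      periodic = FALSE)), 5L)
  expect_error(lattice_neighbors(c(10, 0, 0), box = 10), "outside")
})

test_that("contact rule excludes sequential neighbours and self", {
  ch <- lattice_chain("AAAA", rbind(c(2, 2, 2), c(3, 2, 2),
                                    c(3, 3, 2), c(2, 3, 2)))
  sys <- lattice_system(ch, box = 10)
  # U-turn: residues 1 and 4 are adjacent but not sequential
  expect_equal(in_contact(sys, c(1, 1), c(1, 4)), 1L)
  expect_equal(in_contact(sys, c(1, 4), c(1, 1)), 1L)  # symmetric
  expect_equal(in_contact(sys, c(1, 1), c(1, 2)), 0L)  # sequential
  expect_equal(in_contact(sys, c(1, 1), c(1, 3)), 0L)  # diagonal
  expect_error(in_contact(sys, c(1, 2), c(1, 2)), "same residue")

  two <- lattice_system(list(
    lattice_chain("AA", rbind(c(2, 2, 2), c(3, 2, 2))),
    lattice_chain("AA", rbind(c(2, 3, 2), c(3, 3, 2)))), box = 10)
  expect_equal(in_contact(two, c(1, 1), c(2, 1)), 1L)

  # invariant under rigid translation and periodic wrapping
  shifted <- sys
  shifted$chains[[1]]$pos <- (sys$chains[[1]]$pos + 7L) %% 10L
  expect_equal(in_contact(shifted, c(1, 1), c(1, 4)), 1L)
  expect_equal(in_contact(shifted, c(1, 1), c(1, 3)), 0L)
})

test_that("collinearity is two-sided and terminals are never collinear", {
  straight <- lattice_system(
    lattice_chain("AAA", rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))),
    box = 10)
  corner <- lattice_system(
    lattice_chain("AAA", rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2))),
    box = 10)
  expect_true(is_collinear_at(straight, 1, 2))
  expect_false(is_collinear_at(corner, 1, 2))
  expect_false(is_collinear_at(straight, 1, 1))
  expect_false(is_collinear_at(straight, 1, 3))
})

test_that("validate_system reports overlaps and side-chain violations", {
  clean <- lattice_system(
    lattice_chain("AAAA", rbind(c(2, 2, 2), c(3, 2, 2),
                                c(4, 2, 2), c(5, 2, 2))), box = 10)
  expect_equal(nrow(validate_system(clean)), 0L)

  overlap <- lattice_system(list(
    lattice_chain("AA", rbind(c(2, 2, 2), c(3, 2, 2))),
    lattice_chain("AA", rbind(c(3, 2, 2), c(4, 2, 2)))),
    box = 10, check = FALSE)
  v <- validate_system(overlap)
  expect_true(any(v$rule == "site occupied twice"))

  badside <- lattice_system(
    lattice_chain("AA", rbind(c(2, 2, 2), c(3, 2, 2)),
                  side_chains = rbind(c(1, 0, 0), c(0, 0, 1))),
    box = 10, check = FALSE)
  v2 <- validate_system(badside)
  expect_true(any(v2$rule == "side chain along backbone bond"))

  badstrand <- lattice_system(
    lattice_chain("AAA", rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2)),
                  states = c("coil", "strand", "coil")),
    box = 10, check = FALSE)
  expect_true(any(validate_system(badstrand)$rule ==
                  "strand residue at backbone turn"))
})

test_that("admissible side-chain directions: 4 internal, 5 terminal", {
  # exhaustively try all 6 unit vectors at every residue of random chains
  set.seed(21)
  for (rep in 1:5) {
    sys <- random_system(n_chains = 1, max_len = 9, strand_prob = 0)
    ch <- sys$chains[[1]]
    n <- nrow(ch$pos)
    for (i in seq_len(n)) {
      n_ok <- 0L
      for (k in 1:6) {
        cand <- sys
        cand$chains[[1]]$side[i, ] <- ODIRS[k, ]
        viol <- validate_system(cand)
        if (!any(viol$rule == "side chain along backbone bond" &
                 viol$residue == i)) n_ok <- n_ok + 1L
      }
      expect_equal(n_ok, if (i == 1L || i == n) 5L else 4L)
    }
  }
})

test_that("conformation text format round-trips exactly", {
  set.seed(5)
  sys <- random_system(n_chains = 3, max_len = 8)
  f <- tempfile(fileext = ".conf")
  write_conformation(sys, f)
  back <- read_conformation(f)
  expect_identical(back$box, sys$box)
  expect_identical(back$periodic, sys$periodic)
  for (c in seq_along(sys$chains)) {
    expect_identical(back$chains[[c]]$aa, sys$chains[[c]]$aa)
    expect_equal(unname(back$chains[[c]]$pos), unname(sys$chains[[c]]$pos))
    expect_equal(unname(back$chains[[c]]$side), unname(sys$chains[[c]]$side))
    expect_identical(back$chains[[c]]$state, sys$chains[[c]]$state)
  }
  unlink(f)
})

test_that("PDB export writes CA and CB pseudo-atoms per residue", {
  sys <- seed_fibril(2, "TTTTTTT", box = 20)
  f <- tempfile(fileext = ".pdb")
  export_pdb(sys, f)
  lines <- readLines(f)
  atoms <- grep("^ATOM", lines, value = TRUE)
  expect_equal(length(atoms), 2L * 14L)
  expect_equal(sum(lines == "TER"), 2L)
  # CA coordinates are lattice position x 3.8
  x1 <- as.numeric(substr(atoms[1], 31, 38))
  expect_equal(x1, sys$chains[[1]]$pos[1, 1] * 3.8)
  unlink(f)
})

test_that("run configuration files populate matrix, params and schedule", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("box: 20", "temperature: 12", "n_iterations: 500",
               "sample_interval: 50", "seed: 9", "eps_hb: -40",
               "matrix: default"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$params$eps_hb, -40)
  expect_equal(cfg$params$eps_steric, 55)
  expect_equal(cfg$schedule$n_iterations, 500)
  expect_equal(cfg$schedule$seed, 9)
  expect_equal(dim(cfg$matrix), c(21L, 21L))
  unlink(f)
})

test_that("trajectories serialise to delimited text", {
  sys <- seed_fibril(2, "TTTTTTT", box = 16)
  tr <- run_canonical(sys, default_interaction_matrix(), energy_params(),
                      mc_schedule(1000, sample_interval = 100, seed = 1),
                      temperature = 10)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(tr$trajectory))
  expect_equal(back$e_total, tr$trajectory$e_total)
  unlink(f)
})
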