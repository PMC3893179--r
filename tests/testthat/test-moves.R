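zero_m <- function() {
  matrix(0, 21, 21, dimnames = list(amino_acids(), amino_acids()))
}

corner_chain <- function() {
  lattice_system(
    lattice_chain("AAAA", rbind(c(4, 4, 4), c(5, 4, 4),
                                c(5, 5, 4), c(5, 6, 4))), box = 12)
}

test_that("corner flip / point rotation re-places a corner residue", {
  sys <- corner_chain()
  p <- propose_move(sys, "corner_flip", c(1, 2), seed = 3)
  expect_true(p$valid)
  expect_equal(unlist(p$payload[1, c("x", "y", "z")]),
               c(x = 4, y = 5, z = 4))
  expect_equal(nrow(validate_system(p$new_system)), 0L)
  # a straight interior residue has no alternative placement
  straight <- lattice_system(
    lattice_chain("AAA", rbind(c(4, 4, 4), c(5, 4, 4), c(6, 4, 4))),
    box = 12)
  q <- propose_move(straight, "point_rotation", c(1, 2))
  expect_false(q$valid)
})

test_that("backbone moves targeting strand residues are rejected as frozen", {
  sf <- seed_fibril(2, "TTTTTTT", box = 20)
  for (kind in c("corner_flip", "crankshaft")) {
    p <- propose_move(sf, kind, c(1, 4))
    expect_false(p$valid)
    expect_match(p$reason, "strand frozen")
  }
  # end moves are blocked too: the inner neighbour (residue 2) is strand
  p <- propose_move(sf, "end_move", c(1, 1))
  expect_false(p$valid)
  expect_match(p$reason, "strand frozen")
  # side chains of strand residues may not rotate
  p <- propose_move(sf, "side_chain_rotate", c(1, 4))
  expect_false(p$valid)
  expect_match(p$reason, "strand frozen")
})

test_that("crankshaft applies only to U-shaped interior segments", {
  # enumerate 4-residue motifs: the U (bonds x, y, -x) supports a crank,
  # straight and L-shaped ones do not
  u <- lattice_system(
    lattice_chain("AAAA", rbind(c(4, 4, 4), c(5, 4, 4),
                                c(5, 5, 4), c(4, 5, 4))), box = 12)
  p <- propose_move(u, "crankshaft", c(1, 2), seed = 1,
                    args = list(angle = 2))
  expect_true(p$valid)
  expect_equal(nrow(p$payload), 2L)
  expect_equal(nrow(validate_system(p$new_system)), 0L)

  straight <- lattice_system(
    lattice_chain("AAAA", rbind(c(4, 4, 4), c(5, 4, 4),
                                c(6, 4, 4), c(7, 4, 4))), box = 12)
  expect_false(propose_move(straight, "crankshaft", c(1, 2))$valid)
  expect_false(propose_move(corner_chain(), "crankshaft", c(1, 2))$valid)
})

test_that("state flips follow the strand/coil rules", {
  straight <- lattice_system(
    lattice_chain("AAA", rbind(c(4, 4, 4), c(5, 4, 4), c(6, 4, 4))),
    box = 12)
  p <- propose_move(straight, "state_flip", c(1, 2))
  expect_true(p$valid)
  expect_equal(p$new_system$chains[[1]]$state[2], "strand")
  # corner residue cannot become strand
  q <- propose_move(corner_chain(), "state_flip", c(1, 2))
  expect_false(q$valid)
  expect_match(q$reason, "turn in backbone")
  # terminal residue cannot become strand (defined non-collinear)
  expect_false(propose_move(straight, "state_flip", c(1, 1))$valid)
  # strand neighbour with non-opposite side chain blocks the flip
  sf <- seed_fibril(2, "TTTTT", box = 20)
  sys <- sf
  sys$chains[[1]]$state[3] <- "coil"
  sys$chains[[1]]$side[3, ] <- c(0, 1, 0)  # neighbours hold +/-z
  r <- propose_move(sys, "state_flip", c(1, 3))
  expect_false(r$valid)
  expect_match(r$reason, "not opposite")
  # with the alternating side chain restored the flip is allowed
  sys$chains[[1]]$side[3, ] <- sf$chains[[1]]$side[3, ]
  expect_true(propose_move(sys, "state_flip", c(1, 3))$valid)
  # strand -> coil is always proposable
  expect_true(propose_move(sf, "state_flip", c(1, 3))$valid)
})

test_that("side-chain rotations draw from the admissible directions", {
  straight <- lattice_system(
    lattice_chain("AAA", rbind(c(4, 4, 4), c(5, 4, 4), c(6, 4, 4))),
    box = 12)
  # internal residue: backbone runs along x, so +/-x are forbidden
  for (d in 0:1) {
    p <- propose_move(straight, "side_chain_rotate", c(1, 2),
                      args = list(direction = d))
    expect_false(p$valid)
  }
  seen <- unique(vapply(1:40, function(s) {
    p <- propose_move(straight, "side_chain_rotate", c(1, 2), seed = s)
    paste(p$new_system$chains[[1]]$side[2, ], collapse = ",")
  }, character(1)))
  expect_equal(length(seen), 3L)  # 4 admissible minus the current one
  # terminal residue: 5 admissible, 4 proposable new ones
  seen1 <- unique(vapply(1:60, function(s) {
    p <- propose_move(straight, "side_chain_rotate", c(1, 1), seed = s)
    paste(p$new_system$chains[[1]]$side[1, ], collapse = ",")
  }, character(1)))
  expect_equal(length(seen1), 4L)
})

test_that("rigid moves preserve internal geometry and energies", {
  set.seed(11)
  M <- default_interaction_matrix()
  sys <- random_system(n_chains = 1, max_len = 10, box = 14)
  e0 <- total_energy(sys, M)$total
  for (s in 1:10) {
    p <- propose_move(sys, "translate", 1, matrix = M, seed = s)
    expect_true(p$valid)
    expect_identical(p$delta_e, 0)
    q <- propose_move(sys, "rotate", 1, matrix = M, seed = s)
    if (q$valid) {
      expect_identical(q$delta_e, 0)
      expect_identical(total_energy(q$new_system, M)$total, e0)
      expect_equal(nrow(validate_system(q$new_system)), 0L)
    }
  }
  # rotation onto another chain's sites is invalid
  two <- lattice_system(list(
    lattice_chain("AAA", rbind(c(4, 4, 4), c(5, 4, 4), c(6, 4, 4))),
    lattice_chain("AAA", rbind(c(6, 5, 4), c(5, 5, 4), c(4, 5, 4)))),
    box = 12)
  p <- propose_move(two, "rotate", 1,
                    args = list(pivot = 0, axis = 2, angle = 1))
  expect_false(p$valid)
})

test_that("moves are reversible bit-exactly", {
  set.seed(17)
  sys <- random_system(n_chains = 2, max_len = 7, box = 10)
  # translate then translate back
  p <- propose_move(sys, "translate", 1, args = list(direction = 2))
  if (p$valid) {
    back <- propose_move(p$new_system, "translate", 1,
                         args = list(direction = 3))
    expect_identical(back$new_system$chains, sys$chains)
  }
  # rotate by k then by 4 - k about the same pivot/axis
  q <- propose_move(sys, "rotate", 1, args = list(pivot = 1, axis = 0,
                                                  angle = 1))
  if (q$valid) {
    back <- propose_move(q$new_system, "rotate", 1,
                         args = list(pivot = 1, axis = 0, angle = 3))
    expect_identical(back$new_system$chains, sys$chains)
  }
  # state flip twice restores the state
  straight <- lattice_system(
    lattice_chain("AAA", rbind(c(4, 4, 4), c(5, 4, 4), c(6, 4, 4))),
    box = 12)
  p1 <- propose_move(straight, "state_flip", c(1, 2))
  p2 <- propose_move(p1$new_system, "state_flip", c(1, 2))
  expect_identical(p2$new_system$chains, straight$chains)
})

test_that("accepted proposals never invalidate a system and deltas are exact", {
  set.seed(41)
  kinds <- c("state_flip", "side_chain_rotate", "end_move", "corner_flip",
             "crankshaft", "translate", "rotate")
  n_checked <- 0
  for (rep in 1:30) {
    sys <- random_system(box = 9)
    M <- random_matrix()
    e0 <- total_energy(sys, M)$total
    kind <- sample(kinds, 1)
    rigid <- kind %in% c("translate", "rotate")
    ch <- sample(length(sys$chains), 1)
    target <- if (rigid) ch else {
      n <- nrow(sys$chains[[ch]]$pos)
      i <- if (kind == "end_move") sample(c(1, n), 1) else sample(n, 1)
      c(ch, i)
    }
    p <- propose_move(sys, kind, target, matrix = M, seed = rep)
    if (!p$valid) next
    n_checked <- n_checked + 1
    expect_equal(nrow(validate_system(p$new_system)), 0L)
    expect_identical(p$delta_e, total_energy(p$new_system, M)$total - e0)
  }
  expect_gt(n_checked, 10)
})

test_that("proposals replay identically for a fixed seed", {
  set.seed(4)
  sys <- random_system(n_chains = 1, max_len = 10)
  a <- propose_move(sys, "side_chain_rotate", c(1, 2), seed = 123)
  b <- propose_move(sys, "side_chain_rotate", c(1, 2), seed = 123)
  expect_identical(a$payload, b$payload)
})
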