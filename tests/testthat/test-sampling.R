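zero_mx <- function() {
  matrix(0, 21, 21, dimnames = list(amino_acids(), amino_acids()))
}

test_that("Metropolis rule: downhill always, uphill at the Boltzmann rate", {
  expect_true(metropolis_accept(-3, 1))
  expect_true(metropolis_accept(0, 1))
  expect_false(metropolis_accept(Inf, 1))
  expect_error(metropolis_accept(1, 0), "positive")
  expect_error(metropolis_accept(1, -2), "positive")
  # delta_e = T ln 2 -> acceptance frequency 1/2
  set.seed(8)
  TT <- 1.7
  n <- 1e5
  acc <- sum(vapply(seq_len(n), function(i)
    metropolis_accept(TT * log(2), TT), logical(1)))
  expect_lt(abs(acc / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("trajectories replay bit-identically for a fixed seed", {
  sys <- seed_fibril(3, "TFTFTFT", box = 16)
  M <- default_interaction_matrix()
  sch <- mc_schedule(2e4, sample_interval = 500, seed = 77)
  a <- run_canonical(sys, M, energy_params(), sch, temperature = 12)
  b <- run_canonical(sys, M, energy_params(), sch, temperature = 12)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_system, b$final_system)
  c <- run_canonical(sys, M, energy_params(),
                     mc_schedule(2e4, sample_interval = 500, seed = 78),
                     temperature = 12)
  expect_false(identical(a$trajectory$e_total, c$trajectory$e_total))
})

test_that("running energy equals full recompute at every sample", {
  set.seed(13)
  sys <- random_system(n_chains = 2, max_len = 9, box = 10)
  M <- random_matrix()
  tr <- run_canonical(sys, M, energy_params(),
                      mc_schedule(3e4, sample_interval = 100, seed = 5),
                      temperature = 30)
  expect_identical(tr$trajectory$e_total, tr$trajectory$e_check)
  expect_identical(tr$final_energy$total, tr$final_energy_recomputed$total)
  expect_equal(nrow(validate_system(tr$final_system)), 0L)
})

test_that("the zero-temperature limit settles into low energy", {
  # a two-chain toy whose ground state is the bound dimer
  sys <- lattice_system(list(
    lattice_chain("II", rbind(c(2, 2, 2), c(3, 2, 2))),
    lattice_chain("II", rbind(c(6, 6, 6), c(7, 6, 6)))), box = 9)
  M <- default_interaction_matrix()
  tr <- run_canonical(sys, M, energy_params(),
                      mc_schedule(2e5, sample_interval = 5000, seed = 2),
                      temperature = 2)
  e_end <- mean(tail(tr$trajectory$e_total, 10))
  expect_lt(e_end, -50)  # bound dimer (an I-I contact is -90)
})

test_that("replica swaps at equal temperature or energy always succeed", {
  sys <- seed_fibril(2, "TTTTTTT", box = 16)
  M <- default_interaction_matrix()
  sch <- mc_schedule(4e3, sample_interval = 1000, seed = 3)
  # equal temperatures encoded as an epsilon-separated pair
  lad <- replica_ladder(c(10, 10 + 1e-9), swap_interval = 200)
  pt <- run_parallel_tempering(sys, M, energy_params(), lad, sch)
  expect_equal(pt$swap_accepted, pt$swap_attempted)
  expect_gt(pt$swap_attempted, 0)
})

test_that("parallel tempering reproduces single-temperature statistics", {
  # two-level toy: per-temperature energy means from a PT run agree with
  # independent canonical runs at the same temperatures
  sys <- lattice_system(
    lattice_chain("AAA", rbind(c(0, 1, 1), c(1, 1, 1), c(2, 1, 1))),
    box = 3, periodic = TRUE)
  M <- default_interaction_matrix()
  temps <- c(20, 45)
  sch <- mc_schedule(3e5, sample_interval = 25, seed = 19)
  pt <- run_parallel_tempering(sys, M, energy_params(),
                               replica_ladder(temps, swap_interval = 250),
                               sch)
  for (r in 1:2) {
    can <- sapply(1:6, function(s)
      mean(run_canonical(sys, M, energy_params(),
                         mc_schedule(1e5, sample_interval = 25,
                                     seed = 100 * r + s),
                         temperature = temps[r]
           )$trajectory$e_total[-(1:400)]))
    dfp <- pt$trajectories[[r]]
    mpt <- mean(dfp$e_total[dfp$iteration > 3e4])
    se <- sd(can) / sqrt(length(can))
    expect_lt(abs(mpt - mean(can)), 5 * se + 1)
  }
})

test_that("grand-canonical runs respect the activity limits", {
  M <- default_interaction_matrix()
  # activity -> 0: the strand-bound seed persists, free peptides vanish
  sf <- seed_fibril(4, "TFTFTFT", box = 16)
  gc0 <- grand_canonical_params(1e-300, "TFTFTFT",
                                insertion_attempt_rate = 0.3)
  tr <- run_grand_canonical(sf, M, energy_params(), gc0,
                            mc_schedule(3e4, sample_interval = 1000,
                                        seed = 6), temperature = 6)
  expect_equal(tail(tr$trajectory$n_peptides, 1), 4)
  expect_identical(tr$trajectory$e_total, tr$trajectory$e_check)
  expect_equal(nrow(validate_system(tr$final_system)), 0L)
})

test_that("trajectory summaries discard burn-in and average the rest", {
  df <- data.frame(iteration = 1:10, e_total = c(rep(100, 5), rep(0, 5)),
                   e_check = 0, n_hb = 1, n_contacts = 2, n_external = 0,
                   n_native = NA, n_peptides = 1)
  s <- trajectory_summary(df, temperature = 2, burn_in = 0.5)
  expect_equal(s$mean_energy, 0)
  expect_equal(s$n_samples, 5)
  expect_equal(s$heat_capacity, 0)
})
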