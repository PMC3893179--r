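#' Heat capacity from energy fluctuations
#'
#' \eqn{C_v = (\langle E^2 \rangle - \langle E \rangle^2) / (k_B T^2)},
#' using the population variance of the supplied samples.
#'
#' @param energy_samples Numeric vector of total-energy samples (at least 2).
#' @param temperature Temperature the samples were taken at (> 0).
#' @param k_B Boltzmann constant convention.
#' @return Numeric heat capacity.
#' @export
heat_capacity <- function(energy_samples, temperature, k_B = 1) {
  stopifnot(length(energy_samples) >= 2L, temperature > 0)
  (mean(energy_samples^2) - mean(energy_samples)^2) / (k_B * temperature^2)
}

#' Extract the contact set of a structure
#'
#' All unordered residue pairs currently in contact (lattice neighbours,
#' not sequential in the same chain); taking this from a design target
#' defines its native contacts.
#'
#' @param sys A \code{lattice_system}.
#' @return Integer matrix with columns \code{chain_i}, \code{res_i},
#'   \code{chain_j}, \code{res_j} (1-based), one row per contact.
#' @export
native_contacts <- function(sys) {
  occ <- .occ_build(sys)
  out <- matrix(0L, 0L, 4L)
  for (c in seq_along(sys$chains)) {
    ch <- sys$chains[[c]]
    for (i in seq_len(nrow(ch$pos))) {
      nb <- lattice_neighbors(ch$pos[i, ], sys$box, sys$periodic)
      for (k in seq_len(nrow(nb))) {
        key <- .site_key(sys, nb[k, ])
        c2 <- occ$chain[key]
        if (c2 == 0L) next
        i2 <- occ$res[key]
        if (c2 < c || (c2 == c && i2 <= i)) next     # each pair once
        if (c2 == c && abs(i2 - i) == 1L) next       # sequential
        out <- rbind(out, c(c, i, c2, i2))
      }
    }
  }
  colnames(out) <- c("chain_i", "res_i", "chain_j", "res_j")
  out
}

#' Count native contacts in a configuration
#'
#' @param sys A \code{lattice_system}.
#' @param reference Contact set of the native (design target) structure,
#'   from \code{\link{native_contacts}}.  Chain lengths must match.
#' @return Integer: number of reference contacts present in \code{sys}.
#' @export
native_contact_count <- function(sys, reference) {
  reference <- as.matrix(reference)
  for (k in seq_len(nrow(reference))) {
    for (col in c(1L, 3L)) {
      ch <- reference[k, col]
      if (ch > length(sys$chains) ||
          reference[k, col + 1L] > nrow(sys$chains[[ch]]$pos))
        stop("reference refers to residues the system does not have ",
             "(chain length mismatch)")
    }
  }
  n <- 0L
  for (k in seq_len(nrow(reference))) {
    i <- reference[k, 1:2]
    j <- reference[k, 3:4]
    n <- n + in_contact(sys, i, j)
  }
  n
}

#' Count hydrogen bonds of a configuration
#'
#' @param sys A \code{lattice_system}.
#' @param params \code{\link{energy_params}} (for the strict-perpendicular
#'   geometry switch).
#' @return Integer: \eqn{\sum_{i<j}} of the hydrogen-bond indicator.
#' @export
hydrogen_bond_count <- function(sys, params = energy_params()) {
  cn <- native_contacts(sys)  # all current contacts
  n <- 0L
  for (k in seq_len(nrow(cn))) {
    n <- n + hb_indicator(sys, cn[k, 1:2], cn[k, 3:4], params)
  }
  n
}

#' Count intermolecular (external) contacts
#'
#' Contacts between residues of different chains -- the order parameter for
#' aggregation and fibril stability.
#'
#' @param sys A \code{lattice_system} with at least two chains.
#' @return Integer count.
#' @export
intermolecular_contact_count <- function(sys) {
  if (length(sys$chains) < 2L)
    stop("intermolecular contacts need at least two chains")
  cn <- native_contacts(sys)
  sum(cn[, 1L] != cn[, 3L])
}

#' Per-trajectory ensemble averages
#'
#' Discards a burn-in fraction of the samples and averages the recorded
#' observables.
#'
#' @param trajectory A trajectory data frame from a run function.
#' @param temperature Temperature of the run (for the heat capacity).
#' @param burn_in Fraction of initial samples discarded (default 0.5).
#' @param k_B Boltzmann constant convention.
#' @return One-row data frame with means of the energy and counts plus the
#'   heat capacity.
#' @export
trajectory_summary <- function(trajectory, temperature, burn_in = 0.5,
                               k_B = 1) {
  stopifnot(burn_in >= 0, burn_in < 1)
  keep <- trajectory[-seq_len(floor(nrow(trajectory) * burn_in)), ,
                     drop = FALSE]
  if (nrow(keep) < 2L) keep <- trajectory
  data.frame(
    temperature = temperature,
    mean_energy = mean(keep$e_total),
    heat_capacity = heat_capacity(keep$e_total, temperature, k_B),
    mean_hb = mean(keep$n_hb),
    mean_contacts = mean(keep$n_contacts),
    mean_external = mean(keep$n_external),
    mean_native = mean(keep$n_native),
    mean_peptides = mean(keep$n_peptides),
    n_samples = nrow(keep))
}

#' Per-temperature summary of a parallel-tempering run
#'
#' Averages are taken per temperature slot (no cross-replica reweighting).
#'
#' @param pt A \code{pt_run} object.
#' @inheritParams trajectory_summary
#' @return Data frame with one row per temperature.
#' @export
pt_summary <- function(pt, burn_in = 0.5, k_B = 1) {
  do.call(rbind, lapply(seq_along(pt$temperatures), function(r) {
    trajectory_summary(pt$trajectories[[r]], pt$temperatures[r],
                       burn_in = burn_in, k_B = k_B)
  }))
}
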