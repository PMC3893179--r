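#' Monte Carlo run schedule
#'
#' One iteration performs a single local trial move (state flip, side-chain
#' rotation or internal backbone move, chosen uniformly) on a uniformly
#' chosen residue, plus, with probability \code{p_global}, one rigid-body
#' move (unit translation or quarter-turn rotation) of a uniformly chosen
#' chain.
#'
#' @param n_iterations Number of iterations.
#' @param p_global Probability of attempting a rigid-body move each
#'   iteration.
#' @param sample_interval Iterations between recorded samples.
#' @param seed Integer seed; the same schedule and seed replay a trajectory
#'   bit-identically.
#' @param swap_interval Iterations between replica swap attempts (parallel
#'   tempering only).
#' @return An object of class \code{mc_schedule}.
#' @export
mc_schedule <- function(n_iterations, p_global = 0.2, sample_interval = 100L,
                        seed = 1L, swap_interval = 1000L) {
  stopifnot(p_global >= 0, p_global <= 1, n_iterations >= 1,
            sample_interval >= 1, swap_interval >= 1)
  structure(list(n_iterations = as.double(n_iterations),
                 p_global = p_global,
                 sample_interval = as.double(sample_interval),
                 seed = as.double(seed),
                 swap_interval = as.double(swap_interval)),
            class = "mc_schedule")
}

#' Temperature ladder for parallel tempering
#'
#' @param temperatures Strictly increasing positive temperatures (reduced
#'   units).  The default is a geometric ladder of 12 temperatures spanning
#'   the folding/dissociation range of the bundled interaction matrix.
#' @param swap_interval Iterations between swap attempts.
#' @return An object of class \code{replica_ladder}.
#' @export
replica_ladder <- function(temperatures = default_temperatures(),
                           swap_interval = 1000L) {
  stopifnot(all(temperatures > 0), !is.unsorted(temperatures, strictly = TRUE))
  structure(list(temperatures = as.double(temperatures),
                 swap_interval = as.double(swap_interval)),
            class = "replica_ladder")
}

#' @rdname replica_ladder
#' @param n Number of replicas.
#' @param t_min,t_max Ladder end points.
#' @export
default_temperatures <- function(n = 12L, t_min = 4, t_max = 60) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Metropolis acceptance rule
#'
#' Accepts with probability \eqn{\min(1, \exp(-\Delta E / k_B T))}.
#'
#' @param delta_e Energy change of the trial move (\code{Inf} encodes an
#'   invalid proposal and is always rejected).
#' @param temperature Simulation temperature, reduced units; must be > 0.
#' @param k_B Boltzmann constant convention.
#' @return Logical: accept?
#' @export
metropolis_accept <- function(delta_e, temperature, k_B = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (delta_e <= 0) return(TRUE)
  runif(1L) < exp(-delta_e / (k_B * temperature))
}

.as_trajectory <- function(res, temperature, kind) {
  structure(list(trajectory = res$trajectory,
                 final_system = .sys_from_engine(res$final_system),
                 final_energy = as.list(res$final_energy),
                 final_energy_recomputed = as.list(res$final_energy_recomputed),
                 acceptance = res$acceptance,
                 temperature = temperature, kind = kind),
            class = "mc_trajectory")
}

.native_ref_engine <- function(native_ref) {
  if (is.null(native_ref)) return(NULL)
  ref <- as.matrix(native_ref)
  storage.mode(ref) <- "integer"
  ref - 1L  # 0-based for the engine
}

#' Canonical Metropolis simulation
#'
#' @param sys Starting \code{lattice_system}.
#' @param matrix 21 x 21 interaction matrix.
#' @param params \code{\link{energy_params}}.
#' @param schedule \code{\link{mc_schedule}}.
#' @param temperature Temperature (reduced units).
#' @param native_ref Optional native contact set from
#'   \code{\link{native_contacts}}; when supplied, the trajectory records
#'   the native-contact count of every sample.
#' @return An \code{mc_trajectory}: the sampled observables (energy
#'   components with a full-recompute check column, hydrogen bonds,
#'   contacts, native contacts, peptide count), the final system, final
#'   running and recomputed energies, and per-move acceptance counts.
#' @export
run_canonical <- function(sys, matrix = default_interaction_matrix(),
                          params = energy_params(), schedule, temperature,
                          native_ref = NULL) {
  .check_matrix(matrix)
  stopifnot(inherits(schedule, "mc_schedule"), temperature > 0)
  res <- cpp_run_canonical(.sys_to_engine(sys), matrix, params,
                           unclass(schedule), temperature,
                           .native_ref_engine(native_ref))
  .as_trajectory(res, temperature, "canonical")
}

#' Parallel tempering (temperature replica exchange)
#'
#' Replicas advance independently; every \code{swap_interval} iterations
#' adjacent temperature pairs attempt a configuration exchange accepted
#' with probability \eqn{\min(1, \exp[(1/T_1 - 1/T_2)(E_1 - E_2)/k_B])}.
#' Trajectories are recorded per temperature slot.
#'
#' @inheritParams run_canonical
#' @param ladder A \code{\link{replica_ladder}}.
#' @return An object of class \code{pt_run}: per-temperature trajectories
#'   and final systems plus swap statistics.
#' @export
run_parallel_tempering <- function(sys, matrix = default_interaction_matrix(),
                                   params = energy_params(), ladder,
                                   schedule, native_ref = NULL) {
  .check_matrix(matrix)
  stopifnot(inherits(ladder, "replica_ladder"),
            length(ladder$temperatures) >= 2L,
            inherits(schedule, "mc_schedule"))
  sch <- unclass(schedule)
  sch$swap_interval <- ladder$swap_interval
  res <- cpp_run_pt(.sys_to_engine(sys), matrix, params,
                    ladder$temperatures, sch, .native_ref_engine(native_ref))
  structure(list(trajectories = res$trajectories,
                 final_systems = lapply(res$final_systems, .sys_from_engine),
                 temperatures = res$temperatures,
                 swap_attempted = res$swap_attempted,
                 swap_accepted = res$swap_accepted),
            class = "pt_run")
}

#' Grand-canonical parameters
#'
#' @param activity Peptide activity \eqn{z > 0}; for non-interacting
#'   peptides the mean count approaches \eqn{z \Omega}, with \eqn{\Omega}
#'   the number of insertable rod conformations (box volume x 6 axes x
#'   admissible side-chain combinations).
#' @param peptide_sequence One-letter sequence of the exchangeable peptide
#'   species (the seed chains should be the same species).
#' @param insertion_attempt_rate Probability per iteration of attempting an
#'   insertion or deletion (half each).
#' @return An object of class \code{gc_params}.
#' @export
grand_canonical_params <- function(activity, peptide_sequence,
                                   insertion_attempt_rate = 0.1) {
  stopifnot(activity > 0, nchar(peptide_sequence) >= 2,
            insertion_attempt_rate > 0, insertion_attempt_rate <= 1)
  structure(list(activity = activity, peptide_sequence = peptide_sequence,
                 insertion_attempt_rate = insertion_attempt_rate),
            class = "gc_params")
}

#' Grand-canonical fibril-growth simulation
#'
#' Canonical sampling plus whole-peptide insertions and deletions at fixed
#' activity.  Insertions propose straight rods in the coil state with
#' uniformly drawn admissible side chains; deletions pick a peptide
#' uniformly and are automatically rejected unless it is currently a
#' straight all-coil rod (the only conformations the insertion move can
#' generate), which keeps the insert/delete pair in detailed balance --
#' exchange with the bath happens through the soluble monomer pool while
#' strand peptides bound to a fibril are not removable in one step.
#'
#' @inheritParams run_canonical
#' @param gc_params A \code{\link{grand_canonical_params}} object.
#' @return An \code{mc_trajectory} whose \code{n_peptides} column tracks
#'   the fluctuating peptide count.
#' @export
run_grand_canonical <- function(sys, matrix = default_interaction_matrix(),
                                params = energy_params(), gc_params,
                                schedule, temperature) {
  .check_matrix(matrix)
  stopifnot(inherits(gc_params, "gc_params"),
            inherits(schedule, "mc_schedule"), temperature > 0)
  aa <- as.integer(.aa_encode(gc_params$peptide_sequence))
  res <- cpp_run_gcmc(.sys_to_engine(sys), matrix, params, unclass(schedule),
                      temperature, gc_params$activity,
                      gc_params$insertion_attempt_rate, aa)
  .as_trajectory(res, temperature, "grand_canonical")
}

# methods -----------------------------------------------------------------

#' @export
print.mc_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("%s run at T = %g: %d samples (final E = %g, %d H-bonds)\n",
              x$kind, x$temperature, nrow(tr),
              x$final_energy$total, as.integer(x$final_energy$n_hb)))
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, burn_in = 0.5, ...) {
  trajectory_summary(object$trajectory, temperature = object$temperature,
                     burn_in = burn_in)
}

#' @export
plot.mc_trajectory <- function(x, ...) {
  tr <- x$trajectory
  oldpar <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(oldpar))
  plot(tr$iteration, tr$e_total, type = "l", xlab = "iteration",
       ylab = "total energy", ...)
  plot(tr$iteration, tr$n_hb, type = "l", xlab = "iteration",
       ylab = "H-bonds", col = "darkgreen", ...)
  invisible(x)
}

#' @export
print.pt_run <- function(x, ...) {
  cat(sprintf(
    "parallel tempering: %d replicas, T in [%g, %g], swap acceptance %.2f\n",
    length(x$temperatures), min(x$temperatures), max(x$temperatures),
    if (x$swap_attempted > 0) x$swap_accepted / x$swap_attempted else NA))
  invisible(x)
}

#' @export
summary.pt_run <- function(object, burn_in = 0.5, k_B = 1, ...) {
  pt_summary(object, burn_in = burn_in, k_B = k_B)
}

#' @export
plot.pt_run <- function(x, burn_in = 0.5, ...) {
  s <- pt_summary(x, burn_in = burn_in)
  oldpar <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(oldpar))
  plot(s$temperature, s$heat_capacity, type = "b", log = "x",
       xlab = "temperature", ylab = "heat capacity", main = "C_v(T)", ...)
  ylab2 <- if (all(is.na(s$mean_native))) "H-bonds" else "native contacts"
  y2 <- if (all(is.na(s$mean_native))) s$mean_hb else s$mean_native
  plot(s$temperature, y2, type = "b", log = "x",
       xlab = "temperature", ylab = ylab2, ...)
  invisible(x)
}
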