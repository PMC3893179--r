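#' Composition distance to a reference amino-acid distribution
#'
#' \eqn{D = \sum_a (f_a^{seq} - f_a^{ref})^2} over the 20 types, with
#' \eqn{f_a^{seq} = N_a / L}.  Keeping \eqn{D} small during design keeps the
#' designed sequence's composition close to that of natural proteins, and
#' hence its variability high.
#'
#' @param sequence One-letter sequence (string or character vector).
#' @param f_ref Reference fractions, named by amino acid, summing to 1
#'   (default \code{\link{natural_aa_frequencies}}).
#' @return Numeric distance \eqn{D \ge 0}.
#' @export
composition_distance <- function(sequence, f_ref = natural_aa_frequencies()) {
  if (length(sequence) == 0L || identical(sequence, ""))
    stop("sequence is empty")
  codes <- .aa_encode(sequence)
  f_ref <- f_ref[amino_acids()[1:20]]
  if (abs(sum(f_ref) - 1) > 1e-12) stop("f_ref must sum to 1")
  counts <- tabulate(codes + 1L, nbins = 20L)
  sum((counts / length(codes) - f_ref)^2)
}

#' O(1) update of the composition distance after one substitution
#'
#' Replacing one residue of type \code{type_from} by \code{type_to} changes
#' only two terms of the sum, so the new distance follows from the old one
#' without a full recomputation.
#'
#' @param D_old Distance before the substitution.
#' @param counts Named integer vector of per-type counts before the
#'   substitution (names from \code{\link{amino_acids}}).
#' @param type_from,type_to One-letter codes of the replaced and the new
#'   type.
#' @param length Sequence length.
#' @param f_ref Reference fractions (default natural composition).
#' @return The updated distance.
#' @export
incremental_distance <- function(D_old, counts, type_from, type_to, length,
                                 f_ref = natural_aa_frequencies()) {
  if (is.na(match(type_from, amino_acids()[1:20])) ||
      is.na(match(type_to, amino_acids()[1:20])))
    stop("unknown amino-acid type")
  if (is.null(counts[type_from]) || is.na(counts[type_from]) ||
      counts[type_from] < 1L)
    stop("type_from '", type_from, "' is absent from the sequence")
  if (type_from == type_to) return(D_old)
  sq <- function(x) x * x
  D_old -
    sq(counts[[type_from]] / length - f_ref[[type_from]]) +
    sq((counts[[type_from]] - 1) / length - f_ref[[type_from]]) -
    sq(counts[[type_to]] / length - f_ref[[type_to]]) +
    sq((counts[[type_to]] + 1) / length - f_ref[[type_to]])
}

#' Composition bias settings for sequence design
#'
#' @param f_ref Reference amino-acid fractions (sum 1).
#' @param k_bias Bias strength: a composition-changing mutation passes an
#'   additional acceptance stage with probability
#'   \eqn{\min(1, \exp(-k_{bias} \Delta D))}.
#' @return An object of class \code{composition_bias}.
#' @export
composition_bias <- function(f_ref = natural_aa_frequencies(),
                             k_bias = 10000) {
  f_ref <- f_ref[amino_acids()[1:20]]
  stopifnot(all(f_ref >= 0), abs(sum(f_ref) - 1) < 1e-12, k_bias >= 0)
  structure(list(f_ref = f_ref, k_bias = k_bias),
            class = "composition_bias")
}

#' Design-run schedule
#'
#' @param n_steps Number of design Monte Carlo steps.
#' @param t_start,t_end Design temperature; equal values (the default) give
#'   a fixed low temperature, \code{t_start > t_end} gives geometric
#'   annealing.
#' @param trace_interval Steps between trace records.
#' @param seed Integer seed.
#' @return An object of class \code{design_schedule}.
#' @export
design_schedule <- function(n_steps = 2e5, t_start = 5, t_end = t_start,
                            trace_interval = 1000L, seed = 1L) {
  stopifnot(n_steps >= 1, t_start > 0, t_end > 0, trace_interval >= 1)
  structure(list(n_steps = as.double(n_steps), t_start = t_start,
                 t_end = t_end, trace_interval = as.double(trace_interval),
                 seed = as.double(seed)),
            class = "design_schedule")
}

#' Design a sequence for a fixed target structure
#'
#' Monte Carlo in sequence space on a rigid backbone: point mutations,
#' type swaps between two positions, and side-chain re-orientations.  Every
#' move passes a Metropolis stage on the total energy of the target
#' conformation; composition-changing mutations additionally pass the
#' composition-bias stage (two independent accept/reject stages, both must
#' pass).  The backbone never moves; the best-energy sequence and its
#' side-chain directions are returned.
#'
#' @param structure Target \code{lattice_system} with a single chain; its
#'   states (e.g. declared strand runs) are kept fixed.
#' @param matrix,params Energy inputs.
#' @param bias A \code{\link{composition_bias}}.
#' @param schedule A \code{\link{design_schedule}}.
#' @param initial_sequence Starting sequence for the search; the default
#'   (\code{NULL}) draws one from the reference composition \code{f_ref},
#'   so the search starts at composition distance near zero.
#' @return An object of class \code{designed_sequence}: \code{sequence}
#'   (string), \code{structure} (the target carrying the designed sequence
#'   and directions), \code{energy}, \code{composition_distance} and the
#'   search \code{trace}.
#' @export
design_sequence <- function(structure, matrix = default_interaction_matrix(),
                            params = energy_params(),
                            bias = composition_bias(),
                            schedule = design_schedule(),
                            initial_sequence = NULL) {
  .check_matrix(matrix)
  if (length(structure$chains) != 1L)
    stop("design expects a single-chain target structure")
  stopifnot(inherits(bias, "composition_bias"),
            inherits(schedule, "design_schedule"))
  n <- length(structure$chains[[1L]]$aa)
  if (is.null(initial_sequence)) {
    rs <- .save_rng()
    on.exit(.restore_rng(rs), add = TRUE)
    set.seed(schedule$seed %% .Machine$integer.max)
    initial_sequence <- paste(
      sample(names(bias$f_ref), n, replace = TRUE, prob = bias$f_ref),
      collapse = "")
  }
  if (nchar(initial_sequence) != n)
    stop("initial_sequence must match the target length")
  structure$chains[[1L]]$aa <- strsplit(initial_sequence, "")[[1L]]
  res <- cpp_design(.sys_to_engine(structure), matrix, params,
                    unname(bias$f_ref), bias$k_bias, schedule$t_start,
                    schedule$t_end, schedule$n_steps,
                    schedule$trace_interval, schedule$seed)
  out_struct <- structure
  out_struct$chains[[1L]]$aa <- .aa_decode(res$best_aa)
  out_struct$chains[[1L]]$side <- .dir_vec(res$best_dir)
  seq_str <- paste(.aa_decode(res$best_aa), collapse = "")
  structure(list(sequence = seq_str,
                 structure = out_struct,
                 energy = res$best_energy,
                 composition_distance = composition_distance(
                   seq_str, bias$f_ref),
                 trace = res$trace),
            class = "designed_sequence")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
}

#' @export
print.designed_sequence <- function(x, ...) {
  cat("designed sequence:", x$sequence, "\n")
  cat(sprintf("target energy %g, composition distance %.5f\n",
              x$energy, x$composition_distance))
  invisible(x)
}

#' @export
plot.designed_sequence <- function(x, ...) {
  plot(x$trace$step, x$trace$energy, type = "l", xlab = "design step",
       ylab = "energy of target conformation", ...)
  invisible(x)
}
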