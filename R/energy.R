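#' Scalar parameters of the potential
#'
#' Defaults: hydrogen bond \code{-50}, steric penalty \code{+55}, strand
#' state energy \code{0} (hydrogen bonding, not an explicit state energy,
#' biases residues towards the strand state) and \code{k_B = 1} (reduced
#' units throughout).
#'
#' @param eps_hb Energy per hydrogen bond.
#' @param eps_steric Penalty per pair of consecutive residues whose side
#'   chains point the same way.
#' @param eps_state Energy per residue in the strand state.
#' @param k_B Boltzmann-constant convention.
#' @param hb_strict_perpendicular When \code{TRUE} (default) a hydrogen bond
#'   additionally requires the contact vector to be perpendicular to the
#'   shared side-chain direction, i.e. the lateral strand-to-strand
#'   geometry; switching it off reverts to the bare
#'   contact + both-strand + same-direction rule.
#' @return An object of class \code{energy_params}.
#' @export
energy_params <- function(eps_hb = -50, eps_steric = 55, eps_state = 0,
                          k_B = 1, hb_strict_perpendicular = TRUE) {
  structure(list(eps_hb = eps_hb, eps_steric = eps_steric,
                 eps_state = eps_state, k_B = k_B,
                 hb_strict_perpendicular = isTRUE(hb_strict_perpendicular)),
            class = "energy_params")
}

#' The bundled hydrophobicity-based interaction matrix
#'
#' The pairwise amino-acid interaction matrix is input data to the model.
#' The package ships a documented stand-in with two physically motivated
#' components.  With \eqn{s_a \in [0,1]} the rescaled Kyte-Doolittle
#' hydropathy and \eqn{q_a \in \{-1, 0, +1/2, +1\}} the nominal side-chain
#' charge of type \eqn{a}, pair entries are
#' \eqn{M_{ab} = round(-\epsilon_p (s_a s_b - c_0) + \epsilon_q q_a q_b)}:
#' hydrophobic-hydrophobic pairs are most attractive, weakly hydrophobic
#' pairs sit near zero or slightly repulsive (the offset \eqn{c_0} keeps
#' nonspecific collapse weak, so compactness has to be earned by a designed
#' core), opposite charges attract and like charges repel (which is what
#' produces alternating charge patterns on designed beta-sheet surfaces).
#' Solvent entries are
#' \eqn{M_{sol,a} = round(\epsilon_s (s_a - 1/2))}: hydrophobic residues
#' pay to face solvent, polar ones gain.  The solvent-solvent entry is 0.
#' All entries are integers so that energy bookkeeping is exact.  A matrix
#' in the same 21 x 21 format from any other source can be supplied to
#' every function that takes one
#' (see \code{\link{read_interaction_matrix}}).
#'
#' The default scales place the strongest hydrophobic contacts at the same
#' order of magnitude as the hydrogen-bond energy (tens), so that side-chain
#' interactions -- not hydrogen bonds alone -- decide whether beta structure
#' forms; see the package vignette for the calibration rationale.
#'
#' @param pair_scale \eqn{\epsilon_p}, strength of the hydrophobic pair
#'   attraction.
#' @param solvent_scale \eqn{\epsilon_s}, strength of the solvent term.
#' @param charge_scale \eqn{\epsilon_q}, strength of the charge
#'   complementarity term.
#' @param pair_offset \eqn{c_0}, repulsive baseline of the pair term.
#' @return A symmetric 21 x 21 integer-valued matrix with dimnames
#'   \code{amino_acids()}.
#' @export
default_interaction_matrix <- function(pair_scale = 100, solvent_scale = 20,
                                       charge_scale = 50, pair_offset = 0.1) {
  aa <- amino_acids()[1:20]
  s <- (.kd_hydropathy[aa] + 4.5) / 9
  q <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5)[aa]
  q[is.na(q)] <- 0
  M <- matrix(0, 21L, 21L, dimnames = list(amino_acids(), amino_acids()))
  M[1:20, 1:20] <- round(-pair_scale * (outer(s, s) - pair_offset) +
                           charge_scale * outer(q, q))
  M[21L, 1:20] <- M[1:20, 21L] <- round(solvent_scale * (s - 0.5))
  M
}

.check_matrix <- function(M) {
  if (!is.matrix(M) || nrow(M) != 21L || ncol(M) != 21L)
    stop("interaction matrix must be 21 x 21 (20 amino acids + solvent)")
  if (!identical(M, t(M))) stop("interaction matrix must be exactly symmetric")
  if (M[21L, 21L] != 0) stop("solvent-solvent entry must be 0")
  M
}

# indicator functions -----------------------------------------------------

#' Hydrogen-bond indicator for a residue pair
#'
#' A hydrogen bond exists when the residues are in contact, both are in the
#' strand state, their side chains point the same way and (under the default
#' strict geometry) the contact vector is perpendicular to that shared
#' direction.
#'
#' @inheritParams in_contact
#' @param params An \code{\link{energy_params}} object (only
#'   \code{hb_strict_perpendicular} is used).
#' @return Integer 0 or 1; symmetric in \code{i}, \code{j}.
#' @export
hb_indicator <- function(sys, i, j, params = energy_params()) {
  i <- .res_index(sys, i, "i")
  j <- .res_index(sys, j, "j")
  if (in_contact(sys, i, j) == 0L) return(0L)
  ci <- sys$chains[[i[1L]]]; cj <- sys$chains[[j[1L]]]
  if (ci$state[i[2L]] != "strand" || cj$state[j[2L]] != "strand") return(0L)
  di <- ci$side[i[2L], ]; dj <- cj$side[j[2L], ]
  if (!all(di == dj)) return(0L)
  if (params$hb_strict_perpendicular) {
    cv <- .mi(matrix(cj$pos[j[2L], ] - ci$pos[i[2L], ], ncol = 3L),
              sys$box, sys$periodic)[1L, ]
    if (sum(cv * di) != 0L) return(0L)
  }
  1L
}

#' Side-chain direction gate for the pair interaction
#'
#' Residues in contact interact through the amino-acid matrix only when
#' their side chains face each other along the contact vector, or lie
#' parallel (same direction, perpendicular to the contact vector).
#'
#' @inheritParams in_contact
#' @return Integer 0 or 1.
#' @export
direction_interaction <- function(sys, i, j) {
  i <- .res_index(sys, i, "i")
  j <- .res_index(sys, j, "j")
  if (in_contact(sys, i, j) == 0L) return(0L)
  ci <- sys$chains[[i[1L]]]; cj <- sys$chains[[j[1L]]]
  di <- ci$side[i[2L], ]; dj <- cj$side[j[2L], ]
  cv <- .mi(matrix(cj$pos[j[2L], ] - ci$pos[i[2L], ], ncol = 3L),
            sys$box, sys$periodic)[1L, ]
  facing <- all(di == cv) && all(dj == -cv)
  lateral <- all(di == dj) && sum(di * cv) == 0L
  as.integer(facing || lateral)
}

#' Steric-hindrance indicator
#'
#' 1 iff the side chains of residues \code{i} and \code{i + 1} of a chain
#' point the same way, mimicking the backbone clash such a conformation
#' would cause in a real protein.
#'
#' @param sys A \code{lattice_system}.
#' @param chain Chain index.
#' @param i Residue index; the pair checked is \code{(i, i + 1)}.
#' @return Integer 0 or 1.
#' @export
steric_indicator <- function(sys, chain, i) {
  ch <- sys$chains[[chain]]
  if (i < 1L || i >= nrow(ch$pos)) stop("i must satisfy 1 <= i < chain length")
  as.integer(all(ch$side[i, ] == ch$side[i + 1L, ]))
}

#' Solvent-exposure indicator
#'
#' 1 iff the site the side chain points at is vacant (implicit solvent);
#' beyond a non-periodic wall also counts as solvent.
#'
#' @param sys A \code{lattice_system}.
#' @param i Residue index \code{c(chain, residue)}.
#' @return Integer 0 or 1.
#' @export
solvent_indicator <- function(sys, i) {
  i <- .res_index(sys, i, "i")
  ch <- sys$chains[[i[1L]]]
  key <- .site_key(sys, ch$pos[i[2L], ] + ch$side[i[2L], ])
  if (is.na(key)) return(1L)
  occ <- .occ_build(sys)
  as.integer(occ$chain[key] == 0L)
}

# total energy ------------------------------------------------------------

#' Total potential energy, split into its components
#'
#' The energy is the sum of five independent terms: hydrogen bonds
#' (\code{eps_hb} per bond), directional pairwise amino-acid interactions
#' (matrix entries gated by \code{\link{direction_interaction}}), the
#' per-strand-residue state energy, solvent exposure (solvent column of the
#' matrix gated by \code{\link{solvent_indicator}}) and the steric penalty
#' (\code{eps_steric} per consecutive-parallel side-chain pair).  Pair sums
#' run over unordered residue pairs exactly once.
#'
#' @param sys A \code{lattice_system}.
#' @param matrix 21 x 21 interaction matrix
#'   (default \code{\link{default_interaction_matrix}()}).
#' @param params An \code{\link{energy_params}} object.
#' @return An object of class \code{energy_breakdown}: a list with
#'   \code{e_hb}, \code{e_aa}, \code{e_state}, \code{e_solvent},
#'   \code{e_steric}, \code{total} and the hydrogen-bond count \code{n_hb}.
#' @export
total_energy <- function(sys, matrix = default_interaction_matrix(),
                         params = energy_params()) {
  .check_matrix(matrix)
  eb <- cpp_total_energy(.sys_to_engine(sys), matrix, params)
  structure(as.list(eb), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "E = %g  (hb %g | aa %g | state %g | solvent %g | steric %g; %d H-bonds)\n",
    x$total, x$e_hb, x$e_aa, x$e_state, x$e_solvent, x$e_steric,
    as.integer(x$n_hb)))
  invisible(x)
}

#' Energy difference of a move proposal
#'
#' Returns the incrementally evaluated energy change carried by a proposal
#' from \code{\link{propose_move}}; it equals
#' \code{total_energy(after)$total - total_energy(before)$total} exactly,
#' which is what the test suite asserts.
#'
#' @param sys The system the proposal was generated from.
#' @param proposal A valid \code{move_proposal}.
#' @return Numeric energy difference.
#' @export
energy_delta <- function(sys, proposal) {
  if (!inherits(proposal, "move_proposal")) stop("not a move proposal")
  if (!isTRUE(proposal$valid)) stop("proposal is not valid")
  proposal$delta_e
}
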