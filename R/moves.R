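#' Propose a single Monte Carlo move
#'
#' Builds one reversible trial move of the given kind, reports whether it is
#' valid (a valid move never breaks a structural invariant), and, for valid
#' moves, the incrementally evaluated energy change and the resulting
#' system.  Validity rules: backbone moves may not touch a residue in the
#' strand state (nor a sequential neighbour of one, since that would change
#' the strand's local backbone geometry), target sites must be vacant, and
#' side chains of relocated residues are redrawn uniformly from the
#' admissible directions at the new geometry -- the admissible count is
#' fixed (4 internal / 5 terminal), which keeps the proposal distribution
#' exactly symmetric.
#'
#' @param sys A \code{lattice_system}.
#' @param kind One of \code{"state_flip"}, \code{"side_chain_rotate"},
#'   \code{"end_move"}, \code{"corner_flip"}, \code{"point_rotation"},
#'   \code{"crankshaft"}, \code{"translate"}, \code{"rotate"}.
#' @param target \code{c(chain, residue)} for residue-level moves, or the
#'   chain index for \code{"translate"}/\code{"rotate"}.
#' @param matrix,params Energy inputs used for the energy change.
#' @param seed Integer seed driving any randomness in the proposal.
#' @param args Optional named list pinning random choices, e.g.
#'   \code{list(direction = 4)} (0-based direction code) for translations,
#'   end moves and side-chain rotations, \code{list(angle = 2)} (quarter
#'   turns) for crankshaft/rotation, \code{list(pivot = 0, axis = 2)} for
#'   rigid rotations.
#' @return An object of class \code{move_proposal} with elements
#'   \code{kind}, \code{target}, \code{valid}, \code{reason},
#'   \code{delta_e}, \code{payload} (per-residue new placement) and
#'   \code{new_system}.
#' @export
propose_move <- function(sys, kind, target,
                         matrix = default_interaction_matrix(),
                         params = energy_params(), seed = 1L, args = list()) {
  .check_matrix(matrix)
  rigid <- kind %in% c("translate", "rotate")
  if (rigid) {
    chain <- as.integer(target[1L])
    residue <- 1L
    if (chain < 1L || chain > length(sys$chains)) stop("chain out of range")
  } else {
    target <- .res_index(sys, target, "target")
    chain <- target[1L]
    residue <- target[2L]
  }
  res <- cpp_single_move(.sys_to_engine(sys), matrix, params, kind,
                         chain - 1L, residue - 1L, as.double(seed), args)
  out <- list(kind = res$kind, target = target, valid = res$valid,
              reason = res$reason %||% "")
  if (res$valid) {
    pl <- as.data.frame(res$payload)
    names(pl) <- c("chain", "residue", "x", "y", "z", "dir", "state")
    pl$chain <- pl$chain + 1L
    pl$residue <- pl$residue + 1L
    out$payload <- pl
    out$delta_e <- res$delta_e
    out$delta_components <- res$delta_components
    out$new_system <- .sys_from_engine(res$new_system)
  }
  structure(out, class = "move_proposal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a valid proposal
#'
#' @param sys The system the proposal was generated from.
#' @param proposal A \code{move_proposal} with \code{valid = TRUE}.
#' @return The modified \code{lattice_system}.
#' @export
apply_move <- function(sys, proposal) {
  if (!inherits(proposal, "move_proposal")) stop("not a move proposal")
  if (!isTRUE(proposal$valid))
    stop("cannot apply an invalid proposal (", proposal$reason, ")")
  proposal$new_system
}

#' @export
print.move_proposal <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("%s: valid, delta E = %g (%d residue(s) touched)\n",
                x$kind, x$delta_e, nrow(x$payload)))
  } else {
    cat(sprintf("%s: invalid (%s)\n", x$kind, x$reason))
  }
  invisible(x)
}
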