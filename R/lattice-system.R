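# the six lattice unit vectors, row k+1 = engine direction code k
.DIRS <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
               c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

.dir_code <- function(v) {
  # v: length-3 vector or n x 3 matrix of unit vectors -> 0-based codes
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  code <- v[, 1L] * 1L + v[, 2L] * 3L + v[, 3L] * 5L
  out <- match(code, c(1L, -1L, 3L, -3L, 5L, -5L)) - 1L
  if (anyNA(out)) stop("not a unit lattice vector")
  out
}

.dir_vec <- function(codes) .DIRS[codes + 1L, , drop = FALSE]

# minimum-image reduction of coordinate differences
.mi <- function(d, box, periodic) {
  for (a in 1:3) {
    if (periodic[a]) {
      d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
    }
  }
  d
}

#' Build a chain for the lattice model
#'
#' @param sequence Amino-acid sequence, a single string of one-letter codes
#'   (or a character vector of single letters).
#' @param positions Integer matrix with one row per residue and columns
#'   x, y, z (0-based lattice coordinates).  Consecutive rows must be
#'   lattice neighbours.
#' @param side_chains Integer matrix of side-chain unit vectors, one row per
#'   residue, or \code{NULL} to assign alternating up/down directions
#'   (falling back to the first admissible direction where the backbone
#'   runs along z).
#' @param states Character vector of per-residue secondary-structure states,
#'   \code{"coil"} or \code{"strand"}; recycled if length 1.
#' @return A list with elements \code{aa}, \code{pos}, \code{side},
#'   \code{state}, suitable for \code{\link{lattice_system}}.
#' @export
lattice_chain <- function(sequence, positions, side_chains = NULL,
                          states = "coil") {
  aa <- attr(.aa_encode(sequence), "letters")
  positions <- matrix(as.integer(positions), ncol = 3L)
  n <- length(aa)
  if (nrow(positions) != n)
    stop("sequence length (", n, ") and number of positions (",
         nrow(positions), ") differ")
  if (is.null(side_chains)) {
    side_chains <- .default_side_chains(positions)
  } else {
    side_chains <- matrix(as.integer(side_chains), ncol = 3L)
  }
  states <- rep_len(as.character(states), n)
  if (!all(states %in% c("coil", "strand")))
    stop("states must be 'coil' or 'strand'")
  list(aa = aa, pos = positions, side = side_chains, state = states)
}

# alternating +z/-z side chains; where a backbone bond runs along z, use
# the first direction not taken by a bond at that residue
.default_side_chains <- function(positions) {
  n <- nrow(positions)
  side <- matrix(0L, n, 3L)
  for (i in seq_len(n)) {
    want <- if (i %% 2L == 1L) c(0L, 0L, 1L) else c(0L, 0L, -1L)
    bonds <- list()
    if (i > 1L) bonds <- c(bonds, list(positions[i - 1L, ] - positions[i, ]))
    if (i < n) bonds <- c(bonds, list(positions[i + 1L, ] - positions[i, ]))
    ok <- !any(vapply(bonds, function(b) all(b == want), logical(1L)))
    if (ok) {
      side[i, ] <- want
    } else {
      for (k in 1:6) {
        cand <- .DIRS[k, ]
        if (!any(vapply(bonds, function(b) all(b == cand), logical(1L)))) {
          side[i, ] <- cand
          break
        }
      }
    }
  }
  side
}

#' Assemble a lattice system from chains
#'
#' A system is a simulation box plus one or more chains; all structural
#' invariants (unit bonds, self-avoidance, admissible side chains, strand
#' geometry) can be checked with \code{\link{validate_system}}.
#'
#' @param chains A single chain (from \code{\link{lattice_chain}}) or a list
#'   of chains.
#' @param box Box edge length(s), one integer or three.
#' @param periodic Logical, per axis (recycled); periodic boundaries are the
#'   default so that multi-chain runs at fixed box volume need no walls.
#' @param check If \code{TRUE} (default), stop when the assembled system
#'   violates an invariant.
#' @return An object of class \code{lattice_system}.
#' @export
lattice_system <- function(chains, box, periodic = TRUE, check = TRUE) {
  if (!is.null(chains$aa)) chains <- list(chains)
  box <- rep_len(as.integer(box), 3L)
  periodic <- rep_len(as.logical(periodic), 3L)
  if (any(box < 3L)) stop("box must be at least 3 lattice units per axis")
  sys <- structure(list(box = box, periodic = periodic, chains = chains),
                   class = "lattice_system")
  if (check) {
    v <- validate_system(sys)
    if (nrow(v) > 0L)
      stop("invalid system: ", v$rule[1L], " (chain ", v$chain[1L],
           ", residue ", v$residue[1L], ")",
           if (nrow(v) > 1L) paste0(" and ", nrow(v) - 1L, " more"))
  }
  sys
}

# engine-facing representation -------------------------------------------

.sys_to_engine <- function(sys) {
  list(box = sys$box, periodic = sys$periodic,
       chains = lapply(sys$chains, function(ch) {
         list(aa = as.integer(.aa_encode(ch$aa)),
              x = ch$pos[, 1L], y = ch$pos[, 2L], z = ch$pos[, 3L],
              dir = .dir_code(ch$side),
              state = as.integer(ch$state == "strand"))
       }))
}

.sys_from_engine <- function(e) {
  structure(list(
    box = as.integer(e$box), periodic = as.logical(e$periodic),
    chains = lapply(e$chains, function(ch) {
      list(aa = .aa_decode(ch$aa),
           pos = cbind(ch$x, ch$y, ch$z),
           side = .dir_vec(ch$dir),
           state = c("coil", "strand")[ch$state + 1L])
    })), class = "lattice_system")
}

# occupancy rebuilt from scratch: linear site index -> c(chain, residue)
.occ_build <- function(sys) {
  V <- prod(sys$box)
  occ_chain <- integer(V)
  occ_res <- integer(V)
  for (c in seq_along(sys$chains)) {
    p <- sys$chains[[c]]$pos
    key <- (p[, 3L] * sys$box[2L] + p[, 2L]) * sys$box[1L] + p[, 1L] + 1L
    occ_chain[key] <- c
    occ_res[key] <- seq_len(nrow(p))
  }
  list(chain = occ_chain, res = occ_res)
}

.site_key <- function(sys, p) {
  for (a in 1:3) {
    if (sys$periodic[a]) {
      p[a] <- p[a] %% sys$box[a]
    } else if (p[a] < 0L || p[a] >= sys$box[a]) {
      return(NA_integer_)  # off a wall: implicit solvent, never occupied
    }
  }
  (p[3L] * sys$box[2L] + p[2L]) * sys$box[1L] + p[1L] + 1L
}

#' Check every structural invariant of a system
#'
#' Verifies, per chain and residue: positions inside the box (reduced when
#' periodic), unit backbone bonds, self-avoidance within and between
#' chains, side chains that are unit vectors not pointing along a backbone
#' bond, and strand-state geometry (a strand residue sits on a straight
#' backbone segment -- so terminal residues are never strand -- and
#' sequential strand neighbours carry opposite side chains).
#'
#' @param sys A \code{lattice_system}.
#' @return A data frame with one row per violation (columns \code{rule},
#'   \code{chain}, \code{residue}, \code{detail}); zero rows iff the system
#'   is valid.
#' @export
validate_system <- function(sys) {
  bad <- list()
  note <- function(rule, chain, residue, detail = "") {
    bad[[length(bad) + 1L]] <<- data.frame(
      rule = rule, chain = chain, residue = residue, detail = detail,
      stringsAsFactors = FALSE)
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (c in seq_along(sys$chains)) {
    ch <- sys$chains[[c]]
    n <- nrow(ch$pos)
    for (i in seq_len(n)) {
      p <- ch$pos[i, ]
      for (a in 1:3) {
        if (p[a] < 0L || p[a] >= sys$box[a]) {
          note("position outside box", c, i, paste0("axis ", a))
        }
      }
      key <- as.character(.site_key(sys, p))
      if (!is.null(seen[[key]])) {
        note("site occupied twice", c, i,
             paste0("also chain ", seen[[key]][1L],
                    " residue ", seen[[key]][2L]))
      } else {
        seen[[key]] <- c(c, i)
      }
    }
    bonds <- .mi(diff(ch$pos), sys$box, sys$periodic)
    for (i in seq_len(n - 1L)) {
      if (sum(abs(bonds[i, ])) != 1L)
        note("backbone bond not unit length", c, i)
    }
    for (i in seq_len(n)) {
      s <- ch$side[i, ]
      if (sum(abs(s)) != 1L) {
        note("side chain not a unit vector", c, i)
        next
      }
      if (i > 1L && all(s == -bonds[i - 1L, ]))
        note("side chain along backbone bond", c, i)
      if (i < n && all(s == bonds[i, ]))
        note("side chain along backbone bond", c, i)
    }
    strand <- ch$state == "strand"
    for (i in which(strand)) {
      if (i == 1L || i == n || !all(bonds[i - 1L, ] == bonds[i, ])) {
        note("strand residue at backbone turn", c, i)
      }
      for (j in c(i - 1L, i + 1L)) {
        if (j >= 1L && j <= n && j > i && strand[j] &&
            !all(ch$side[i, ] == -ch$side[j, ])) {
          note("sequential strand residues without opposite side chains",
               c, i)
        }
      }
    }
  }
  if (length(bad) == 0L) {
    data.frame(rule = character(), chain = integer(), residue = integer(),
               detail = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' @export
print.lattice_system <- function(x, ...) {
  cat("Lattice system:", length(x$chains), "chain(s) in a",
      paste(x$box, collapse = " x "), "box",
      if (all(x$periodic)) "(periodic)" else "", "\n")
  for (c in seq_along(x$chains)) {
    ch <- x$chains[[c]]
    cat(sprintf("  chain %d: %s (%d residues, %d strand)\n", c,
                paste(ch$aa, collapse = ""), length(ch$aa),
                sum(ch$state == "strand")))
  }
  invisible(x)
}

#' @export
summary.lattice_system <- function(object, ...) {
  cat("chains:", length(object$chains),
      " residues:", sum(vapply(object$chains, function(ch) length(ch$aa),
                               integer(1L))), "\n")
  cat("hydrogen bonds:", hydrogen_bond_count(object), "\n")
  viol <- validate_system(object)
  cat("violations:", nrow(viol), "\n")
  invisible(object)
}

#' @export
plot.lattice_system <- function(x, ...) {
  # xy and xz projections, chains coloured, side chains as short ticks
  oldpar <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(oldpar))
  proj <- function(a, b, lab) {
    xs <- unlist(lapply(x$chains, function(ch) ch$pos[, a]))
    ys <- unlist(lapply(x$chains, function(ch) ch$pos[, b]))
    plot(xs, ys, type = "n", xlab = c("x", "y", "z")[a],
         ylab = c("x", "y", "z")[b], main = lab, asp = 1, ...)
    for (c in seq_along(x$chains)) {
      ch <- x$chains[[c]]
      lines(ch$pos[, a], ch$pos[, b], col = c, lwd = 2)
      points(ch$pos[, a], ch$pos[, b], col = c, pch = 19, cex = 0.8)
    }
  }
  proj(1L, 2L, "xy projection")
  proj(1L, 3L, "xz projection")
  invisible(x)
}
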