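#' Face-adjacent neighbours of a lattice site
#'
#' @param p Integer site, length 3 (0-based coordinates).
#' @param box Box edge length(s), one integer or three.
#' @param periodic Logical, per axis (recycled).  On a non-periodic axis,
#'   sites beyond a wall are dropped, so boundary sites have fewer than six
#'   neighbours.
#' @return Integer matrix, one neighbouring site per row (six rows in a
#'   periodic box).
#' @export
lattice_neighbors <- function(p, box, periodic = TRUE) {
  box <- rep_len(as.integer(box), 3L)
  periodic <- rep_len(as.logical(periodic), 3L)
  p <- as.integer(p)
  if (any(p < 0L | p >= box)) stop("site outside box")
  out <- matrix(NA_integer_, 0L, 3L)
  for (k in 1:6) {
    q <- p + .DIRS[k, ]
    ok <- TRUE
    for (a in 1:3) {
      if (q[a] < 0L || q[a] >= box[a]) {
        if (periodic[a]) q[a] <- q[a] %% box[a] else ok <- FALSE
      }
    }
    if (ok) out <- rbind(out, q)
  }
  dimnames(out) <- NULL
  out
}

# resolve an index pair c(chain, residue) with bounds checking
.res_index <- function(sys, i, what = "index") {
  i <- as.integer(i)
  if (length(i) != 2L) stop(what, " must be c(chain, residue)")
  if (i[1L] < 1L || i[1L] > length(sys$chains))
    stop(what, ": chain out of range")
  if (i[2L] < 1L || i[2L] > nrow(sys$chains[[i[1L]]]$pos))
    stop(what, ": residue out of range")
  i
}

.adjacent <- function(sys, i, j) {
  d <- .mi(matrix(sys$chains[[i[1L]]]$pos[i[2L], ] -
                  sys$chains[[j[1L]]]$pos[j[2L], ], ncol = 3L),
           sys$box, sys$periodic)
  sum(abs(d)) == 1L
}

#' Contact indicator between two residues
#'
#' Two residues are in contact when they sit on neighbouring lattice sites
#' and are not sequential neighbours in the same chain.
#'
#' @param sys A \code{lattice_system}.
#' @param i,j Residue indices, each \code{c(chain, residue)} (1-based).
#' @return Integer 0 or 1.
#' @export
in_contact <- function(sys, i, j) {
  i <- .res_index(sys, i, "i")
  j <- .res_index(sys, j, "j")
  if (all(i == j)) stop("i and j refer to the same residue")
  if (i[1L] == j[1L] && abs(i[2L] - j[2L]) == 1L) return(0L)
  as.integer(.adjacent(sys, i, j))
}

#' Is the backbone straight at a residue?
#'
#' True iff the two bonds flanking residue \code{i} point the same way.
#' Terminal residues, which have only one bond, are defined non-collinear,
#' so they can never enter the strand state.
#'
#' @param sys A \code{lattice_system}.
#' @param chain Chain index.
#' @param i Residue index within the chain.
#' @return Logical.
#' @export
is_collinear_at <- function(sys, chain, i) {
  ch <- sys$chains[[chain]]
  n <- nrow(ch$pos)
  if (i <= 1L || i >= n) return(FALSE)
  b <- .mi(diff(ch$pos[(i - 1L):(i + 1L), ]), sys$box, sys$periodic)
  all(b[1L, ] == b[2L, ])
}
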