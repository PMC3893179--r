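#' Amino-acid alphabet of the model
#'
#' The twenty standard one-letter codes, in the fixed order used by the
#' interaction matrix, followed by the solvent pseudo-type \code{"SOL"}
#' (every vacant lattice site is implicit solvent).
#'
#' @return Character vector of length 21.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "SOL")
}

# Kyte-Doolittle hydropathy, used to build the bundled interaction matrix
.kd_hydropathy <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Reference amino-acid composition of natural proteins
#'
#' Average single-residue frequencies of the twenty amino acids in a large
#' curated protein-sequence database, rounded to multiples of 1e-4 and
#' adjusted so they sum to exactly one.  This is the default reference
#' distribution for the composition bias of the sequence-design algorithm.
#'
#' @return Named numeric vector of length 20 summing to 1, in the order of
#'   \code{\link{amino_acids}}.
#' @export
natural_aa_frequencies <- function() {
  f <- c(A = 825, C = 138, D = 545, E = 675, F = 386, G = 707, H = 227,
         I = 596, K = 584, L = 976, M = 242, N = 406, P = 470, Q = 393,
         R = 553, S = 656, T = 534, V = 687, W = 108, Y = 292)
  stopifnot(sum(f) == 10000L)
  f / 10000
}

# sequence string (or character vector) -> 0-based engine codes
.aa_encode <- function(sequence) {
  letters1 <- if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    strsplit(sequence, "")[[1L]] else as.character(sequence)
  idx <- match(letters1, amino_acids()[1:20])
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("unknown amino-acid code '", letters1[bad], "' at position ", bad)
  }
  structure(idx - 1L, letters = letters1)
}

.aa_decode <- function(codes) amino_acids()[codes + 1L]
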