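#' Compact cuboid target structure
#'
#' A space-filling self-avoiding walk through an \code{nx x ny x nz} block
#' (serpentine within each layer, layers stacked along z), centred in the
#' box.  The 3 x 3 x 4 block holds a 36-residue chain and is the standard
#' design target for beta-sheet-forming model proteins.
#'
#' With \code{strand_runs = TRUE} (the default) the interior residues of
#' each straight x-run are declared strand, with side chains along +/-y by
#' column parity, so that vertically stacked runs form a native
#' hydrogen-bond pattern; all remaining residues are coil with side chains
#' alternating along +/-z.  With \code{strand_runs = FALSE} every residue
#' is coil.
#'
#' @param nx,ny,nz Block dimensions; the product is the chain length.
#' @param sequence Optional sequence of length \code{nx*ny*nz}; default
#'   poly-alanine (the design algorithm replaces it anyway).
#' @param box Box edge length(s); default leaves ample solvent around the
#'   block.
#' @param periodic Periodic boundaries (default TRUE).
#' @param strand_runs Declare native strand runs (see above).
#' @return A valid single-chain \code{lattice_system}.
#' @export
compact_cuboid_structure <- function(nx, ny, nz, sequence = NULL,
                                     box = max(nx, ny, nz) + 10L,
                                     periodic = TRUE, strand_runs = TRUE) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (nx < 1L || ny < 1L || nz < 1L) stop("impossible dimensions")
  n <- nx * ny * nz
  if ((nx > 1L) + (ny > 1L) + (nz > 1L) == 0L && n > 1L)
    stop("impossible dimensions")
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  if (nchar(sequence) != n)
    stop("sequence length must equal nx * ny * nz = ", n)
  pos <- matrix(0L, n, 3L)
  k <- 0L
  for (iz in 0L:(nz - 1L)) {
    for (iy0 in 0L:(ny - 1L)) {
      iy <- if (iz %% 2L == 0L) iy0 else ny - 1L - iy0     # reverse layers
      for (ix0 in 0L:(nx - 1L)) {
        fwd <- (iz * ny + iy0) %% 2L == 0L  # flip x with every row walked
        ix <- if (fwd) ix0 else nx - 1L - ix0              # serpentine rows
        k <- k + 1L
        pos[k, ] <- c(ix, iy, iz)
      }
    }
  }
  box <- rep_len(as.integer(box), 3L)
  off <- (box - c(nx, ny, nz)) %/% 2L
  grid <- pos  # block-frame coordinates before centring
  pos <- sweep(pos, 2L, off, "+")
  states <- rep("coil", n)
  side <- NULL
  if (strand_runs && nx >= 3L) {
    bonds <- diff(pos)
    interior <- vapply(seq_len(n), function(i) {
      i > 1L && i < n && bonds[i - 1L, 1L] != 0L && bonds[i, 1L] != 0L
    }, logical(1L))
    states[interior] <- "strand"
    side <- .default_side_chains(pos)
    side[interior, ] <- 0L
    side[interior, 2L] <- ifelse(grid[interior, 1L] %% 2L == 0L, 1L, -1L)
  }
  lattice_system(lattice_chain(sequence, pos, side, states), box = box,
                 periodic = periodic)
}

#' Idealised cross-beta fibril seed
#'
#' \code{n_peptides} copies of a peptide laid out as straight, in-register
#' strands along x, stacked along y.  Internal residues are in the strand
#' state with side chains alternating +z/-z along the chain and identical
#' across strands, so every laterally adjacent internal residue pair forms
#' a hydrogen bond: \code{(n_peptides - 1) * (length - 2)} bonds in total
#' (terminal residues sit on a single bond, are defined non-collinear and
#' therefore stay coil).
#'
#' @param n_peptides Number of peptides (>= 2).
#' @param sequence Peptide sequence (>= 2 residues).
#' @param box Box edge length(s), default 30 as used for small-fibril
#'   simulations.
#' @param periodic Periodic boundaries.
#' @param antiparallel If TRUE, alternate the chain direction of successive
#'   strands (default FALSE: parallel stacking).
#' @return A valid \code{lattice_system}.
#' @export
seed_fibril <- function(n_peptides, sequence, box = 30L, periodic = TRUE,
                        antiparallel = FALSE) {
  if (n_peptides < 2L) stop("a seed needs at least 2 peptides")
  len <- nchar(sequence)
  if (len < 2L) stop("peptide must have at least 2 residues")
  box <- rep_len(as.integer(box), 3L)
  if (len + 2L > box[1L] || n_peptides + 2L > box[2L])
    stop("box too small for the seed")
  x0 <- (box[1L] - len) %/% 2L
  y0 <- (box[2L] - n_peptides) %/% 2L
  z0 <- box[3L] %/% 2L
  side_for <- function(ix) if (ix %% 2L == 0L) c(0L, 0L, 1L) else c(0L, 0L, -1L)
  chains <- vector("list", n_peptides)
  for (k in seq_len(n_peptides)) {
    xs <- x0 + 0:(len - 1L)
    if (antiparallel && k %% 2L == 0L) xs <- rev(xs)
    pos <- cbind(xs, y0 + k - 1L, z0)
    side <- t(vapply(xs - x0, side_for, integer(3L)))
    states <- rep("coil", len)
    states[2:(len - 1L)] <- "strand"
    chains[[k]] <- lattice_chain(sequence, pos, side, states)
  }
  lattice_system(chains, box = box, periodic = periodic)
}

#' Bundled reference sequences
#'
#' The four sequences used throughout the documentation and tests: a
#' 36-residue sequence designed to fold into a compact beta-sheet
#' structure, a random 36-residue sequence of similar amino-acid
#' composition, and the two 7-residue peptides (uniformly polar
#' \code{TTTTTTT} and alternating polar/hydrophobic \code{TFTFTFT}) whose
#' fibril stability differs sharply.
#'
#' @return Named character vector of length 4.
#' @export
reference_sequences <- function() {
  c(designed = "TLSINDYGESEPFKVAVCELQNDDIHIKSLRPARCG",
    random = "PEAMIGPLTGAIHFKVSTSNWGREDLEDVYRQANLI",
    TTTTTTT = "TTTTTTT",
    TFTFTFT = "TFTFTFT")
}

#' Randomly dispersed peptides at fixed count
#'
#' Places \code{n_peptides} straight rods at non-overlapping random
#' positions and orientations with no initial inter-peptide contacts, the
#' starting condition for spontaneous-aggregation runs.
#'
#' @inheritParams seed_fibril
#' @param seed Integer seed for the placement.
#' @return A valid \code{lattice_system}.
#' @export
dispersed_peptides <- function(n_peptides, sequence, box = 30L,
                               periodic = TRUE, seed = 1L) {
  len <- nchar(sequence)
  box <- rep_len(as.integer(box), 3L)
  set.seed(seed)
  chains <- list()
  taken <- new.env(hash = TRUE, parent = emptyenv())
  guard <- 0L
  while (length(chains) < n_peptides) {
    guard <- guard + 1L
    if (guard > 20000L) stop("could not place peptides; box too crowded")
    p0 <- vapply(box, function(L) sample.int(L, 1L) - 1L, integer(1L))
    ax <- sample.int(6L, 1L)
    periodic3 <- rep_len(as.logical(periodic), 3L)
    raw <- t(vapply(0:(len - 1L), function(i) p0 + i * .DIRS[ax, ],
                    integer(3L)))
    if (any(!periodic3 & (raw < 0L | raw >= matrix(box, len, 3L, TRUE))))
      next
    pos <- sweep(raw, 2L, box, "%%")
    storage.mode(pos) <- "integer"
    # demand one site of clearance so no initial contacts exist
    keys <- character(0)
    ok <- TRUE
    for (i in seq_len(len)) {
      for (dk in 0:6) {
        q <- if (dk == 0L) pos[i, ] else (pos[i, ] + .DIRS[dk, ]) %% box
        key <- paste(q, collapse = ",")
        if (dk == 0L) keys <- c(keys, key)
        if (!is.null(taken[[key]])) ok <- FALSE
      }
      if (!ok) break
    }
    if (!ok) next
    for (key in keys) taken[[key]] <- TRUE
    perp <- (which(.DIRS[ax, ] != 0L)) %% 3L + 1L  # axis orthogonal to rod
    side <- matrix(0L, len, 3L)
    side[, perp] <- rep_len(c(1L, -1L), len)
    chains[[length(chains) + 1L]] <- lattice_chain(sequence, pos, side)
  }
  lattice_system(chains, box = box, periodic = periodic)
}
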