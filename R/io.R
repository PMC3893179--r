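#' Write a system in the plain-text conformation format
#'
#' One line per residue: \code{chain_id index aa x y z dx dy dz state},
#' preceded by two comment lines carrying the box size and periodicity so
#' the reader can rebuild the system exactly.
#'
#' @param sys A \code{lattice_system}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_conformation <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# box", paste(sys$box, collapse = " ")), con)
  writeLines(paste("# periodic", paste(as.integer(sys$periodic),
                                       collapse = " ")), con)
  for (c in seq_along(sys$chains)) {
    ch <- sys$chains[[c]]
    for (i in seq_len(nrow(ch$pos))) {
      writeLines(paste(c, i, ch$aa[i], paste(ch$pos[i, ], collapse = " "),
                       paste(ch$side[i, ], collapse = " "), ch$state[i]),
                 con)
    }
  }
  invisible(path)
}

#' Read a system from the conformation format
#'
#' @param path File written by \code{\link{write_conformation}}.
#' @param check Validate the system after reading (default TRUE).
#' @return A \code{lattice_system}; the write/read round trip is exact.
#' @export
read_conformation <- function(path, check = TRUE) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  box <- c(20L, 20L, 20L)
  periodic <- c(TRUE, TRUE, TRUE)
  for (h in hdr) {
    f <- strsplit(trimws(sub("^#", "", h)), "\\s+")[[1L]]
    if (f[1L] == "box") box <- as.integer(f[2:4])
    if (f[1L] == "periodic") periodic <- as.integer(f[2:4]) == 1L
  }
  f <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  if (ncol(f) != 10L) stop("malformed conformation file")
  chains <- lapply(split(seq_len(nrow(f)), as.integer(f[, 1L])), function(r) {
    r <- r[order(as.integer(f[r, 2L]))]
    pos <- matrix(as.integer(f[r, 4:6]), ncol = 3L)
    side <- matrix(as.integer(f[r, 7:9]), ncol = 3L)
    lattice_chain(f[r, 3L], pos, side, f[r, 10L])
  })
  names(chains) <- NULL
  lattice_system(chains, box = box, periodic = periodic, check = check)
}

#' Export a system as a pseudo-atom PDB file
#'
#' One CA atom per residue at 3.8 A per lattice unit, plus a CB pseudo-atom
#' one lattice unit along the side-chain direction; chains get distinct PDB
#' chain identifiers.  For visualisation only.
#'
#' @param sys A \code{lattice_system}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_pdb <- function(sys, path) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  ids <- c(LETTERS, letters, 0:9)
  for (c in seq_along(sys$chains)) {
    ch <- sys$chains[[c]]
    for (i in seq_len(nrow(ch$pos))) {
      for (atom in c("CA", "CB")) {
        p <- if (atom == "CA") ch$pos[i, ] else ch$pos[i, ] + ch$side[i, ]
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, atom, aa3[[ch$aa[i]]], ids[(c - 1L) %% 62L + 1L], i,
          p[1L] * 3.8, p[2L] * 3.8, p[3L] * 3.8), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an interaction matrix file
#'
#' Whitespace-delimited square table: a header row of the 20 one-letter
#' codes plus \code{SOL}, then 21 labelled rows.  Symmetry and a zero
#' solvent-solvent entry are validated exactly.
#'
#' @param path Matrix file path.
#' @return A 21 x 21 matrix with dimnames \code{amino_acids()}.
#' @export
read_interaction_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  M <- as.matrix(tab[, -1L])
  rownames(M) <- tab[[1L]]
  M <- M[amino_acids(), amino_acids()]
  .check_matrix(M)
}

#' @rdname read_interaction_matrix
#' @param M The matrix to write.
#' @export
write_interaction_matrix <- function(M, path) {
  .check_matrix(M)
  tab <- data.frame(type = rownames(M), M, check.names = FALSE)
  write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value file understood by the command-line interface; keys:
#' \code{box}, \code{periodic}, \code{temperature} (scalar or vector),
#' \code{n_iterations}, \code{p_global}, \code{sample_interval},
#' \code{swap_interval}, \code{seed}, \code{matrix} (path or
#' \code{"default"}), \code{eps_hb}, \code{eps_steric}, \code{eps_state},
#' \code{hb_strict_perpendicular}, \code{activity},
#' \code{insertion_attempt_rate}, \code{sequence}.
#'
#' @param path YAML file path.
#' @return A list with components \code{config} (raw values),
#'   \code{matrix}, \code{params} and \code{schedule}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  M <- if (is.null(cfg$matrix) || identical(cfg$matrix, "default"))
    default_interaction_matrix() else read_interaction_matrix(cfg$matrix)
  params <- energy_params(
    eps_hb = cfg$eps_hb %||% -50, eps_steric = cfg$eps_steric %||% 55,
    eps_state = cfg$eps_state %||% 0, k_B = cfg$k_B %||% 1,
    hb_strict_perpendicular = cfg$hb_strict_perpendicular %||% TRUE)
  schedule <- mc_schedule(
    n_iterations = cfg$n_iterations %||% 1e5,
    p_global = cfg$p_global %||% 0.2,
    sample_interval = cfg$sample_interval %||% 100,
    seed = cfg$seed %||% 1,
    swap_interval = cfg$swap_interval %||% 1000)
  list(config = cfg, matrix = M, params = params, schedule = schedule)
}

#' Write a trajectory as delimited text
#'
#' @param traj An \code{mc_trajectory} or a bare trajectory data frame.
#' @param path Output path (tab-separated, with header).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- if (inherits(traj, "mc_trajectory")) traj$trajectory else traj
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
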