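# Independent reference machinery used across the test suite.
# Everything here is written from the model definition directly (plain
# double loops, no incremental bookkeeping, no package geometry helpers)
# so it can serve as an oracle for the package's implementation.

ODIRS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

omi <- function(d, box, per) {
  for (a in 1:3) if (per[a]) d[a] <- d[a] - box[a] * round(d[a] / box[a])
  d
}

# brute-force total energy by a double loop over all residue pairs
oracle_energy <- function(sys, M, params) {
  res <- do.call(rbind, lapply(seq_along(sys$chains), function(c) {
    ch <- sys$chains[[c]]
    data.frame(chain = c, idx = seq_along(ch$aa), aa = ch$aa,
               x = ch$pos[, 1], y = ch$pos[, 2], z = ch$pos[, 3],
               dx = ch$side[, 1], dy = ch$side[, 2], dz = ch$side[, 3],
               strand = ch$state == "strand")
  }))
  n <- nrow(res); box <- sys$box; per <- sys$periodic
  e_hb <- e_aa <- e_st <- e_sol <- e_state <- 0
  n_hb <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    dv <- omi(c(res$x[j] - res$x[i], res$y[j] - res$y[i],
                res$z[j] - res$z[i]), box, per)
    if (sum(abs(dv)) != 1) next
    if (res$chain[i] == res$chain[j] && abs(res$idx[i] - res$idx[j]) == 1) next
    di <- c(res$dx[i], res$dy[i], res$dz[i])
    dj <- c(res$dx[j], res$dy[j], res$dz[j])
    same <- all(di == dj)
    if (res$strand[i] && res$strand[j] && same &&
        (!params$hb_strict_perpendicular || sum(di * dv) == 0)) {
      e_hb <- e_hb + params$eps_hb
      n_hb <- n_hb + 1L
    }
    facing <- all(di == dv) && all(dj == -dv)
    lateral <- same && sum(di * dv) == 0
    if (facing || lateral) e_aa <- e_aa + M[res$aa[i], res$aa[j]]
  }
  occupied <- function(p) {
    for (a in 1:3) {
      if (per[a]) p[a] <- p[a] %% box[a]
      else if (p[a] < 0 || p[a] >= box[a]) return(FALSE)
    }
    any(res$x == p[1] & res$y == p[2] & res$z == p[3])
  }
  for (i in seq_len(n)) {
    if (!occupied(c(res$x[i] + res$dx[i], res$y[i] + res$dy[i],
                    res$z[i] + res$dz[i])))
      e_sol <- e_sol + M["SOL", res$aa[i]]
    e_state <- e_state + params$eps_state * res$strand[i]
  }
  for (c in seq_along(sys$chains)) {
    ch <- sys$chains[[c]]
    for (i in seq_len(nrow(ch$pos) - 1))
      if (all(ch$side[i, ] == ch$side[i + 1, ]))
        e_st <- e_st + params$eps_steric
  }
  list(e_hb = e_hb, e_aa = e_aa, e_state = e_state, e_solvent = e_sol,
       e_steric = e_st, total = e_hb + e_aa + e_state + e_sol + e_st,
       n_hb = n_hb)
}

# grow a random valid system: self-avoiding chains, admissible side chains,
# legal strand assignments; built with its own arithmetic
random_system <- function(n_chains = NULL, max_len = 12, box = 8,
                          periodic = TRUE, strand_prob = 0.4) {
  box <- rep_len(as.integer(box), 3)
  per <- rep_len(as.logical(periodic), 3)
  if (is.null(n_chains)) n_chains <- sample(1:3, 1)
  wrap <- function(p) {
    for (a in 1:3) {
      if (per[a]) p[a] <- p[a] %% box[a]
    }
    p
  }
  inbox <- function(p) all(p >= 0 & p < box)
  taken <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  chains <- list()
  aa20 <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  for (c in seq_len(n_chains)) {
    len <- sample(2:max_len, 1)
    for (attempt in 1:200) {
      p <- sapply(box, function(L) sample.int(L, 1) - 1L)
      if (!is.null(taken[[key(p)]])) next
      pos <- matrix(p, 1, 3)
      ok <- TRUE
      for (i in seq_len(len - 1)) {
        cand <- list()
        for (k in 1:6) {
          q <- wrap(pos[i, ] + ODIRS[k, ])
          if (!inbox(q)) next
          if (is.null(taken[[key(q)]]) &&
              !any(apply(pos, 1, function(r) all(r == q))))
            cand[[length(cand) + 1]] <- q
        }
        if (length(cand) == 0) { ok <- FALSE; break }
        pos <- rbind(pos, cand[[sample.int(length(cand), 1)]])
      }
      if (!ok) next
      # side chains: uniform over directions not along a bond
      bonds <- t(apply(rbind(diff(pos)), 1, omi, box = box, per = per))
      side <- matrix(0L, len, 3)
      for (i in 1:len) {
        excl <- c(if (i > 1) list(-bonds[i - 1, ]) else NULL,
                  if (i < len) list(bonds[i, ]) else NULL)
        opts <- which(apply(ODIRS, 1, function(d)
          !any(vapply(excl, function(b) all(d == b), logical(1)))))
        side[i, ] <- ODIRS[sample(opts, 1), ]
      }
      # strand states: only at straight internal residues, sequential
      # strand neighbours must carry opposite side chains
      state <- rep("coil", len)
      for (i in seq_len(len)) {
        if (i == 1 || i == len) next
        if (!all(bonds[i - 1, ] == bonds[i, ])) next
        if (runif(1) > strand_prob) next
        legal <- TRUE
        for (j in c(i - 1, i + 1)) {
          if (j >= 1 && j <= len && state[j] == "strand" &&
              !all(side[i, ] == -side[j, ])) legal <- FALSE
        }
        if (legal) state[i] <- "strand"
      }
      for (i in 1:len) taken[[key(pos[i, ])]] <- TRUE
      chains[[c]] <- lattice_chain(paste(sample(aa20, len, replace = TRUE),
                                         collapse = ""),
                                   pos, side, state)
      break
    }
    if (length(chains) < c) stop("could not grow a chain")
  }
  lattice_system(chains, box = box, periodic = per)
}

# a random integer interaction matrix (symmetric, SOL-SOL zero)
random_matrix <- function(scale = 20) {
  aa <- amino_acids()
  M <- matrix(sample(-scale:scale, 21 * 21, replace = TRUE), 21, 21,
              dimnames = list(aa, aa))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M[21, 21] <- 0
  storage.mode(M) <- "double"
  M
}

# all microstates of a 3-mer in a periodic box, as total-energy values;
# translation multiplicity is uniform and cancels in class probabilities
enumerate_3mer_energies <- function(seqstr, M, params, box = 3L) {
  Es <- numeric(0)
  negd <- function(b) which(apply(ODIRS, 1, function(v) all(v == -ODIRS[b, ])))
  for (b1 in 1:6) for (b2 in setdiff(1:6, negd(b1))) {
    p1 <- c(1L, 1L, 1L)
    p2 <- (p1 + ODIRS[b1, ]) %% box
    p3 <- (p2 + ODIRS[b2, ]) %% box
    for (d1 in setdiff(1:6, b1))
      for (d2 in setdiff(1:6, c(negd(b1), b2)))
        for (d3 in setdiff(1:6, negd(b2))) {
          ch <- lattice_chain(seqstr, rbind(p1, p2, p3),
                              ODIRS[c(d1, d2, d3), ], "coil")
          sys <- lattice_system(ch, box = box, periodic = TRUE,
                                check = FALSE)
          E <- oracle_energy(sys, M, params)$total
          Es <- c(Es, E)
          if (b1 == b2) Es <- c(Es, E)  # strand state of the middle residue
        }
  }
  Es
}
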