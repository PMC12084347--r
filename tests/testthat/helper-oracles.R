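# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately use plain O(N^2) loops and per-axis
# minimum-image arithmetic, independent of the package's cell-list path.

mi_dist <- function(a, b, L) {
  d <- a - b
  d <- d - L * round(d / L)
  sqrt(sum(d^2))
}

# O(N^2) residue-residue contact frequency map over all frames.
brute_contact_map <- function(traj, cutoff = 4.5) {
  top <- traj$topology
  idx <- which(top$molecule_kind == "protein" & top$heavy)
  resids <- sort(unique(top$residue_index[idx]))
  N <- length(resids)
  nf <- dim(traj$coords)[3]
  f <- matrix(0, N, N)
  for (fr in seq_len(nf)) {
    X <- traj$coords[idx, , fr]
    L <- traj$box[fr, ]
    hit <- matrix(FALSE, N, N)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a >= b) next
        if (mi_dist(X[a, ], X[b, ], L) <= cutoff) {
          i <- match(top$residue_index[idx[a]], resids)
          j <- match(top$residue_index[idx[b]], resids)
          if (i != j) { hit[i, j] <- TRUE; hit[j, i] <- TRUE }
        }
      }
    }
    f <- f + hit
  }
  f <- f / nf
  diag(f) <- NA_real_
  f
}

# O(N*M) per-residue count of cosolvent molecules in contact, frame-mean.
brute_cosolvent_contacts <- function(traj, cutoff = 4.5) {
  top <- traj$topology
  pidx <- which(top$molecule_kind == "protein" & top$heavy)
  cidx <- which(top$molecule_kind == "cosolvent" & top$heavy)
  resids <- sort(unique(top$residue_index[pidx]))
  N <- length(resids)
  nf <- dim(traj$coords)[3]
  if (length(cidx) == 0) return(rep(0, N))
  mols <- sort(unique(top$molecule_id[cidx]))
  acc <- rep(0, N)
  for (fr in seq_len(nf)) {
    L <- traj$box[fr, ]
    for (i in seq_len(N)) {
      ai <- pidx[top$residue_index[pidx] == resids[i]]
      n_mol <- 0
      for (mol in mols) {
        aj <- cidx[top$molecule_id[cidx] == mol]
        found <- FALSE
        for (a in ai) {
          for (b in aj) {
            if (mi_dist(traj$coords[a, , fr], traj$coords[b, , fr], L)
                <= cutoff) { found <- TRUE; break }
          }
          if (found) break
        }
        if (found) n_mol <- n_mol + 1
      }
      acc[i] <- acc[i] + n_mol
    }
  }
  acc / nf
}

# Build a trajectory directly from an atom table and coordinate array, for
# hand-constructed geometries.
toy_traj <- function(coords, residue_index, box = c(100, 100, 100),
                     molecule_kind = "protein", heavy = TRUE,
                     sidechain = FALSE, residue_type = "G",
                     atom_name = "BB", mass = 12, molecule_id = NULL) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  n <- dim(coords)[1]
  rec <- function(x) rep_len(x, n)
  if (is.null(molecule_id)) {
    molecule_id <- ifelse(rec(molecule_kind) == "protein", 1L,
                          rec(residue_index))
  }
  trajectory(data.frame(
    residue_index = rec(residue_index), residue_type = rec(residue_type),
    atom_name = rec(atom_name), element = "C", mass = rec(mass),
    heavy = rec(heavy), sidechain = rec(sidechain),
    molecule_id = rec(molecule_id), molecule_kind = rec(molecule_kind),
    stringsAsFactors = FALSE), coords, box)
}

# A random compact protein + cosolvent system for oracle comparisons.
random_system <- function(n_res = 20, n_mol = 10, n_frames = 5, seed = 1,
                          box_edge = 25) {
  ch <- gen_chain_ensemble(chain_spec(n_res, confinement_strength = 1.2,
                                      n_frames = n_frames, seed = seed,
                                      box_edge = box_edge))
  gen_cosolvent_box(cosolvent_spec(n_mol, box_edge = box_edge,
                                   adsorption_bias = 0.5, seed = seed + 100),
                    ch)
}

# Vectorised all-pairs (brute-force) oracles for the acceptance-scale
# comparisons: same O(N^2) arithmetic as the loop versions above, computed
# with whole-matrix operations so 100-frame systems stay fast. Entirely
# independent of the package's cell-list path.

mi_d2_matrix <- function(A, B, L) {
  d2 <- 0
  for (d in 1:3) {
    dd <- outer(A[, d], B[, d], "-")
    dd <- dd - L[d] * round(dd / L[d])
    d2 <- d2 + dd * dd
  }
  d2
}

brute_contact_map_vec <- function(traj, cutoff = 4.5) {
  top <- traj$topology
  idx <- which(top$molecule_kind == "protein" & top$heavy)
  resids <- sort(unique(top$residue_index[idx]))
  N <- length(resids)
  grp <- match(top$residue_index[idx], resids)
  nf <- dim(traj$coords)[3]
  f <- matrix(0, N, N)
  for (fr in seq_len(nf)) {
    X <- matrix(traj$coords[idx, , fr], length(idx), 3)
    hit <- mi_d2_matrix(X, X, traj$box[fr, ]) <= cutoff^2
    byres <- rowsum(hit + 0, grp)
    pairhits <- rowsum(t(byres), grp)  # residue x residue atom-pair counts
    dimnames(pairhits) <- NULL
    f <- f + (pairhits > 0)
  }
  f <- f / nf
  diag(f) <- NA_real_
  f
}

brute_cosolvent_contacts_vec <- function(traj, cutoff = 4.5) {
  top <- traj$topology
  pidx <- which(top$molecule_kind == "protein" & top$heavy)
  cidx <- which(top$molecule_kind == "cosolvent" & top$heavy)
  resids <- sort(unique(top$residue_index[pidx]))
  N <- length(resids)
  if (length(cidx) == 0) return(rep(0, N))
  pgrp <- match(top$residue_index[pidx], resids)
  mols <- sort(unique(top$molecule_id[cidx]))
  cgrp <- match(top$molecule_id[cidx], mols)
  nf <- dim(traj$coords)[3]
  acc <- rep(0, N)
  for (fr in seq_len(nf)) {
    P <- matrix(traj$coords[pidx, , fr], length(pidx), 3)
    C <- matrix(traj$coords[cidx, , fr], length(cidx), 3)
    hit <- mi_d2_matrix(P, C, traj$box[fr, ]) <= cutoff^2
    byres <- rowsum(hit + 0, pgrp)
    bymol <- rowsum(t(byres), cgrp)     # molecule x residue atom-pair counts
    dimnames(bymol) <- NULL
    acc <- acc + colSums(bymol > 0)
  }
  acc / nf
}
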