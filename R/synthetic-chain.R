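# Run code with a private RNG state so generators are pure in (spec, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Residue-type weights loosely matching the composition of a low-complexity
# SYGQ-rich domain, so residue-type binning is exercised with realistic
# proportions. Labels are what matters downstream, not chemistry.
lc_composition <- c(S = 0.26, G = 0.17, Q = 0.21, Y = 0.15,
                    T = 0.08, P = 0.07, A = 0.04, N = 0.02)

random_unit_vectors <- function(n) {
  u <- matrix(rnorm(n * 3), ncol = 3)
  u / sqrt(rowSums(u^2))
}

#' Specification for a synthetic disordered-chain ensemble
#'
#' Parameters of a pseudo-atom polymer ensemble standing in for a
#' single-chain simulation of a disordered low-complexity domain. At
#' `confinement_strength = 0` frames are i.i.d. freely jointed chains with
#' exactly `bond_length` between consecutive backbone pseudo-atoms; positive
#' values bias each step toward the running centre of mass, producing more
#' compact, contact-rich ensembles.
#'
#' @param n_residues number of residues (>= 2).
#' @param bond_length backbone step length in Angstrom (> 0).
#' @param sidechain_atoms_per_residue pseudo-heavy-atoms per sidechain, each
#'   offset from the backbone atom by at most `bond_length`.
#' @param confinement_strength dimensionless >= 0 compaction bias.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed.
#' @param box_edge optional cubic box edge (Angstrom); by default a box
#'   comfortably containing every frame is chosen.
#' @return A list of class `"chain_spec"`.
#' @export
chain_spec <- function(n_residues, bond_length = 3.8,
                       sidechain_atoms_per_residue = 2L,
                       confinement_strength = 0, n_frames = 1L,
                       seed = 0L, box_edge = NULL) {
  if (!is.numeric(n_residues) || n_residues < 2)
    stop("invalid ChainSpec: n_residues must be >= 2")
  if (!is.numeric(bond_length) || bond_length <= 0)
    stop("invalid ChainSpec: bond_length must be > 0")
  if (sidechain_atoms_per_residue < 0)
    stop("invalid ChainSpec: sidechain_atoms_per_residue must be >= 0")
  if (confinement_strength < 0)
    stop("invalid ChainSpec: confinement_strength must be >= 0")
  if (n_frames < 1)
    stop("invalid ChainSpec: n_frames must be >= 1")
  if (!is.null(box_edge) && box_edge <= 0)
    stop("invalid ChainSpec: box_edge must be > 0")
  structure(list(n_residues = as.integer(n_residues),
                 bond_length = bond_length,
                 sidechain_atoms_per_residue =
                   as.integer(sidechain_atoms_per_residue),
                 confinement_strength = confinement_strength,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed), box_edge = box_edge),
            class = "chain_spec")
}

#' Generate a synthetic disordered-chain ensemble
#'
#' Builds a [trajectory()] containing one protein molecule. Each residue
#' carries one backbone pseudo-heavy-atom on the chain walk plus
#' `sidechain_atoms_per_residue` pseudo-heavy-atoms offset by at most the
#' bond length. Consecutive backbone atoms are exactly `bond_length` apart
#' in every frame. Residue types are drawn from an S/G/Q/Y-rich
#' low-complexity composition. Deterministic under a fixed seed.
#'
#' @param spec a [chain_spec()].
#' @return A [trajectory()] with `n_residues * (1 + k)` atoms per frame.
#' @examples
#' traj <- gen_chain_ensemble(chain_spec(10, n_frames = 5))
#' @export
gen_chain_ensemble <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  N <- spec$n_residues; b <- spec$bond_length
  k <- spec$sidechain_atoms_per_residue
  F <- spec$n_frames; conf <- spec$confinement_strength

  with_seed(spec$seed, {
    types <- sample(names(lc_composition), N, replace = TRUE,
                    prob = lc_composition)

    # backbone walk: (N x 3 x F)
    bb <- array(0, dim = c(N, 3, F))
    if (conf == 0) {
      u <- random_unit_vectors((N - 1L) * F) * b
      for (d in 1:3) {
        s <- matrix(u[, d], nrow = N - 1L, ncol = F)
        bb[2:N, d, ] <- apply(s, 2, cumsum)
      }
    } else {
      cur <- matrix(0, F, 3)
      csum <- matrix(0, F, 3)
      for (i in 2:N) {
        centroid <- csum / (i - 1)
        dirc <- centroid - cur
        nrm <- sqrt(rowSums(dirc^2))
        ok <- nrm > 0
        dirc[ok, ] <- dirc[ok, ] / nrm[ok]
        dirc[!ok, ] <- 0
        v <- random_unit_vectors(F) + conf * dirc
        v <- v / sqrt(rowSums(v^2))
        cur <- cur + v * b
        bb[i, , ] <- t(cur)
        csum <- csum + cur
      }
    }

    # sidechain offsets: uniform in a ball of radius b around the backbone
    natoms <- N * (1L + k)
    coords <- array(0, dim = c(natoms, 3, F))
    bb_rows <- (seq_len(N) - 1L) * (1L + k) + 1L
    coords[bb_rows, , ] <- bb
    if (k > 0) {
      nsc <- N * k * F
      off <- random_unit_vectors(nsc) * (b * runif(nsc)^(1 / 3))
      sc_rows <- rep(bb_rows, each = k) + seq_len(k)  # per residue: S1..Sk
      # reshape (row r = (f-1)*N*k + a) into an (N*k, 3, F) array
      off_arr <- array(0, dim = c(N * k, 3, F))
      for (d in 1:3) off_arr[, d, ] <- matrix(off[, d], N * k, F)
      coords[sc_rows, , ] <-
        coords[rep(bb_rows, each = k), , , drop = FALSE] + off_arr
    }

    # centre each frame, then place in a cubic box
    for (f in seq_len(F)) {
      frame <- coords[, , f]
      coords[, , f] <- sweep(frame, 2, colMeans(frame))
    }
    edge <- spec$box_edge
    if (is.null(edge)) edge <- max(2 * max(abs(coords)) + 10, 30)
    coords <- coords + edge / 2

    topology <- data.frame(
      residue_index = rep(seq_len(N), each = 1L + k),
      residue_type = rep(types, each = 1L + k),
      atom_name = rep(c("BB", if (k > 0) paste0("S", seq_len(k))), times = N),
      element = "C",
      mass = rep(c(56.0, rep(30.0, k)), times = N),
      heavy = TRUE,
      sidechain = rep(c(FALSE, rep(TRUE, k)), times = N),
      molecule_id = 1L,
      molecule_kind = "protein",
      stringsAsFactors = FALSE)

    out <- trajectory(topology, coords, c(edge, edge, edge))
    attr(out, "spec") <- spec
    out
  })
}
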