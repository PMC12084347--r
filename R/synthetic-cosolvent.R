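#' Specification for a diol-like cosolvent box
#'
#' Parameters for filling a cubic periodic box with rigid small molecules of
#' `heavy_atoms_per_molecule` pseudo-heavy-atoms (8 for a hexanediol-like
#' molecule: 6 C + 2 O). At `adsorption_bias = 0` molecule centres are
#' uniform over the box; for positive bias a fraction
#' `adsorption_bias / (1 + adsorption_bias)` of the molecules is re-placed
#' within `adsorption_shell` of a randomly chosen protein heavy atom,
#' emulating surface-adsorbing diols.
#'
#' @param n_molecules number of cosolvent molecules (>= 0).
#' @param heavy_atoms_per_molecule heavy atoms per molecule (>= 1).
#' @param box_edge cubic box edge, Angstrom; must exceed twice the
#'   adsorption shell.
#' @param adsorption_bias dimensionless >= 0.
#' @param adsorption_shell shell radius in Angstrom.
#' @param seed RNG seed.
#' @return A list of class `"cosolvent_spec"`.
#' @export
cosolvent_spec <- function(n_molecules, heavy_atoms_per_molecule = 8L,
                           box_edge = 60, adsorption_bias = 0,
                           adsorption_shell = 6, seed = 0L) {
  if (n_molecules < 0) stop("invalid CosolventSpec: n_molecules must be >= 0")
  if (heavy_atoms_per_molecule < 1)
    stop("invalid CosolventSpec: heavy_atoms_per_molecule must be >= 1")
  if (box_edge <= 2 * adsorption_shell)
    stop("invalid CosolventSpec: box_edge must exceed 2 * adsorption_shell")
  if (adsorption_bias < 0)
    stop("invalid CosolventSpec: adsorption_bias must be >= 0")
  structure(list(n_molecules = as.integer(n_molecules),
                 heavy_atoms_per_molecule =
                   as.integer(heavy_atoms_per_molecule),
                 box_edge = box_edge, adsorption_bias = adsorption_bias,
                 adsorption_shell = adsorption_shell,
                 seed = as.integer(seed)),
            class = "cosolvent_spec")
}

# Apply unit quaternions (n x 4) to one 3-vector, vectorised over rows.
rotate_by_quaternions <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # t = 2 * cross(q_vec, v); v' = v + w*t + cross(q_vec, t)
  tx <- 2 * (y * v[3] - z * v[2])
  ty <- 2 * (z * v[1] - x * v[3])
  tz <- 2 * (x * v[2] - y * v[1])
  cbind(v[1] + w * tx + (y * tz - z * ty),
        v[2] + w * ty + (z * tx - x * tz),
        v[3] + w * tz + (x * ty - y * tx))
}

# Rigid template: heavy-atom zigzag chain centred at its own COM.
cosolvent_template <- function(m) {
  tpl <- cbind(1.25 * (seq_len(m) - 1), 0.5 * (seq_len(m) %% 2), 0)
  sweep(tpl, 2, colMeans(tpl))
}

#' Add diffusing cosolvent molecules to a chain trajectory
#'
#' Re-centres the protein chain in a cubic box of edge `spec$box_edge` and
#' appends `n_molecules` rigid cosolvent molecules to every frame, with
#' independent placements per frame (an i.i.d. stand-in for fast-diffusing
#' small molecules). Placement is uniform at `adsorption_bias = 0`; with
#' positive bias a fraction `bias / (1 + bias)` of molecules is placed
#' within `adsorption_shell` of a random protein heavy atom. Each molecule's
#' orientation is an independent uniform random rotation.
#'
#' For an `m`-atom molecule with `m >= 3`, the last two atoms are labelled
#' oxygen (diol hydroxyl-bearing termini) and the rest carbon.
#'
#' @param spec a [cosolvent_spec()].
#' @param chain a protein [trajectory()] from [gen_chain_ensemble()].
#' @return A [trajectory()] with the protein plus cosolvent molecules.
#' @export
gen_cosolvent_box <- function(spec, chain) {
  stopifnot(inherits(spec, "cosolvent_spec"), inherits(chain, "trajectory"))
  L <- spec$box_edge
  n <- spec$n_molecules
  m <- spec$heavy_atoms_per_molecule
  F <- n_frames(chain)
  np <- n_atoms(chain)

  # re-centre the chain COM at the box centre, frame by frame
  pc <- chain$coords
  for (f in seq_len(F)) {
    frame <- pc[, , f]
    pc[, , f] <- sweep(frame, 2, colMeans(frame) - L / 2)
  }
  if (any(pc < 0) || any(pc > L))
    stop("chain atom outside box: increase box_edge")

  prot_heavy <- atom_which(chain, kind = "protein", heavy = TRUE)

  tpl <- cosolvent_template(m)
  f_ads <- spec$adsorption_bias / (1 + spec$adsorption_bias)
  n_ads <- round(f_ads * n)

  co <- if (n > 0) array(0, dim = c(n * m, 3, F)) else
    array(0, dim = c(0, 3, F))
  with_seed(spec$seed, {
    for (f in seq_len(F)) {
      if (n == 0) break
      centers <- matrix(runif(n * 3, 0, L), n, 3)
      if (n_ads > 0) {
        anchors <- pc[sample(prot_heavy, n_ads, replace = TRUE), , f,
                      drop = FALSE][, , 1]
        if (n_ads == 1) anchors <- matrix(anchors, 1, 3)
        dirs <- random_unit_vectors(n_ads)
        centers[seq_len(n_ads), ] <-
          anchors + dirs * runif(n_ads, 0, spec$adsorption_shell)
      }
      q <- matrix(rnorm(n * 4), n, 4)
      q <- q / sqrt(rowSums(q^2))
      for (a in seq_len(m)) {
        rows <- (seq_len(n) - 1L) * m + a
        co[rows, , f] <- centers + rotate_by_quaternions(q, tpl[a, ])
      }
    }
  })

  elements <- if (m >= 3) c(rep("C", m - 2), "O", "O") else rep("C", m)
  masses <- ifelse(elements == "O", 15.999, 12.011)
  names_a <- character(m)
  names_a[elements == "C"] <- paste0("C", seq_len(sum(elements == "C")))
  names_a[elements == "O"] <- paste0("O", seq_len(sum(elements == "O")))

  max_res <- max(chain$topology$residue_index)
  max_mol <- max(chain$topology$molecule_id)
  topology <- chain$topology
  if (n > 0) {
    co_top <- data.frame(
      residue_index = rep(max_res + seq_len(n), each = m),
      residue_type = "HD6",
      atom_name = rep(names_a, times = n),
      element = rep(elements, times = n),
      mass = rep(masses, times = n),
      heavy = TRUE,
      sidechain = FALSE,
      molecule_id = rep(max_mol + seq_len(n), each = m),
      molecule_kind = "cosolvent",
      stringsAsFactors = FALSE)
    topology <- rbind(topology, co_top)
  }
  coords <- array(0, dim = c(np + n * m, 3, F))
  coords[seq_len(np), , ] <- pc
  if (n > 0) coords[np + seq_len(n * m), , ] <- co

  out <- trajectory(topology, coords, c(L, L, L),
                    replica_id = chain$replica_id)
  attr(out, "spec") <- spec
  out
}
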