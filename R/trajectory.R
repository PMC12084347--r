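#' Trajectory container
#'
#' A lightweight in-memory representation of a (possibly multi-frame)
#' molecular system: a shared topology table plus per-frame coordinates and
#' periodic box edges. All lengths are in Angstrom; boxes are orthorhombic
#' (edge vectors along x, y, z).
#'
#' @param topology data frame with one row per atom and columns
#'   `residue_index` (1-based, contiguous within the protein molecule),
#'   `residue_type` (one-letter code for protein residues, a residue name
#'   such as `"HD6"` for cosolvent), `atom_name`, `element`, `mass` (Da),
#'   `heavy` (logical, element != H), `sidechain` (logical),
#'   `molecule_id` (integer), `molecule_kind` (`"protein"`, `"cosolvent"`
#'   or `"other"`).
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param box numeric matrix `n_frames x 3` of box edges (Angstrom), or a
#'   length-3 vector recycled to all frames.
#' @param replica_id integer label used when aggregating replicas.
#'
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, box, replica_id = 1L) {
  required <- c("residue_index", "residue_type", "atom_name", "element",
                "mass", "heavy", "sidechain", "molecule_id", "molecule_kind")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0L)
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("coords atom count does not match topology")
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("box must be an n_frames x 3 matrix of edges")
  if (any(box <= 0)) stop("box edges must be positive")
  prot <- topology$molecule_kind == "protein"
  if (any(prot)) {
    ridx <- sort(unique(topology$residue_index[prot]))
    if (!all(diff(ridx) == 1L))
      stop("protein residue indices must be contiguous")
  }
  structure(list(topology = topology, coords = coords, box = box,
                 replica_id = as.integer(replica_id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, replica %d\n",
              n_atoms(x), n_frames(x), x$replica_id))
  kinds <- table(x$topology$molecule_kind)
  cat("  atoms by kind:",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  cat(sprintf("  box (frame 1): %.1f x %.1f x %.1f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory` object.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

# Indices of protein heavy atoms, optionally restricted.
atom_which <- function(traj, kind = NULL, heavy = FALSE, sidechain = NA,
                       residue_type = NULL) {
  top <- traj$topology
  sel <- rep(TRUE, nrow(top))
  if (!is.null(kind)) sel <- sel & top$molecule_kind == kind
  if (heavy) sel <- sel & top$heavy
  if (!is.na(sidechain)) sel <- sel & top$sidechain == sidechain
  if (!is.null(residue_type)) sel <- sel & top$residue_type %in% residue_type
  which(sel)
}

#' Minimum-image distance under periodic boundary conditions
#'
#' Shortest distance between two points given a periodic box. Orthorhombic
#' boxes (length-3 edge vector) use the per-axis wrap; general triclinic
#' boxes (3 x 3 matrix of row box vectors) are handled by searching the 27
#' neighbouring images.
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @param box length-3 vector of orthorhombic edges, or a 3 x 3 matrix whose
#'   rows are the box vectors.
#' @return The minimum-image distance in Angstrom.
#' @examples
#' minimum_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10))  # 1
#' @export
minimum_image_distance <- function(a, b, box) {
  if (is.matrix(box)) {
    if (any(diag(box) <= 0)) stop("box diagonal must be positive")
    d <- b - a
    # reduce into the primary cell first so one image layer suffices
    frac <- solve(t(box), d)
    d0 <- d - as.numeric(t(box) %*% round(frac))
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    imgs <- shifts %*% box
    cand <- sweep(imgs, 2, d0, "+")
    sqrt(min(rowSums(cand^2)))
  } else {
    if (any(box <= 0)) stop("box edges must be positive")
    d <- b - a
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
}

#' Unwrap molecules across periodic boundaries
#'
#' Makes each molecule whole by shifting every atom to the minimum-image
#' position relative to the previous atom of the same molecule (atoms are
#' assumed ordered along the chain, as written by the generators and by
#' standard topologies). Applied by default to the protein before computing
#' intrachain observables.
#'
#' @param traj a [trajectory()].
#' @param kinds molecule kinds to unwrap.
#' @return A `trajectory` with continuous molecules.
#' @export
unwrap_molecules <- function(traj, kinds = "protein") {
  top <- traj$topology
  xyz <- traj$coords
  nf <- n_frames(traj)
  for (mol in unique(top$molecule_id[top$molecule_kind %in% kinds])) {
    idx <- which(top$molecule_id == mol)
    if (length(idx) < 2L) next
    for (f in seq_len(nf)) {
      L <- traj$box[f, ]
      for (k in seq_along(idx)[-1]) {
        d <- xyz[idx[k], , f] - xyz[idx[k - 1L], , f]
        xyz[idx[k], , f] <- xyz[idx[k], , f] - L * round(d / L)
      }
    }
  }
  traj$coords <- xyz
  traj
}

#' Residue-type sequence of the protein molecule
#'
#' One residue-type label per protein residue, in residue order — the form
#' the NMR helpers expect as a sequence.
#'
#' @param traj a [trajectory()].
#' @return Character vector of residue types.
#' @export
sequence_of <- function(traj) {
  top <- traj$topology
  prot <- top$molecule_kind == "protein"
  resids <- sort(unique(top$residue_index[prot]))
  top$residue_type[prot][match(resids, top$residue_index[prot])]
}
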