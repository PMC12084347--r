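# One-letter residue codes get expanded to 3-letter names in PDB output;
# anything else (cosolvent residue names) is written as-is.
one_to_three <- function(x) {
  out <- x
  single <- nchar(x) == 1
  if (any(single)) {
    conv <- vapply(unique(x[single]), function(a)
      tryCatch(bio3d::aa123(a), error = function(e) a), character(1))
    out[single] <- unname(conv[x[single]])
  }
  out
}

#' Write a trajectory as PDB topology plus multi-frame XYZ coordinates
#'
#' The PDB file carries the topology (residue names and numbers, atom
#' names, element column) with frame-1 coordinates; the XYZ file carries
#' every frame in Angstrom, with the box edges recorded on each frame's
#' comment line (`box Lx Ly Lz`).
#'
#' @param traj a [trajectory()].
#' @param pdb_file,xyz_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_trajectory <- function(traj, pdb_file, xyz_file) {
  top <- traj$topology
  bio3d::write.pdb(file = pdb_file,
                   xyz = as.numeric(t(traj$coords[, , 1])),
                   resno = top$residue_index,
                   resid = one_to_three(top$residue_type),
                   eleno = seq_len(nrow(top)),
                   elety = top$atom_name,
                   chain = ifelse(top$molecule_kind == "protein", "A", "B"),
                   elesy = top$element)
  con <- file(xyz_file, "w")
  on.exit(close(con))
  na <- n_atoms(traj)
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(na),
                 sprintf("frame %d box %.6f %.6f %.6f", f,
                         traj$box[f, 1], traj$box[f, 2], traj$box[f, 3])),
               con)
    writeLines(sprintf("%s %.6f %.6f %.6f", top$element,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(c(pdb_file, xyz_file))
}

read_xyz_frames <- function(xyz_file, n_atoms_expected) {
  lines <- readLines(xyz_file)
  per <- n_atoms_expected + 2L
  nf <- length(lines) %/% per
  if (nf * per != length(lines))
    stop("XYZ file length is not a whole number of frames")
  coords <- array(0, dim = c(n_atoms_expected, 3, nf))
  box <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * per
    hdr <- strsplit(trimws(lines[off + 2L]), "\\s+")[[1]]
    bpos <- which(hdr == "box")
    if (length(bpos) != 1L || bpos + 3 > length(hdr))
      stop("XYZ comment line lacks 'box Lx Ly Lz'")
    box[f, ] <- as.numeric(hdr[bpos + 1:3])
    flds <- strsplit(trimws(lines[off + 2L + seq_len(n_atoms_expected)]),
                     "\\s+")
    coords[, , f] <- t(vapply(flds, function(x) as.numeric(x[2:4]),
                              numeric(3)))
  }
  list(coords = coords, box = box)
}

#' Read a trajectory from a PDB topology and XYZ or DCD coordinates
#'
#' The PDB (read with \pkg{bio3d}) provides the topology; heavy atoms are
#' those whose element is not hydrogen, cosolvent molecules are recognised
#' by residue name, and each cosolvent residue is treated as one molecule.
#' Coordinates come from a multi-frame XYZ file as written by
#' [write_trajectory()] (box on the comment line) or from a DCD file read
#' with \pkg{bio3d} (pass `box` explicitly then). XTC is not supported;
#' convert to DCD or XYZ first.
#'
#' @param pdb_file topology path.
#' @param traj_file optional XYZ (`.xyz`) or DCD (`.dcd`) coordinates; by
#'   default only the PDB frame is used.
#' @param box optional length-3 box edges, required for DCD input and used
#'   as an override otherwise.
#' @param cosolvent_residues residue names treated as cosolvent.
#' @param replica_id replica label.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(pdb_file, traj_file = NULL, box = NULL,
                            cosolvent_residues = c("HD6", "HD2", "HEX"),
                            replica_id = 1L) {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- substr(trimws(at$elety), 1, 1)
  is_cos <- at$resid %in% cosolvent_residues
  rtype <- at$resid
  conv <- vapply(unique(at$resid), function(a)
    tryCatch(suppressWarnings(bio3d::aa321(a)),
             error = function(e) NA_character_), character(1))
  aa1 <- unname(conv[at$resid])
  ok1 <- !is_cos & !is.na(aa1) & aa1 != "NA"
  rtype[ok1] <- aa1[ok1]
  backbone_names <- c("N", "CA", "C", "O", "BB", "OXT", "H", "HA")
  mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)
  mass <- unname(mass_table[element])
  mass[is.na(mass)] <- 12.011
  # pseudo-atom topologies written by this package carry their own masses
  if (all(at$elety %in% c("BB", paste0("S", 1:9)))) {
    mass[at$elety == "BB"] <- 56.0
    mass[at$elety != "BB"] <- 30.0
  }
  molecule_id <- ifelse(is_cos, at$resno + max(at$resno[!is_cos], 0), 1L)
  topology <- data.frame(
    residue_index = at$resno,
    residue_type = rtype,
    atom_name = trimws(at$elety),
    element = element,
    mass = mass,
    heavy = toupper(element) != "H",
    sidechain = !is_cos & !(trimws(at$elety) %in% backbone_names),
    molecule_id = molecule_id,
    molecule_kind = ifelse(is_cos, "cosolvent", "protein"),
    stringsAsFactors = FALSE)

  if (is.null(traj_file)) {
    coords <- array(0, dim = c(nrow(at), 3, 1))
    coords[, , 1] <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    if (is.null(box)) {
      span <- apply(coords[, , 1], 2, function(v) diff(range(v)))
      box <- rep(max(span) + 20, 3)
    }
    return(trajectory(topology, coords, box, replica_id))
  }
  if (grepl("\\.xyz$", traj_file, ignore.case = TRUE)) {
    fr <- read_xyz_frames(traj_file, nrow(at))
    bx <- if (is.null(box)) fr$box else
      matrix(box, nrow(fr$box), 3, byrow = TRUE)
    trajectory(topology, fr$coords, bx, replica_id)
  } else if (grepl("\\.dcd$", traj_file, ignore.case = TRUE)) {
    if (is.null(box)) stop("DCD input requires an explicit box")
    xyz <- bio3d::read.dcd(traj_file, verbose = FALSE)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nrow(at), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    trajectory(topology, coords, box, replica_id)
  } else {
    stop("unsupported trajectory format (use .xyz or .dcd); ",
         "XTC is not supported")
  }
}

#' Read and write peak-list CSV files
#'
#' Columns: `residue_index`, `residue_type`, `nucleus`, `shift_ppm`,
#' `intensity`, `condition`.
#'
#' @param peaks a peak-list data frame.
#' @param file path.
#' @return `read_peak_list` returns the data frame; `write_peak_list`
#'   returns the path invisibly.
#' @export
write_peak_list <- function(peaks, file) {
  write.csv(peaks, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}

#' Read a simple Sparky-style peak list
#'
#' Parses lines like `G156N-H 110.93 8.45 12345` into 15N and 1H entries
#' of the standard peak-list layout. Lines that do not match the
#' assignment pattern (headers, unassigned peaks) are skipped.
#'
#' @param file path to the text list.
#' @param condition condition label attached to the peaks.
#' @return A peak-list data frame.
#' @export
read_sparky_peaks <- function(file, condition = NA_character_) {
  lines <- readLines(file)
  pat <- "^\\s*([A-Z])(\\d+)N-H\\s+([-0-9.]+)\\s+([-0-9.]+)(\\s+([-0-9.eE+]+))?"
  m <- regmatches(lines, regexec(pat, lines))
  keep <- vapply(m, length, integer(1)) > 0
  m <- m[keep]
  if (length(m) == 0) stop("no assigned peaks found in ", file)
  get <- function(i) vapply(m, `[`, character(1), i)
  inten <- suppressWarnings(as.numeric(get(7)))
  inten[is.na(inten)] <- 1
  data.frame(
    residue_index = rep(as.integer(get(3)), 2),
    residue_type = rep(get(2), 2),
    nucleus = rep(c("15N", "1H"), each = length(m)),
    shift_ppm = c(as.numeric(get(4)), as.numeric(get(5))),
    intensity = rep(inten, 2),
    condition = condition,
    stringsAsFactors = FALSE)
}

#' Read and write melting curves as CSV
#'
#' Columns `temperature_c`, `mre`.
#'
#' @param curve a melting-curve data frame.
#' @param file path.
#' @export
write_melting_curve <- function(curve, file) {
  write.csv(as.data.frame(curve)[, c("temperature_c", "mre")], file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname write_melting_curve
#' @export
read_melting_curve <- function(file) {
  out <- read.csv(file)
  class(out) <- c("melting_curve", "data.frame")
  out
}

#' Write and read 16-bit grayscale TIFF images
#'
#' Grey levels are stored on the 0..65535 scale used by the synthetic
#' droplet generator.
#'
#' @param image numeric matrix of grey levels in 0..65535.
#' @param file path.
#' @export
write_droplet_tiff <- function(image, file) {
  tiff::writeTIFF(pmin(pmax(image / 65535, 0), 1), file,
                  bits.per.sample = 16L)
  invisible(file)
}

#' @rdname write_droplet_tiff
#' @export
read_droplet_tiff <- function(file) {
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Write a ground-truth table as JSON
#'
#' @param truth any list or data frame of ground-truth values.
#' @param file path.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
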