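# Extract one frame of coordinates for an index set as an n x 3 matrix,
# robust to single-atom selections.
frame_coords <- function(coords, idx, f) {
  matrix(coords[idx, , f], length(idx), 3)
}

# Squared pairwise distances between rows of X (n x 3).
pairwise_sq <- function(X) {
  G <- tcrossprod(X)
  dg <- diag(G)
  d2 <- outer(dg, dg, "+") - 2 * G
  d2[d2 < 0] <- 0
  d2
}

as_replica_list <- function(traj) {
  if (inherits(traj, "trajectory")) list(traj)
  else if (is.list(traj) && all(vapply(traj, inherits, TRUE, "trajectory")))
    traj
  else stop("expected a trajectory or a list of trajectories")
}

check_cutoff <- function(traj, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (cutoff > min(traj$box) / 2)
    stop("cutoff exceeds half the smallest box edge; ",
         "minimum-image distances would be ambiguous")
}

#' Radius of gyration distribution
#'
#' Per-frame radius of gyration
#' \eqn{R_g = \sqrt{\sum_k m_k |x_k - x_{com}|^2 / \sum_k m_k}} over a
#' selection of atoms (protein heavy atoms by default). For a list of
#' replica trajectories, the replica means are combined with
#' [replica_sem()].
#'
#' @param traj a [trajectory()] or a list of replica trajectories.
#' @param selection integer or logical atom index vector; default all
#'   protein heavy atoms.
#' @param mass_weighted if `FALSE`, all masses are taken as 1.
#' @return A list of class `"rg_distribution"`: `per_frame` (list per
#'   replica), `mean`, `sem` (NA for a single replica), `n_replicas`.
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = TRUE) {
  reps <- as_replica_list(traj)
  per_frame <- lapply(reps, function(tr) {
    sel <- selection
    if (is.null(sel)) sel <- atom_which(tr, kind = "protein", heavy = TRUE)
    if (is.logical(sel)) sel <- which(sel)
    if (length(sel) == 0L) stop("empty atom selection")
    m <- if (mass_weighted) tr$topology$mass[sel] else rep(1, length(sel))
    if (any(!is.finite(m))) stop("selection has missing masses")
    M <- sum(m)
    nf <- n_frames(tr)
    rg <- numeric(nf)
    for (f in seq_len(nf)) {
      X <- frame_coords(tr$coords, sel, f)
      if (length(sel) == 1L) { rg[f] <- 0; next }
      com <- colSums(X * m) / M
      rg[f] <- sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / M)
    }
    rg
  })
  means <- vapply(per_frame, mean, numeric(1))
  agg <- replica_sem(as.list(means))
  structure(list(per_frame = per_frame, mean = agg$mean, sem = agg$sem,
                 n_replicas = length(reps)),
            class = "rg_distribution")
}

#' Mean intrachain distances and separation profile
#'
#' Computes the residue-residue mean distance matrix \eqn{\langle R_{ij}
#' \rangle} (and mean squared distances) over frames, using either the
#' backbone site of each residue or the residue heavy-atom centre of mass,
#' and the separation profile r(s): the average over all pairs with
#' `|i - j| = s`. With several replicas, the profile carries the standard
#' error of the mean across replicas; for a single replica the SEM is
#' reported as `NA` (not zero).
#'
#' @param traj a [trajectory()] or list of replica trajectories.
#' @param site `"backbone"` (default) or `"com"` (residue heavy-atom COM).
#' @return A list of class `"rij_profile"`: `mean`, `mean_sq` (N x N
#'   matrices, diagonal `NA`), `profile` (data frame with columns
#'   `separation`, `r_mean`, `r_sem`, `r_sq_mean`, `r_sq_sem`, `n_pairs`)
#'   and `per_replica` profiles.
#' @export
intrachain_distances <- function(traj, site = c("backbone", "com")) {
  site <- match.arg(site)
  reps <- as_replica_list(traj)

  one <- function(tr) {
    top <- tr$topology
    prot <- top$molecule_kind == "protein"
    resids <- sort(unique(top$residue_index[prot]))
    N <- length(resids)
    if (N < 2L) stop("need at least 2 protein residues")
    nf <- n_frames(tr)
    sum_d <- matrix(0, N, N)
    sum_d2 <- matrix(0, N, N)
    if (site == "backbone") {
      idx <- which(prot & !top$sidechain & top$heavy)
      if (length(idx) != N) stop("expected one backbone site per residue")
      ord <- order(top$residue_index[idx])
      idx <- idx[ord]
      for (f in seq_len(nf)) {
        d2 <- pairwise_sq(frame_coords(tr$coords, idx, f))
        sum_d2 <- sum_d2 + d2
        sum_d <- sum_d + sqrt(d2)
      }
    } else {
      hidx <- which(prot & top$heavy)
      ri <- factor(match(top$residue_index[hidx], resids),
                   levels = seq_len(N))
      m <- top$mass[hidx]
      M <- as.numeric(tapply(m, ri, sum))
      for (f in seq_len(nf)) {
        X <- frame_coords(tr$coords, hidx, f)
        com <- cbind(tapply(X[, 1] * m, ri, sum),
                     tapply(X[, 2] * m, ri, sum),
                     tapply(X[, 3] * m, ri, sum)) / M
        dimnames(com) <- NULL
        d2 <- pairwise_sq(com)
        sum_d2 <- sum_d2 + d2
        sum_d <- sum_d + sqrt(d2)
      }
    }
    mean_d <- sum_d / nf
    mean_d2 <- sum_d2 / nf
    diag(mean_d) <- NA_real_
    diag(mean_d2) <- NA_real_
    sep <- abs(outer(seq_len(N), seq_len(N), "-"))
    ut <- upper.tri(mean_d)
    prof <- data.frame(
      separation = sort(unique(sep[ut])),
      r_mean = as.numeric(tapply(mean_d[ut], sep[ut], mean)),
      r_sq_mean = as.numeric(tapply(mean_d2[ut], sep[ut], mean)),
      n_pairs = as.numeric(table(sep[ut])))
    list(mean = mean_d, mean_sq = mean_d2, profile = prof)
  }

  rr <- lapply(reps, one)
  prof <- rr[[1]]$profile
  rmat <- vapply(rr, function(x) x$profile$r_mean, numeric(nrow(prof)))
  r2mat <- vapply(rr, function(x) x$profile$r_sq_mean, numeric(nrow(prof)))
  rmat <- matrix(rmat, nrow = nrow(prof))
  r2mat <- matrix(r2mat, nrow = nrow(prof))
  n <- length(reps)
  prof$r_mean <- rowMeans(rmat)
  prof$r_sq_mean <- rowMeans(r2mat)
  prof$r_sem <- if (n > 1) apply(rmat, 1, sd) / sqrt(n) else NA_real_
  prof$r_sq_sem <- if (n > 1) apply(r2mat, 1, sd) / sqrt(n) else NA_real_
  mean_all <- Reduce(`+`, lapply(rr, `[[`, "mean")) / n
  mean_sq_all <- Reduce(`+`, lapply(rr, `[[`, "mean_sq")) / n
  structure(list(mean = mean_all, mean_sq = mean_sq_all, profile = prof,
                 per_replica = lapply(rr, `[[`, "profile"),
                 site = site, n_replicas = n),
            class = "rij_profile")
}

#' Residue-residue contact frequency map
#'
#' A contact between residues i and j is formed in a frame when any heavy
#' atom of i lies within `cutoff` (inclusive) of any heavy atom of j under
#' the minimum-image convention. The map holds the fraction of frames with
#' a contact, computed with a periodic cell-list neighbour search; the
#' diagonal is masked.
#'
#' @param traj a [trajectory()] containing a protein molecule.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param unwrap make the protein whole across periodic boundaries first.
#' @return A list of class `"contact_map"`: `frequency` (N x N symmetric
#'   matrix in `[0, 1]`, diagonal `NA`), `n_residues`, `frame_count`,
#'   `cutoff`.
#' @export
residue_contact_map <- function(traj, cutoff = 4.5, unwrap = TRUE) {
  check_cutoff(traj, cutoff)
  if (unwrap) traj <- unwrap_molecules(traj)
  top <- traj$topology
  idx <- atom_which(traj, kind = "protein", heavy = TRUE)
  if (length(idx) == 0L) stop("no protein heavy atoms present")
  resids <- sort(unique(top$residue_index[idx]))
  N <- length(resids)
  grp <- match(top$residue_index[idx], resids)
  co <- traj$coords[idx, , , drop = FALSE]
  counts <- contact_counts_cpp(co, co, grp, grp, N, N, traj$box, cutoff,
                               binary = TRUE, symmetric = TRUE)
  f <- (counts + t(counts)) / n_frames(traj)
  diag(f) <- NA_real_
  structure(list(frequency = f, n_residues = N,
                 frame_count = n_frames(traj), cutoff = cutoff),
            class = "contact_map")
}

#' Mean contact frequency binned by sequence separation
#'
#' Averages contact frequencies over residue pairs whose separation
#' `|i - j|` falls within each bin. Long-range bins (separation above 100)
#' highlight the chain-compaction contacts most sensitive to cosolvents.
#'
#' @param map a [residue_contact_map()] result.
#' @param bins list of `c(lo, hi)` separation ranges (inclusive,
#'   non-overlapping, `hi` may be `Inf`).
#' @return A data frame with columns `lo`, `hi`, `mean_contact`, `n_pairs`,
#'   `empty`; bins containing no pairs are flagged empty with `NA` mean.
#' @export
contacts_by_separation <- function(map,
                                   bins = list(c(1, 10), c(11, 25),
                                               c(26, 50), c(51, 100),
                                               c(101, Inf))) {
  stopifnot(inherits(map, "contact_map"))
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(lo > hi)) stop("bins must have lo <= hi")
  if (any(lo < 1)) stop("bins must lie within [1, N - 1]")
  ord <- order(lo)
  if (any(lo[ord][-1] <= hi[ord][-length(ord)]))
    stop("bins must be non-overlapping")
  N <- map$n_residues
  sep <- abs(outer(seq_len(N), seq_len(N), "-"))
  ut <- upper.tri(sep)
  s <- sep[ut]; fv <- map$frequency[ut]
  res <- data.frame(lo = lo, hi = hi, mean_contact = NA_real_,
                    n_pairs = 0L, empty = TRUE)
  for (i in seq_along(bins)) {
    in_bin <- s >= lo[i] & s <= hi[i]
    res$n_pairs[i] <- sum(in_bin)
    if (res$n_pairs[i] > 0) {
      res$mean_contact[i] <- mean(fv[in_bin])
      res$empty[i] <- FALSE
    }
  }
  res
}

#' Per-residue cosolvent contact profile
#'
#' For each frame and residue, counts the cosolvent molecules having any
#' heavy atom within `cutoff` of any heavy atom of the residue, then
#' averages over frames. Results are also binned by residue type (mean, sd
#' and n over the residues of each type), the representation used to ask
#' which residue chemistries recruit the diol.
#'
#' @param traj a [trajectory()] with protein and (possibly zero) cosolvent.
#' @param cutoff heavy-atom cutoff, Angstrom.
#' @return A list of class `"cosolvent_profile"`: `per_residue` (data frame
#'   `residue_index`, `residue_type`, `contacts`), `by_type` (data frame
#'   `residue_type`, `mean`, `sd`, `n`), `cutoff`, `frame_count`.
#' @export
cosolvent_contacts <- function(traj, cutoff = 4.5) {
  check_cutoff(traj, cutoff)
  top <- traj$topology
  pidx <- atom_which(traj, kind = "protein", heavy = TRUE)
  resids <- sort(unique(top$residue_index[pidx]))
  N <- length(resids)
  cidx <- atom_which(traj, kind = "cosolvent", heavy = TRUE)
  nf <- n_frames(traj)
  if (length(cidx) == 0L) {
    per_res <- rep(0, N)
  } else {
    mols <- sort(unique(top$molecule_id[cidx]))
    M <- length(mols)
    counts <- contact_counts_cpp(
      traj$coords[pidx, , , drop = FALSE],
      traj$coords[cidx, , , drop = FALSE],
      match(top$residue_index[pidx], resids),
      match(top$molecule_id[cidx], mols),
      N, M, traj$box, cutoff, binary = TRUE, symmetric = FALSE)
    per_res <- rowSums(counts) / nf
  }
  rtype <- top$residue_type[pidx][match(resids, top$residue_index[pidx])]
  per_residue <- data.frame(residue_index = resids, residue_type = rtype,
                            contacts = per_res, stringsAsFactors = FALSE)
  by_type <- do.call(rbind, lapply(split(per_residue, per_residue$residue_type),
                                   function(d) data.frame(
    residue_type = d$residue_type[1], mean = mean(d$contacts),
    sd = if (nrow(d) > 1) sd(d$contacts) else NA_real_, n = nrow(d),
    stringsAsFactors = FALSE)))
  rownames(by_type) <- NULL
  structure(list(per_residue = per_residue, by_type = by_type,
                 cutoff = cutoff, frame_count = nf),
            class = "cosolvent_profile")
}

#' Atomistic sidechain-cosolvent contact map
#'
#' Mean number of contacts per frame and per residue instance between each
#' named sidechain heavy atom of a residue type and each named cosolvent
#' heavy atom, with row and column marginal sums. Resolves which parts of a
#' sidechain and which end of the diol drive the interaction.
#'
#' @param traj a [trajectory()].
#' @param residue_type residue-type label that must be present in the
#'   protein.
#' @param cutoff heavy-atom cutoff, Angstrom.
#' @return A list of class `"atom_contact_map"`: `matrix` (sidechain atom x
#'   cosolvent atom), `row_marginal`, `col_marginal`, `n_instances`,
#'   `frame_count`, `cutoff`.
#' @export
atomistic_contact_map <- function(traj, residue_type, cutoff = 4.5) {
  check_cutoff(traj, cutoff)
  top <- traj$topology
  avail <- unique(top$residue_type[top$molecule_kind == "protein"])
  if (!residue_type %in% avail)
    stop("residue type '", residue_type, "' absent; available: ",
         paste(sort(avail), collapse = ", "))
  aidx <- atom_which(traj, kind = "protein", heavy = TRUE, sidechain = TRUE,
                     residue_type = residue_type)
  if (length(aidx) == 0L)
    stop("residue type '", residue_type, "' has no sidechain heavy atoms")
  row_names <- sort(unique(top$atom_name[aidx]))
  n_inst <- length(unique(top$residue_index[aidx]))
  cidx <- atom_which(traj, kind = "cosolvent", heavy = TRUE)
  nf <- n_frames(traj)
  if (length(cidx) == 0L) {
    mat <- matrix(0, length(row_names), 0,
                  dimnames = list(row_names, NULL))
  } else {
    col_names <- sort(unique(top$atom_name[cidx]))
    counts <- contact_counts_cpp(
      traj$coords[aidx, , , drop = FALSE],
      traj$coords[cidx, , , drop = FALSE],
      match(top$atom_name[aidx], row_names),
      match(top$atom_name[cidx], col_names),
      length(row_names), length(col_names), traj$box, cutoff,
      binary = FALSE, symmetric = FALSE)
    mat <- counts / (nf * n_inst)
    dimnames(mat) <- list(row_names, col_names)
  }
  structure(list(matrix = mat,
                 row_marginal = rowSums(mat),
                 col_marginal = colSums(mat),
                 residue_type = residue_type, n_instances = n_inst,
                 frame_count = nf, cutoff = cutoff),
            class = "atom_contact_map")
}

#' Radial distribution function from sidechain centres of mass
#'
#' g(r) between the heavy-atom centre of mass of every sidechain of a given
#' residue type (reference sites) and all cosolvent heavy atoms (targets),
#' with minimum-image distances in the periodic box:
#' \deqn{g(r) = \frac{\langle n(r) \rangle}{4 \pi r_{mid}^2 \, dr \,
#'   \rho_{bulk}}}
#' where \eqn{\rho_{bulk}} is the target count over the box volume. Values
#' above 1 indicate enrichment of the cosolvent around that sidechain.
#'
#' @param traj a [trajectory()] with cosolvent present.
#' @param residue_type reference residue type (e.g. `"Y"` or `"Q"`).
#' @param r_max maximum radius, Angstrom; at most half the smallest box
#'   edge.
#' @param dr bin width, Angstrom.
#' @return A list of class `"rdf"`: `table` (data frame `r_lo`, `r_mid`,
#'   `r_hi`, `count`, `g`), `bulk_density`, `n_reference_sites`,
#'   `n_targets`, `frame_count`.
#' @export
rdf_sidechain_com <- function(traj, residue_type, r_max = 12, dr = 0.1) {
  if (dr <= 0) stop("dr must be > 0")
  if (r_max <= 0) stop("r_max must be > 0")
  if (r_max > min(traj$box) / 2)
    stop("r_max exceeds half the smallest box edge; ",
         "minimum-image distances would be ambiguous")
  top <- traj$topology
  aidx <- atom_which(traj, kind = "protein", heavy = TRUE, sidechain = TRUE,
                     residue_type = residue_type)
  if (length(aidx) == 0L)
    stop("no sidechain heavy atoms for residue type '", residue_type, "'")
  cidx <- atom_which(traj, kind = "cosolvent", heavy = TRUE)
  if (length(cidx) == 0L) stop("no cosolvent heavy atoms present")
  ref_res <- sort(unique(top$residue_index[aidx]))
  ri <- factor(match(top$residue_index[aidx], ref_res),
               levels = seq_along(ref_res))
  m <- top$mass[aidx]
  M <- as.numeric(tapply(m, ri, sum))
  nf <- n_frames(traj)
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  denom <- numeric(nb)
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- 4 * pi * r_mid^2 * diff(edges)
  for (f in seq_len(nf)) {
    X <- frame_coords(traj$coords, aidx, f)
    com <- cbind(tapply(X[, 1] * m, ri, sum),
                 tapply(X[, 2] * m, ri, sum),
                 tapply(X[, 3] * m, ri, sum)) / M
    dimnames(com) <- NULL
    Tg <- frame_coords(traj$coords, cidx, f)
    L <- traj$box[f, ]
    d2 <- 0
    for (d in 1:3) {
      dd <- outer(com[, d], Tg[, d], "-")
      dd <- dd - L[d] * round(dd / L[d])
      d2 <- d2 + dd * dd
    }
    r <- sqrt(d2)
    vals <- r[r <= r_max]
    b <- findInterval(vals, edges, rightmost.closed = TRUE, left.open = TRUE)
    b[vals == 0] <- 1L  # coincident sites land in the first shell
    b <- b[b >= 1 & b <= nb]
    counts <- counts + tabulate(b, nbins = nb)
    rho_f <- length(cidx) / prod(L)
    denom <- denom + nrow(com) * shell * rho_f
  }
  g <- counts / denom
  structure(list(table = data.frame(r_lo = edges[-length(edges)],
                                    r_mid = r_mid, r_hi = edges[-1],
                                    count = counts, g = g),
                 bulk_density = length(cidx) / mean(apply(traj$box, 1, prod)),
                 n_reference_sites = length(ref_res), n_targets = length(cidx),
                 frame_count = nf),
            class = "rdf")
}

#' Solution mass density
#'
#' \eqn{\rho = \sum_k m_k / V_{box}} converted from Da per cubic Angstrom
#' to g/cm3 (1 Da/A3 = 1.66053906660 g/cm3), per frame, with mean and SEM
#' over frames.
#'
#' @param traj a [trajectory()] whose topology carries masses.
#' @return A list with `per_frame` (g/cm3), `mean`, `sem`.
#' @export
solution_density <- function(traj) {
  m <- traj$topology$mass
  if (any(!is.finite(m))) stop("topology has missing masses")
  total <- sum(m)
  vol <- apply(traj$box, 1, prod)
  rho <- total / vol * 1.66053906660
  list(per_frame = rho, mean = mean(rho),
       sem = if (length(rho) > 1) sd(rho) / sqrt(length(rho)) else NA_real_)
}

#' Mean and standard error over replicas
#'
#' Elementwise mean and SEM (`sd / sqrt(n)`) over a list of equally shaped
#' numeric observables (scalars, vectors or matrices), as used to report
#' simulation observables over independent trajectories. With a single
#' replica the SEM is reported as `NA`, never zero.
#'
#' @param per_replica_values list of numeric objects of identical shape.
#' @return A list with `mean`, `sem` and `n`.
#' @examples
#' replica_sem(list(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
replica_sem <- function(per_replica_values) {
  stopifnot(is.list(per_replica_values), length(per_replica_values) >= 1L)
  shapes <- lapply(per_replica_values, function(x) dim(x) %||% length(x))
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stop("replicas have mismatched shapes")
  n <- length(per_replica_values)
  mn <- Reduce(`+`, per_replica_values) / n
  if (n == 1L) {
    sem <- mn
    sem[] <- NA_real_
  } else {
    ss <- Reduce(`+`, lapply(per_replica_values, function(x) (x - mn)^2))
    sem <- sqrt(ss / (n - 1)) / sqrt(n)
  }
  list(mean = mn, sem = sem, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
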