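test_that("minimum-image distance wraps correctly", {
  expect_equal(minimum_image_distance(c(0, 0, 0), c(9, 0, 0),
                                      c(10, 10, 10)), 1)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3),
                                      c(10, 10, 10)), 0)
  expect_error(minimum_image_distance(c(0, 0, 0), c(1, 1, 1), c(0, 10, 10)),
               "positive")
  # invariance under integer box shifts, orthorhombic and triclinic
  set.seed(101)
  tri <- rbind(c(12, 0, 0), c(3, 11, 0), c(-2, 1, 10))
  for (i in 1:200) {
    a <- runif(3, -20, 20); b <- runif(3, -20, 20)
    L <- runif(3, 8, 15)
    k <- sample(-3:3, 3, replace = TRUE)
    expect_equal(minimum_image_distance(a, b + k * L, L),
                 minimum_image_distance(a, b, L))
    kt <- as.numeric(t(tri) %*% sample(-2:2, 3, replace = TRUE))
    expect_equal(minimum_image_distance(a, b + kt, tri),
                 minimum_image_distance(a, b, tri), tolerance = 1e-10)
  }
})

test_that("radius of gyration matches closed-form cases", {
  one <- toy_traj(rbind(c(0, 0, 0)), 1)
  expect_equal(radius_of_gyration(one)$per_frame[[1]], 0)
  two <- toy_traj(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 2))
  expect_equal(radius_of_gyration(two)$per_frame[[1]], 1)
  # 4 collinear atoms, spacing 1: Rg^2 = b^2 (N^2 - 1) / 12 = 1.25
  four <- toy_traj(cbind(0:3, 0, 0), 1:4)
  expect_equal(radius_of_gyration(four)$per_frame[[1]], sqrt(1.25))
  expect_error(radius_of_gyration(four, selection = integer(0)), "empty")
})

test_that("intrachain distances are exact for a straight chain and carry the
           replica SEM contract", {
  b <- 3.1
  straight <- toy_traj(cbind(b * (0:9), 0, 0), 1:10)
  rij <- intrachain_distances(straight)
  prof <- rij$profile
  expect_equal(prof$r_mean, b * prof$separation)
  expect_true(all(is.na(prof$r_sem)))  # single replica: NA, not zero
  expect_true(all(is.na(diag(rij$mean))))
  expect_error(intrachain_distances(toy_traj(rbind(c(0, 0, 0)), 1)),
               "2 protein residues")
  # backbone sites and residue-COM sites agree when residues are one atom
  rij_com <- intrachain_distances(straight, site = "com")
  expect_equal(rij_com$mean, rij$mean)
})

test_that("FJC ensembles reproduce <Rij^2> = |i-j| b^2 within Monte-Carlo
           error", {
  N <- 40; b <- 3.8; nf <- 800
  tr <- gen_chain_ensemble(chain_spec(N, sidechain_atoms_per_residue = 0,
                                      n_frames = nf, seed = 2))
  prof <- intrachain_distances(tr)$profile
  # independent per-frame recomputation gives the frame-level SEM
  bb <- which(!tr$topology$sidechain)
  sep <- abs(outer(1:N, 1:N, "-")); ut <- upper.tri(sep)
  fsep <- factor(sep[ut], levels = 1:(N - 1))
  M <- matrix(0, N - 1, nf)
  for (f in seq_len(nf)) {
    X <- tr$coords[bb, , f]
    G <- tcrossprod(X); dg <- diag(G)
    d2 <- outer(dg, dg, "+") - 2 * G
    M[, f] <- tapply(d2[ut], fsep, mean)
  }
  expect_equal(prof$r_sq_mean, unname(rowMeans(M)))  # package = oracle
  se <- apply(M, 1, sd) / sqrt(nf)
  # spot-check separations against the closed form at 3 SE each
  for (s in c(1, 5, 10, 20, 39)) {
    expect_lt(abs(prof$r_sq_mean[s] - s * b^2), 3 * se[s] + 1e-9)
  }
})

test_that("cell-list contact map equals the brute-force oracle", {
  for (seed in 1:3) {
    sys <- random_system(n_res = 15, n_mol = 8, n_frames = 4, seed = seed)
    cm <- residue_contact_map(sys, unwrap = FALSE)
    expect_equal(cm$frequency, brute_contact_map(sys), tolerance = 0)
    prof <- cosolvent_contacts(sys)
    expect_equal(prof$per_residue$contacts, brute_cosolvent_contacts(sys),
                 tolerance = 0)
  }
})

test_that("contact cutoff is inclusive and frequency is monotone in cutoff", {
  # two single-atom residues at exactly 4.5, then beyond
  at_45 <- toy_traj(rbind(c(0, 0, 0), c(4.5, 0, 0)), 1:2, box = rep(50, 3))
  expect_equal(residue_contact_map(at_45)$frequency[1, 2], 1)
  at_40 <- toy_traj(rbind(c(0, 0, 0), c(4.0, 0, 0)), 1:2, box = rep(50, 3))
  expect_equal(residue_contact_map(at_40)$frequency[1, 2], 1)
  at_46 <- toy_traj(rbind(c(0, 0, 0), c(4.6, 0, 0)), 1:2, box = rep(50, 3))
  expect_equal(residue_contact_map(at_46)$frequency[1, 2], 0)
  # monotone non-decreasing in cutoff on a random system
  sys <- random_system(seed = 4)
  f1 <- residue_contact_map(sys, cutoff = 3.5)$frequency
  f2 <- residue_contact_map(sys, cutoff = 4.5)$frequency
  f3 <- residue_contact_map(sys, cutoff = 6.0)$frequency
  expect_true(all(f2 - f1 >= 0, na.rm = TRUE))
  expect_true(all(f3 - f2 >= 0, na.rm = TRUE))
  expect_error(residue_contact_map(sys, cutoff = -1), "cutoff")
  expect_error(residue_contact_map(sys, cutoff = 1000), "half")
})

test_that("observables are invariant under global translation and periodic
           wrapping", {
  sys <- random_system(n_res = 12, n_mol = 6, n_frames = 3, seed = 6)
  shifted <- sys
  shifted$coords <- sys$coords + 7.3
  expect_equal(residue_contact_map(shifted, unwrap = FALSE)$frequency,
               residue_contact_map(sys, unwrap = FALSE)$frequency)
  expect_equal(cosolvent_contacts(shifted)$per_residue$contacts,
               cosolvent_contacts(sys)$per_residue$contacts)
  # wrap a whole cosolvent molecule by one box period
  wrapped <- sys
  mol <- which(sys$topology$molecule_kind == "cosolvent" &
                 sys$topology$molecule_id ==
                   max(sys$topology$molecule_id))
  wrapped$coords[mol, 1, ] <- wrapped$coords[mol, 1, ] + sys$box[1, 1]
  expect_equal(cosolvent_contacts(wrapped)$per_residue$contacts,
               cosolvent_contacts(sys)$per_residue$contacts)
})

test_that("separation binning matches a brute-force group-by", {
  sys <- random_system(n_res = 18, n_mol = 0, n_frames = 4, seed = 7)
  cm <- residue_contact_map(sys)
  bins <- list(c(1, 3), c(4, 8), c(9, 17))
  got <- contacts_by_separation(cm, bins)
  N <- cm$n_residues
  for (k in seq_along(bins)) {
    vals <- c()
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      if (abs(i - j) >= bins[[k]][1] && abs(i - j) <= bins[[k]][2])
        vals <- c(vals, cm$frequency[i, j])
    }
    expect_equal(got$mean_contact[k], mean(vals))
    expect_equal(got$n_pairs[k], length(vals))
  }
  # uniform map: every bin mean equals the constant
  cmu <- cm
  cmu$frequency[] <- 0.25
  diag(cmu$frequency) <- NA
  u <- contacts_by_separation(cmu, bins)
  expect_equal(u$mean_contact, rep(0.25, 3))
  # empty bin flagged, not zero
  e <- contacts_by_separation(cm, list(c(1, 5), c(30, 40)))
  expect_true(e$empty[2])
  expect_true(is.na(e$mean_contact[2]))
  expect_error(contacts_by_separation(cm, list(c(1, 5), c(3, 8))),
               "non-overlapping")
})

test_that("single pinned cosolvent molecule registers on exactly one
           residue", {
  # residues on a line, one cosolvent atom 4 A from residue 3 only
  pro <- cbind(10 * (0:4) + 10, 25, 25)
  coords <- rbind(pro, c(30, 21, 25))  # 4.0 A below residue 3
  tr <- toy_traj(coords, c(1:5, 6), box = rep(60, 3),
                 molecule_kind = c(rep("protein", 5), "cosolvent"))
  prof <- cosolvent_contacts(tr)
  expect_equal(prof$per_residue$contacts, c(0, 0, 1, 0, 0))
})

test_that("atomistic contact map counts pairs and its marginals are
           consistent", {
  sys <- random_system(n_res = 15, n_mol = 10, n_frames = 4, seed = 9)
  rt <- sys$topology$residue_type[sys$topology$sidechain][1]
  am <- atomistic_contact_map(sys, rt)
  expect_equal(am$row_marginal, rowSums(am$matrix))
  expect_equal(am$col_marginal, colSums(am$matrix))
  expect_error(atomistic_contact_map(sys, "ZZZ"), "available")
  # no cosolvent: all-zero map
  ch <- gen_chain_ensemble(chain_spec(6, n_frames = 2, seed = 2))
  rt2 <- ch$topology$residue_type[ch$topology$sidechain][1]
  am0 <- atomistic_contact_map(ch, rt2)
  expect_equal(sum(am0$matrix), 0)
  expect_equal(sum(am0$row_marginal), 0)
  # hand-checkable toy: one sidechain atom, one cosolvent atom within cutoff
  coords <- rbind(c(10, 10, 10), c(11, 10, 10), c(13, 10, 10))
  tr <- trajectory(data.frame(
    residue_index = c(1L, 1L, 2L), residue_type = c("Y", "Y", "HD6"),
    atom_name = c("BB", "S1", "C1"), element = "C", mass = 12,
    heavy = TRUE, sidechain = c(FALSE, TRUE, FALSE),
    molecule_id = c(1L, 1L, 2L),
    molecule_kind = c("protein", "protein", "cosolvent")),
    array(coords, dim = c(3, 3, 1)), rep(40, 3))
  am1 <- atomistic_contact_map(tr, "Y")
  expect_equal(unname(am1$matrix["S1", "C1"]), 1)
})

test_that("RDF has ideal-gas normalisation, conserves counts and evaluates
           the single-pair formula", {
  ch <- gen_chain_ensemble(chain_spec(2, sidechain_atoms_per_residue = 1,
                                      n_frames = 40, seed = 1,
                                      box_edge = 30))
  bx <- gen_cosolvent_box(cosolvent_spec(400, heavy_atoms_per_molecule = 1,
                                         box_edge = 30, seed = 2), ch)
  rt <- ch$topology$residue_type[1]
  rdf <- rdf_sidechain_com(bx, rt, r_max = 12, dr = 0.5)
  tb <- rdf$table
  lam <- rdf$n_reference_sites * 40 * 4 * pi * tb$r_mid^2 * 0.5 *
    (400 / 30^3)
  sel <- tb$r_mid > 2
  expect_true(all(abs(tb$g[sel] - 1) < 3.5 / sqrt(lam[sel])))
  # count conservation against direct distance counting
  cidx <- which(bx$topology$molecule_kind == "cosolvent")
  sidx <- which(bx$topology$sidechain)
  total <- 0
  for (f in 1:40) {
    for (s in sidx) {
      for (c in cidx) {
        if (mi_dist(bx$coords[s, , f], bx$coords[c, , f], bx$box[f, ]) <= 12)
          total <- total + 1
      }
    }
  }
  expect_equal(sum(tb$count), total)
  expect_error(rdf_sidechain_com(bx, rt, r_max = 20), "half")

  # single reference, single target at fixed 5 A: g = 1/(4 pi r^2 dr rho)
  coords <- rbind(c(10, 10, 10), c(10, 10, 11), c(15, 10, 11))
  tr <- trajectory(data.frame(
    residue_index = c(1L, 1L, 2L), residue_type = c("Y", "Y", "HD6"),
    atom_name = c("BB", "S1", "C1"), element = "C", mass = 12,
    heavy = TRUE, sidechain = c(FALSE, TRUE, FALSE),
    molecule_id = c(1L, 1L, 2L),
    molecule_kind = c("protein", "protein", "cosolvent")),
    array(coords, dim = c(3, 3, 1)), rep(30, 3))
  rdf1 <- rdf_sidechain_com(tr, "Y", r_max = 8, dr = 0.1)
  hit <- which(rdf1$table$count == 1)
  expect_length(hit, 1)
  r_mid <- rdf1$table$r_mid[hit]
  expect_true(rdf1$table$r_lo[hit] < 5 && rdf1$table$r_hi[hit] >= 5)
  expect_equal(rdf1$table$g[hit],
               1 / (4 * pi * r_mid^2 * 0.1 * (1 / 30^3)))
})

test_that("solution density converts Da per cubic Angstrom correctly", {
  one <- toy_traj(rbind(c(5, 5, 5)), 1, box = c(10, 10, 10), mass = 602.2)
  expect_equal(solution_density(one)$mean, 0.99998, tolerance = 1e-4)
})

test_that("density is linear in mass and zero for an empty box", {
  one <- toy_traj(rbind(c(5, 5, 5)), 1, box = c(10, 10, 10), mass = 100)
  two <- toy_traj(rbind(c(5, 5, 5)), 1, box = c(10, 10, 10), mass = 200)
  expect_equal(solution_density(two)$mean, 2 * solution_density(one)$mean)
})

test_that("replica aggregation reports mean and SEM with the single-replica
           contract", {
  agg <- replica_sem(list(1, 2, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem, 1 / sqrt(3))
  same <- replica_sem(list(c(1, 2), c(1, 2)))
  expect_equal(same$sem, c(0, 0))
  single <- replica_sem(list(matrix(1:4, 2)))
  expect_true(all(is.na(single$sem)))
  expect_error(replica_sem(list(1:2, 1:3)), "shape")
})
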