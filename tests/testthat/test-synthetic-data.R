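test_that("chain generator enforces exact bond lengths and validates input", {
  tr <- gen_chain_ensemble(chain_spec(2, bond_length = 3.8, n_frames = 1,
                                      sidechain_atoms_per_residue = 0))
  d <- sqrt(sum((tr$coords[1, , 1] - tr$coords[2, , 1])^2))
  expect_equal(d, 3.8)

  tr2 <- gen_chain_ensemble(chain_spec(12, bond_length = 2.5, n_frames = 4,
                                       sidechain_atoms_per_residue = 2,
                                       confinement_strength = 0.8, seed = 3))
  bb <- which(!tr2$topology$sidechain)
  for (f in 1:4) {
    steps <- diff(tr2$coords[bb, , f])
    expect_equal(sqrt(rowSums(steps^2)), rep(2.5, 11))
  }
  # sidechain atoms stay within one bond length of their backbone atom
  top <- tr2$topology
  for (f in 1:4) {
    for (i in which(top$sidechain)) {
      host <- bb[top$residue_index[bb] == top$residue_index[i]]
      off <- sqrt(sum((tr2$coords[i, , f] - tr2$coords[host, , f])^2))
      expect_lte(off, 2.5 + 1e-12)
    }
  }

  expect_error(chain_spec(1), "n_residues")
  expect_error(chain_spec(5, bond_length = 0), "bond_length")
  expect_error(chain_spec(5, n_frames = 0), "n_frames")
  expect_error(chain_spec(5, confinement_strength = -1),
               "confinement_strength")
})

test_that("chain generator is bit-reproducible under a fixed seed", {
  s <- chain_spec(30, n_frames = 8, confinement_strength = 0.5, seed = 42)
  expect_identical(gen_chain_ensemble(s)$coords, gen_chain_ensemble(s)$coords)
  s2 <- chain_spec(30, n_frames = 8, confinement_strength = 0.5, seed = 43)
  expect_false(identical(gen_chain_ensemble(s)$coords,
                         gen_chain_ensemble(s2)$coords))
})

test_that("freely jointed chains reproduce the closed-form mean squared
           end-to-end distance", {
  N <- 60; b <- 3.8; nf <- 3000
  tr <- gen_chain_ensemble(chain_spec(N, bond_length = b,
                                      sidechain_atoms_per_residue = 0,
                                      n_frames = nf, seed = 11))
  bb <- which(!tr$topology$sidechain)
  r2 <- vapply(seq_len(nf), function(f)
    sum((tr$coords[bb[N], , f] - tr$coords[bb[1], , f])^2), numeric(1))
  se <- sd(r2) / sqrt(nf)
  expect_lt(abs(mean(r2) - (N - 1) * b^2), 3 * se)
})

test_that("cosolvent placement is uniform at zero bias and respects the box", {
  ch <- gen_chain_ensemble(chain_spec(5, n_frames = 2, seed = 1,
                                      box_edge = 40))
  bx <- gen_cosolvent_box(cosolvent_spec(500, heavy_atoms_per_molecule = 1,
                                         box_edge = 40, seed = 2), ch)
  cidx <- bx$topology$molecule_kind == "cosolvent"
  x <- bx$coords[cidx, 1, 1]
  n <- length(x)
  # fraction in one half-box within binomial 3 sigma
  frac <- mean(x < 20)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  wide <- toy_traj(rbind(c(0, 0, 0), c(30, 0, 0)), 1:2)
  expect_error(gen_cosolvent_box(cosolvent_spec(10, box_edge = 15,
                                                adsorption_shell = 6),
                                 wide),
               "outside box")
  expect_error(cosolvent_spec(10, box_edge = 10, adsorption_shell = 6),
               "box_edge")
  expect_error(cosolvent_spec(-1, box_edge = 40), "n_molecules")
})

test_that("zero cosolvent molecules give an all-zero contact profile", {
  ch <- gen_chain_ensemble(chain_spec(8, n_frames = 2, seed = 5))
  bx <- gen_cosolvent_box(cosolvent_spec(0, box_edge = 60), ch)
  prof <- cosolvent_contacts(bx)
  expect_true(all(prof$per_residue$contacts == 0))
})

test_that("adsorption bias increases protein-cosolvent contacts", {
  ch <- gen_chain_ensemble(chain_spec(15, confinement_strength = 1,
                                      n_frames = 5, seed = 8, box_edge = 50))
  m <- vapply(c(0, 2), function(bias) {
    bx <- gen_cosolvent_box(cosolvent_spec(100, box_edge = 50,
                                           adsorption_bias = bias,
                                           seed = 21), ch)
    mean(cosolvent_contacts(bx)$per_residue$contacts)
  }, numeric(1))
  expect_gt(m[2], m[1])
})

test_that("CSP dataset construction is exact at zero noise", {
  seq_str <- "GSYQGSYQGS"
  pat <- c(0.1, -0.05, 0.3, 0.02, 0.15, -0.2, 0.25, 0.05, 0.12, -0.08)
  ds <- gen_csp_dataset(csp_pattern(pat, c(A = 0.5)), seq_str)
  csp_a <- compute_csp(ds$reference, ds$conditions$A, "15N")
  expect_equal(csp_a$delta_shift, 0.5 * pat)
  # null condition: no perturbation at all
  ds0 <- gen_csp_dataset(csp_pattern(pat, c(Z = 0)), seq_str)
  csp_0 <- compute_csp(ds0$reference, ds0$conditions$Z, "15N")
  expect_equal(csp_0$delta_shift, rep(0, 10))
  expect_error(gen_csp_dataset(csp_pattern(pat, c(A = 1)), "GSY"),
               "length")
})

test_that("melt curve generator matches the two-state limits", {
  sp <- melt_spec(tm_true = 333.15, dh_vant_hoff = 300,
                  folded_baseline = c(-10000, 0),
                  unfolded_baseline = c(-2000, 0), noise_sd = 0)
  cv <- gen_melt_curve(sp)
  # at Tm the signal is the midpoint of the baselines
  at_tm <- approx(cv$temperature_c, cv$mre, xout = 60)$y
  expect_equal(at_tm, -6000, tolerance = 1e-3)
  # far below Tm the folded baseline dominates
  expect_equal(cv$mre[1], -10000, tolerance = 1)
  expect_error(melt_spec(t_range = c(90, 25)), "t_range")
  expect_error(melt_spec(tm_true = 500), "tm_true")
})

test_that("partition generator obeys mass balance and symmetry", {
  # logP 0 and equal volumes: equal concentrations
  pm0 <- gen_partition_measurement(partition_spec(0, 1e-4, 1e-3, 1e-3))
  expect_equal(pm0$truth$c_octanol, pm0$truth$c_water)
  # closed form: 100 umol in 1+1 mL at P = 10
  pm <- gen_partition_measurement(partition_spec(1, 100e-6, 1e-3, 1e-3))
  expect_equal(pm$truth$c_water, 100e-6 / (1e-3 + 10e-3) * 1)
  expect_equal(pm$truth$c_octanol, 10 * pm$truth$c_water)
  # mass conservation, exact at zero noise
  expect_equal(pm$truth$c_water * 1e-3 + pm$truth$c_octanol * 1e-3, 100e-6)
  expect_error(partition_spec(0, -1, 1, 1), "total_amount")
})

test_that("droplet image truth bookkeeping is exact", {
  # no droplets
  sp0 <- image_spec(32, 32)
  expect_equal(gen_droplet_image(sp0)$truth$area_fraction, 0)
  expect_equal(gen_droplet_image(sp0)$truth$count, 0)
  # disks must fit in the frame
  expect_error(image_spec(32, 32, centers = cbind(2, 2), radii = 10),
               "inside the frame")
  # overlapping disks merge into one component in the truth
  sp2 <- image_spec(64, 64, centers = rbind(c(20, 20), c(26, 20), c(50, 50)),
                    radii = c(5, 5, 4))
  t2 <- gen_droplet_image(sp2)$truth
  expect_equal(t2$count, 2)
})
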