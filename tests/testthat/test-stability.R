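test_that("melting fit recovers a noiseless two-state curve", {
  sp <- melt_spec(tm_true = 348.15, dh_vant_hoff = 420, noise_sd = 0)
  fit <- fit_melting_curve(gen_melt_curve(sp))
  expect_true(fit$converged)
  expect_equal(fit$tm_k, 348.15, tolerance = 0.01 / 348.15)
  expect_equal(fit$dh_kj_mol, 420, tolerance = 1e-3)
  # the midpoint cross-check agrees on a clean symmetric transition
  expect_lt(abs(fit$tm_midpoint_c - fit$tm_c), 1)
  expect_false(fit$method_disagreement)
})

test_that("flat melting curves are flagged unconverged, not fabricated", {
  flat <- data.frame(temperature_c = seq(25, 90, length.out = 40),
                     mre = -8000 + rnorm(40, 0, 20))
  fit <- fit_melting_curve(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$tm_c))
  expect_error(fit_melting_curve(flat[1:5, ]), "10 points")
  bad <- flat
  bad$temperature_c[2] <- bad$temperature_c[1]
  expect_error(fit_melting_curve(bad), "strictly increasing")
})

test_that("delta Tm subtracts fits with propagated uncertainty and
           antisymmetry", {
  ref <- fit_melting_curve(gen_melt_curve(melt_spec(tm_true = 345.15,
                                                    noise_sd = 0)))
  cond <- fit_melting_curve(gen_melt_curve(melt_spec(tm_true = 335.15,
                                                     noise_sd = 0)))
  d <- delta_tm(ref, cond)
  expect_equal(d$delta_tm_c, -10, tolerance = 1e-3)
  expect_equal(delta_tm(ref, ref)$delta_tm_c, 0)
  expect_equal(delta_tm(cond, ref)$delta_tm_c, -d$delta_tm_c)
  unc <- ref
  unc$converged <- FALSE
  expect_error(delta_tm(unc, cond), "converged")
})

test_that("Tm shift recovery under realistic noise", {
  # amplitude ~7500 MRE at the transition; SNR 50 -> noise_sd 150
  shifts <- vapply(1:10, function(s) {
    ref <- fit_melting_curve(gen_melt_curve(
      melt_spec(tm_true = 345.15, noise_sd = 150, seed = s)))
    cond <- fit_melting_curve(gen_melt_curve(
      melt_spec(tm_true = 335.15, noise_sd = 150, seed = s + 1000)))
    delta_tm(ref, cond)$delta_tm_c
  }, numeric(1))
  expect_true(all(abs(shifts + 10) < 0.3))
})

test_that("NMR concentration quantification is proton-normalised and
           linear", {
  expect_equal(concentration_from_integral(1, 2, 1, 2, 5e-3), 5e-3)
  expect_equal(concentration_from_integral(6, 12, 1, 2, 1e-3), 1e-3)
  expect_equal(concentration_from_integral(2, 12, 1, 2, 1e-3),
               2 * concentration_from_integral(1, 12, 1, 2, 1e-3))
  expect_error(concentration_from_integral(1, 2, 0, 2, 1e-3),
               "reference integral")
})

test_that("logP is the log ratio of phase concentrations", {
  expect_equal(log_p(1e-3, 1e-3), 0)
  expect_equal(log_p(50e-3, 5e-3), 1)
  expect_error(log_p(0, 1), "concentrations")
  # end-to-end: generate -> quantify -> logP at zero noise is exact
  for (lp in c(-0.5, 0, 1)) {
    pm <- gen_partition_measurement(partition_spec(lp, 1e-4, 1e-3, 1e-3))
    expect_equal(measure_log_p(pm)$logp, lp, tolerance = 1e-12)
  }
})

test_that("Pearson correlation with exclusion is affine-invariant and
           honest about small n", {
  x <- setNames(c(1, 2, 3, 4), letters[1:4])
  y <- 2 * x + 1
  pe <- pearson_with_exclusion(x, y)
  expect_equal(pe$pcc, 1)
  expect_equal(pe$pcc_excluded, pe$pcc)  # empty exclusion reduces to plain
  # collinear points plus constructed outliers
  x2 <- setNames(c(1, 2, 3, 4, 10, -5), c(letters[1:4], "out1", "out2"))
  y2 <- setNames(c(3, 5, 7, 9, -20, 40), names(x2))
  pe2 <- pearson_with_exclusion(x2, y2, exclude = c("out1", "out2"))
  expect_equal(pe2$pcc_excluded, 1)
  expect_lt(pe2$pcc, pe2$pcc_excluded)
  expect_equal(sort(pe2$excluded), c("out1", "out2"))
  # affine invariance
  set.seed(100)
  a <- setNames(rnorm(8), letters[1:8])
  b <- setNames(rnorm(8), letters[1:8])
  p1 <- pearson_with_exclusion(a, b)$pcc
  p2 <- pearson_with_exclusion(3 * a + 2, 0.5 * b - 1)$pcc
  expect_equal(p1, p2)
  # too few pairs after exclusion: flagged unavailable
  pe3 <- pearson_with_exclusion(x, y, exclude = c("a", "b"))
  expect_true(is.na(pe3$pcc_excluded))
  expect_error(pearson_with_exclusion(x[1:2], y[1:2]), "3 paired")
})

test_that("potency ledger outer-joins compounds and computes pairwise
           correlations", {
  csat <- c(hd16 = 320, hd25 = 250, pd15 = 210, bd14 = 180, chd12 = 150)
  slope <- c(hd16 = 1.0, hd25 = 0.7, pd15 = 0.55, bd14 = 0.4)
  logp <- c(hd16 = 0.2, hd25 = -0.1, pd15 = -0.3, bd14 = -0.6,
            extra = 2)
  led <- assemble_potency_ledger(csat = csat, slope = slope, logp = logp)
  # join preserves every input compound
  expect_setequal(led$table$compound,
                  union(names(csat), union(names(slope), names(logp))))
  expect_true(is.na(led$table$csp_slope[led$table$compound == "extra"]))
  # correlations over paired complete observations only
  row <- led$correlations[led$correlations$var_x == "csat" &
                            led$correlations$var_y == "csp_slope", ]
  common <- intersect(names(csat), names(slope))
  expect_equal(row$pcc, cor(csat[common], slope[common]))
  expect_equal(row$n, length(common))
  # permutation invariance in row order
  led2 <- assemble_potency_ledger(csat = rev(csat), slope = slope,
                                  logp = logp)
  expect_equal(led2$correlations$pcc, led$correlations$pcc)
  # single shared compound: flagged unavailable
  led3 <- assemble_potency_ledger(csat = c(a = 1, b = 2, c = 3),
                                  dtm = c(a = -1))
  expect_true(is.na(led3$correlations$pcc))
  expect_error(assemble_potency_ledger(csat = c(a = 1, a = 2, b = 3)),
               "duplicate")
})

test_that("ledger built from synthetic CSP truth recovers the constructed
           potency-Csat relation", {
  set.seed(110)
  seq_v <- sample(c("G", "S", "Y", "Q"), 60, replace = TRUE)
  pat <- rnorm(60, 0, 0.25)
  lam <- c(hd16 = 1.0, hd25 = 0.75, pd15 = 0.5, bd14 = 0.3, chd12 = 0.15)
  ds <- gen_csp_dataset(csp_pattern(pat, lam, noise_sd = 0.01), seq_v,
                        seed = 111)
  tabs <- lapply(ds$conditions, function(cd) compute_csp(ds$reference, cd))
  slopes <- vapply(names(tabs), function(nm)
    cross_condition_slope(tabs[[nm]], tabs$hd16)$slope, numeric(1))
  csat <- setNames(ds$truth$csat, ds$truth$condition)
  led <- assemble_potency_ledger(csat = csat, slope = slopes)
  pcc <- led$correlations$pcc[led$correlations$var_x == "csat"]
  expect_gt(pcc, 0.95)  # construction links Csat positively to potency
})
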