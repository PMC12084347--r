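#' Fit a two-state van't Hoff melting curve
#'
#' Nonlinear least-squares fit of the two-state model with linear folded
#' and unfolded baselines (the same form as [gen_melt_curve()]):
#' \deqn{\theta(T) = \frac{\theta_N(T) + \theta_U(T) K(T)}{1 + K(T)},
#'   \quad K(T) = e^{-(\Delta H / R)(1/T - 1/T_m)}}
#' Initial Tm comes from the steepest-slope temperature of the smoothed
#' signal, with additional starts nearby (multi-start). A cross-check Tm
#' from the midpoint of the min-max-normalised signal is reported, and a
#' disagreement beyond 1 degree C between the two methods is flagged.
#'
#' A curve with no transition in range yields `converged = FALSE` rather
#' than a fabricated Tm.
#'
#' @param curve data frame with columns `temperature_c` (strictly
#'   increasing, >= 10 points) and `mre`.
#' @return A list of class `"melt_fit"`: `tm_c`, `tm_k`, `tm_se`,
#'   `dh_kj_mol`, `folded_baseline`, `unfolded_baseline`, `converged`,
#'   `tm_midpoint_c`, `method_disagreement`, and the `nls` fit.
#' @export
fit_melting_curve <- function(curve) {
  need <- c("temperature_c", "mre")
  if (!all(need %in% names(curve)))
    stop("curve needs columns temperature_c and mre")
  t_c <- curve$temperature_c; y <- curve$mre
  if (length(t_c) < 10L) stop("need at least 10 points across the melt")
  if (any(diff(t_c) <= 0)) stop("temperatures must be strictly increasing")

  # smoothed derivative for the transition-midpoint start
  ks <- max(3L, min(7L, length(y) %/% 10))
  sm <- stats::filter(y, rep(1 / ks, ks), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  dy <- diff(sm) / diff(t_c)
  tm0_c <- t_c[which.max(abs(dy))]

  nb <- max(3L, length(y) %/% 8)
  bf <- coef(lm(y ~ t_c, subset = seq_len(nb)))
  bu <- coef(lm(y ~ t_c, subset = seq(length(y) - nb + 1L, length(y))))

  fits <- list()
  for (tm_start in unique(pmin(pmax(tm0_c + c(0, -5, 5), min(t_c)),
                               max(t_c)))) {
    for (dh_start in c(200, 450)) {
      mod <- tryCatch(minpack.lm::nlsLM(
        y ~ two_state_signal(t_c, tm_k, dh, c(a_n, b_n), c(a_u, b_u)),
        start = list(tm_k = tm_start + 273.15, dh = dh_start,
                     a_n = unname(bf[1]), b_n = unname(bf[2]),
                     a_u = unname(bu[1]), b_u = unname(bu[2])),
        control = nls.control(maxiter = 500, tol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(mod)) fits[[length(fits) + 1L]] <- mod
    }
  }

  # midpoint cross-check: where the normalised smoothed signal crosses 1/2
  s_norm <- (sm - min(sm)) / max(diff(range(sm)), .Machine$double.eps)
  if (s_norm[1] > s_norm[length(s_norm)]) s_norm <- 1 - s_norm
  cross <- which(diff(sign(s_norm - 0.5)) != 0)
  tm_mid <- if (length(cross) > 0) {
    i <- cross[1]
    approx(s_norm[c(i, i + 1L)], t_c[c(i, i + 1L)], xout = 0.5)$y
  } else NA_real_

  empty <- list(tm_c = NA_real_, tm_k = NA_real_, tm_se = NA_real_,
                dh_kj_mol = NA_real_,
                folded_baseline = c(NA_real_, NA_real_),
                unfolded_baseline = c(NA_real_, NA_real_),
                converged = FALSE, tm_midpoint_c = tm_mid,
                method_disagreement = NA, fit = NULL)
  if (length(fits) == 0) return(structure(empty, class = "melt_fit"))
  rss <- vapply(fits, function(m) sum(residuals(m)^2), numeric(1))
  mod <- fits[[which.min(rss)]]
  cf <- coef(mod)
  tm_k <- unname(cf[["tm_k"]])
  tm_c <- tm_k - 273.15
  resid_sd <- sqrt(min(rss) / max(length(y) - 6, 1))
  amplitude <- abs((cf[["a_n"]] + cf[["b_n"]] * tm_c) -
                     (cf[["a_u"]] + cf[["b_u"]] * tm_c))
  converged <- tm_c >= min(t_c) && tm_c <= max(t_c) &&
    cf[["dh"]] > 0 && amplitude > 3 * resid_sd
  if (!converged) {
    out <- empty
    out$fit <- mod
    return(structure(out, class = "melt_fit"))
  }
  se <- tryCatch(summary(mod)$coefficients["tm_k", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(
    tm_c = tm_c, tm_k = tm_k, tm_se = se,
    dh_kj_mol = unname(cf[["dh"]]),
    folded_baseline = unname(c(cf[["a_n"]], cf[["b_n"]])),
    unfolded_baseline = unname(c(cf[["a_u"]], cf[["b_u"]])),
    converged = TRUE, tm_midpoint_c = tm_mid,
    method_disagreement = !is.na(tm_mid) && abs(tm_mid - tm_c) > 1,
    fit = mod), class = "melt_fit")
}

#' Melting-temperature change between conditions
#'
#' `delta_tm = Tm_condition - Tm_reference` in degrees C, with the fit
#' uncertainties combined in quadrature. Both fits must have converged.
#'
#' @param reference,condition [fit_melting_curve()] results.
#' @return A list with `delta_tm_c` and `se`.
#' @export
delta_tm <- function(reference, condition) {
  stopifnot(inherits(reference, "melt_fit"), inherits(condition, "melt_fit"))
  if (!isTRUE(reference$converged) || !isTRUE(condition$converged))
    stop("both melting fits must have converged")
  list(delta_tm_c = condition$tm_c - reference$tm_c,
       se = sqrt(sum(c(reference$tm_se, condition$tm_se)^2)))
}

#' Concentration from an NMR integral against a reference standard
#'
#' Proton-normalised quantification:
#' `c = ref_concentration * (integral / protons) /
#' (ref_integral / ref_protons)`.
#'
#' @param integral solute peak integral (>= 0).
#' @param protons protons contributing to the solute integral.
#' @param ref_integral reference-standard integral (> 0).
#' @param ref_protons protons of the reference resonance.
#' @param ref_concentration reference-standard concentration.
#' @return Concentration in the reference's units; vectorised in
#'   `integral`.
#' @export
concentration_from_integral <- function(integral, protons, ref_integral,
                                        ref_protons, ref_concentration) {
  if (any(ref_integral <= 0)) stop("reference integral must be > 0")
  if (any(c(protons, ref_protons) <= 0)) stop("proton counts must be > 0")
  if (any(ref_concentration <= 0))
    stop("reference concentration must be > 0")
  if (any(integral < 0)) stop("integrals must be >= 0")
  ref_concentration * (integral / protons) / (ref_integral / ref_protons)
}

#' Octanol/water partition coefficient
#'
#' `logP = log10(c_octanol / c_water)`, the operational hydrophobicity of
#' the solute.
#'
#' @param c_octanol,c_water phase concentrations (> 0, same units).
#' @return logP, dimensionless; vectorised.
#' @export
log_p <- function(c_octanol, c_water) {
  if (any(c_octanol <= 0) || any(c_water <= 0))
    stop("concentrations must be > 0")
  log10(c_octanol / c_water)
}

#' logP from a partition measurement
#'
#' Quantifies both phase concentrations of a [gen_partition_measurement()]
#' (or equivalently structured) record via
#' [concentration_from_integral()] and returns [log_p()] of the pair.
#'
#' @param pm a `partition_measurement` list.
#' @return A list with `logp`, `c_octanol`, `c_water`.
#' @export
measure_log_p <- function(pm) {
  c_o <- concentration_from_integral(pm$integral_octanol, pm$protons,
                                     pm$integral_reference, pm$ref_protons,
                                     pm$reference_concentration)
  c_w <- concentration_from_integral(pm$integral_water, pm$protons,
                                     pm$integral_reference, pm$ref_protons,
                                     pm$reference_concentration)
  list(logp = log_p(c_o, c_w), c_octanol = c_o, c_water = c_w)
}

#' Pearson correlation with explicit outlier exclusion
#'
#' Pearson correlation over label-matched pairs, reported both for all
#' pairs and for the pairs remaining after removing a named set of
#' compounds. Exclusion is always explicit by label, never automatic.
#'
#' @param x,y named numeric vectors (names are compound labels).
#' @param exclude character vector of labels to exclude in the second
#'   correlation.
#' @return A list with `pcc`, `n`, `pcc_excluded`, `n_excluded`,
#'   `excluded` (the labels actually removed); `pcc_excluded` is `NA` when
#'   fewer than 3 pairs remain.
#' @export
pearson_with_exclusion <- function(x, y, exclude = character()) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by compound label")
  labels <- intersect(names(x), names(y))
  xv <- x[labels]; yv <- y[labels]
  ok <- is.finite(xv) & is.finite(yv)
  labels <- labels[ok]; xv <- xv[ok]; yv <- yv[ok]
  if (length(labels) < 3L) stop("need at least 3 paired values")
  keep <- !(labels %in% exclude)
  pcc_ex <- if (sum(keep) >= 3L) cor(xv[keep], yv[keep]) else NA_real_
  list(pcc = cor(xv, yv), n = length(labels),
       pcc_excluded = pcc_ex, n_excluded = sum(keep),
       excluded = intersect(exclude, labels))
}

#' Assemble the cross-assay potency ledger
#'
#' Outer-joins per-compound tables of saturation concentration, CSP slope,
#' logP and delta-Tm, and computes every pairwise Pearson correlation over
#' the compounds where both quantities are present (n >= 3 required,
#' otherwise flagged unavailable). This is the summary table linking how
#' strongly a diol perturbs residue chemical environments to how strongly
#' it disrupts phase separation, its hydrophobicity and its effect on a
#' folded protein's stability.
#'
#' @param csat,slope,logp,dtm named numeric vectors keyed by compound
#'   label (any may be `NULL`); duplicate keys are an error.
#' @param exclude labels excluded in the secondary correlations (see
#'   [pearson_with_exclusion()]).
#' @return A list of class `"potency_ledger"`: `table` (data frame with
#'   one row per compound, `NA` for missing cells) and `correlations`
#'   (data frame `var_x`, `var_y`, `pcc`, `n`, `pcc_excluded`,
#'   `n_excluded`).
#' @export
assemble_potency_ledger <- function(csat = NULL, slope = NULL, logp = NULL,
                                    dtm = NULL, exclude = character()) {
  cols <- list(csat = csat, csp_slope = slope, logp = logp, delta_tm = dtm)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (length(cols) == 0) stop("no input tables provided")
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (is.null(names(v))) stop(nm, " must be named by compound label")
    if (anyDuplicated(names(v)))
      stop("duplicate compound keys in ", nm, ": ",
           paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  }
  compounds <- sort(unique(unlist(lapply(cols, names))))
  tab <- data.frame(compound = compounds, stringsAsFactors = FALSE)
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]][compounds])

  pairs <- utils::combn(names(cols), 2, simplify = FALSE)
  corr <- do.call(rbind, lapply(pairs, function(p) {
    x <- setNames(tab[[p[1]]], tab$compound)
    y <- setNames(tab[[p[2]]], tab$compound)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3L) {
      pe <- pearson_with_exclusion(x[ok], y[ok], exclude)
      data.frame(var_x = p[1], var_y = p[2], pcc = pe$pcc, n = pe$n,
                 pcc_excluded = pe$pcc_excluded, n_excluded = pe$n_excluded,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(var_x = p[1], var_y = p[2], pcc = NA_real_, n = sum(ok),
                 pcc_excluded = NA_real_, n_excluded = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  }))
  structure(list(table = tab, correlations = corr),
            class = "potency_ledger")
}

#' @export
print.potency_ledger <- function(x, ...) {
  cat("potency ledger:", nrow(x$table), "compounds\n")
  print(x$table, row.names = FALSE)
  cat("\npairwise Pearson correlations (paired complete observations):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
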