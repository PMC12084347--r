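#' Specification of a shared chemical-shift-perturbation pattern
#'
#' Encodes the observation that different alkanediols perturb the same
#' residues of a disordered domain with the same per-residue pattern, scaled
#' by a per-compound potency factor: the perturbation of residue i under
#' condition c is `potency[c] * pattern[i]` plus noise. Each condition also
#' carries a ground-truth dilute-phase (saturation) concentration linked
#' affinely to its potency: more potent diols dissolve condensates more,
#' leaving more protein in the dilute phase.
#'
#' @param pattern per-residue dimensionless sensitivities (length = sequence
#'   length).
#' @param potencies named numeric vector of per-condition scale factors;
#'   names are compound labels.
#' @param noise_sd Gaussian noise on shifts, ppm (>= 0).
#' @param csat_map named numeric vector of true saturation concentrations
#'   per condition (same names as `potencies`); by default
#'   `csat_intercept + csat_slope * potency`.
#' @param csat_intercept,csat_slope affine link used when `csat_map` is
#'   `NULL` (micromolar).
#' @return A list of class `"csp_pattern"`.
#' @export
csp_pattern <- function(pattern, potencies, noise_sd = 0, csat_map = NULL,
                        csat_intercept = 100, csat_slope = 200) {
  if (noise_sd < 0) stop("invalid CSPPattern: noise_sd must be >= 0")
  if (is.null(names(potencies)))
    names(potencies) <- paste0("cmpd", seq_along(potencies))
  if (is.null(csat_map))
    csat_map <- setNames(csat_intercept + csat_slope * potencies,
                         names(potencies))
  if (!identical(sort(names(csat_map)), sort(names(potencies))))
    stop("invalid CSPPattern: csat_map names must match potencies")
  structure(list(pattern = pattern, potencies = potencies,
                 noise_sd = noise_sd, csat_map = csat_map),
            class = "csp_pattern")
}

#' Generate synthetic HSQC peak lists for a reference and cosolvent
#' conditions
#'
#' Produces a no-cosolvent reference peak list plus one peak list per
#' condition, in which the shift of residue i for the primary nucleus (15N)
#' is `shift_ref + potency * pattern_i + noise`; amide-proton shifts move
#' with a tenth of that amplitude. Peak intensities attenuate mildly with
#' potency. A truth table records each condition's potency and true
#' saturation concentration.
#'
#' @param spec a [csp_pattern()]; `length(spec$pattern)` must equal the
#'   sequence length.
#' @param sequence residue-type string (one string or a character vector of
#'   one-letter codes).
#' @param seed RNG seed.
#' @return A list with elements `reference` (peak-list data frame),
#'   `conditions` (named list of peak-list data frames) and `truth`
#'   (data frame with columns `condition`, `potency`, `csat`).
#' @export
gen_csp_dataset <- function(spec, sequence, seed = 0L) {
  stopifnot(inherits(spec, "csp_pattern"))
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  N <- length(sequence)
  if (length(spec$pattern) != N)
    stop("pattern length (", length(spec$pattern),
         ") does not match sequence length (", N, ")")

  with_seed(seed, {
    ref_n <- rnorm(N, 117, 2.5)
    ref_h <- rnorm(N, 8.3, 0.3)
    ref_i <- runif(N, 0.8e5, 1.2e5)
    peaklist <- function(shift_n, shift_h, inten, label) {
      data.frame(residue_index = rep(seq_len(N), 2L),
                 residue_type = rep(sequence, 2L),
                 nucleus = rep(c("15N", "1H"), each = N),
                 shift_ppm = c(shift_n, shift_h),
                 intensity = rep(inten, 2L),
                 condition = label,
                 stringsAsFactors = FALSE)
    }
    reference <- peaklist(ref_n, ref_h, ref_i, "reference")
    conditions <- lapply(names(spec$potencies), function(cond) {
      lam <- spec$potencies[[cond]]
      dn <- lam * spec$pattern + rnorm(N, 0, spec$noise_sd)
      dh <- 0.1 * (lam * spec$pattern) + rnorm(N, 0, 0.1 * spec$noise_sd)
      peaklist(ref_n + dn, ref_h + dh, ref_i * exp(-0.3 * lam), cond)
    })
    names(conditions) <- names(spec$potencies)
    truth <- data.frame(condition = names(spec$potencies),
                        potency = unname(spec$potencies),
                        csat = unname(spec$csat_map[names(spec$potencies)]),
                        stringsAsFactors = FALSE)
    list(reference = reference, conditions = conditions, truth = truth)
  })
}

#' Specification of a two-state thermal melt
#'
#' Parameters of a van't Hoff two-state unfolding transition monitored by a
#' spectroscopic signal (molar residue ellipticity at 222 nm) with linear
#' folded and unfolded baselines in temperature.
#'
#' @param tm_true melting temperature, Kelvin; must lie inside `t_range`.
#' @param dh_vant_hoff van't Hoff enthalpy, kJ/mol (> 0).
#' @param folded_baseline,unfolded_baseline `(intercept, slope)` of the
#'   baselines in MRE units versus temperature in Celsius.
#' @param t_range temperature range scanned, Celsius, increasing.
#' @param noise_sd Gaussian noise, MRE units.
#' @param n_points points across the range.
#' @param seed RNG seed.
#' @return A list of class `"melt_spec"`.
#' @export
melt_spec <- function(tm_true = 341.15, dh_vant_hoff = 430,
                      folded_baseline = c(-11000, -15),
                      unfolded_baseline = c(-3500, -8),
                      t_range = c(25, 90), noise_sd = 0,
                      n_points = 131L, seed = 0L) {
  if (diff(t_range) <= 0) stop("invalid MeltSpec: t_range must be increasing")
  if (dh_vant_hoff <= 0) stop("invalid MeltSpec: dh_vant_hoff must be > 0")
  if (tm_true < t_range[1] + 273.15 || tm_true > t_range[2] + 273.15)
    stop("invalid MeltSpec: tm_true must lie within t_range")
  if (noise_sd < 0) stop("invalid MeltSpec: noise_sd must be >= 0")
  structure(list(tm_true = tm_true, dh_vant_hoff = dh_vant_hoff,
                 folded_baseline = folded_baseline,
                 unfolded_baseline = unfolded_baseline,
                 t_range = t_range, noise_sd = noise_sd,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "melt_spec")
}

GAS_CONSTANT_KJ <- 8.314462618e-3  # kJ mol^-1 K^-1

# Noiseless two-state signal at temperatures in Celsius.
two_state_signal <- function(t_c, tm_k, dh_kj, folded, unfolded) {
  t_k <- t_c + 273.15
  k_eq <- exp(-(dh_kj / GAS_CONSTANT_KJ) * (1 / t_k - 1 / tm_k))
  theta_n <- folded[1] + folded[2] * t_c
  theta_u <- unfolded[1] + unfolded[2] * t_c
  (theta_n + theta_u * k_eq) / (1 + k_eq)
}

#' Generate a synthetic CD melting curve
#'
#' Two-state van't Hoff signal
#' \eqn{\theta(T) = [\theta_N(T) + \theta_U(T) K(T)] / [1 + K(T)]} with
#' \eqn{K(T) = \exp[-(\Delta H/R)(1/T - 1/T_m)]}, linear baselines in
#' Celsius, plus Gaussian noise.
#'
#' @param spec a [melt_spec()].
#' @return A data frame of class `"melting_curve"` with columns
#'   `temperature_c` and `mre`.
#' @export
gen_melt_curve <- function(spec) {
  stopifnot(inherits(spec, "melt_spec"))
  t_c <- seq(spec$t_range[1], spec$t_range[2], length.out = spec$n_points)
  theta <- two_state_signal(t_c, spec$tm_true, spec$dh_vant_hoff,
                            spec$folded_baseline, spec$unfolded_baseline)
  noise <- with_seed(spec$seed, rnorm(length(t_c), 0, spec$noise_sd))
  out <- data.frame(temperature_c = t_c, mre = theta + noise)
  class(out) <- c("melting_curve", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Specification of an octanol/water partition experiment
#'
#' @param logp_true true log10 partition coefficient (octanol over water).
#' @param total_amount total solute amount, mol.
#' @param v_octanol,v_water phase volumes, litres (> 0).
#' @param protons_per_molecule protons contributing to the solute's
#'   integrated NMR resonance.
#' @param reference_concentration concentration of the internal reference
#'   standard, mol/L.
#' @param ref_protons protons of the reference resonance (9 for the
#'   trimethylsilyl singlet of DSS).
#' @param noise_sd relative Gaussian noise on each integral.
#' @param seed RNG seed.
#' @return A list of class `"partition_spec"`.
#' @export
partition_spec <- function(logp_true, total_amount, v_octanol, v_water,
                           protons_per_molecule = 12L,
                           reference_concentration = 1e-3,
                           ref_protons = 9L, noise_sd = 0, seed = 0L) {
  if (total_amount <= 0)
    stop("invalid PartitionSpec: total_amount must be > 0")
  if (v_octanol <= 0 || v_water <= 0)
    stop("invalid PartitionSpec: volumes must be > 0")
  if (reference_concentration <= 0)
    stop("invalid PartitionSpec: reference_concentration must be > 0")
  if (noise_sd < 0) stop("invalid PartitionSpec: noise_sd must be >= 0")
  structure(list(logp_true = logp_true, total_amount = total_amount,
                 v_octanol = v_octanol, v_water = v_water,
                 protons_per_molecule = as.integer(protons_per_molecule),
                 reference_concentration = reference_concentration,
                 ref_protons = as.integer(ref_protons),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "partition_spec")
}

#' Generate a synthetic partition measurement
#'
#' Computes equilibrium phase concentrations from mass balance,
#' `c_w = n_tot / (V_w + P V_o)` and `c_o = P c_w` with
#' `P = 10^logp_true`, and emits NMR-style integrals proportional to
#' concentration times proton count, plus a reference-standard integral,
#' each with relative Gaussian noise.
#'
#' @param spec a [partition_spec()].
#' @return A list of class `"partition_measurement"` with the integrals,
#'   proton counts, reference concentration, volumes and a `truth` element
#'   (`c_octanol`, `c_water`, `logp_true`).
#' @export
gen_partition_measurement <- function(spec) {
  stopifnot(inherits(spec, "partition_spec"))
  P <- 10^spec$logp_true
  c_w <- spec$total_amount / (spec$v_water + P * spec$v_octanol)
  c_o <- P * c_w
  scale <- 1e4  # arbitrary spectrometer response per (mol/L * proton)
  with_seed(spec$seed, {
    noisy <- function(x) x * (1 + rnorm(1, 0, spec$noise_sd))
    structure(list(
      integral_octanol = noisy(scale * c_o * spec$protons_per_molecule),
      integral_water = noisy(scale * c_w * spec$protons_per_molecule),
      integral_reference =
        noisy(scale * spec$reference_concentration * spec$ref_protons),
      protons = spec$protons_per_molecule,
      ref_protons = spec$ref_protons,
      reference_concentration = spec$reference_concentration,
      v_octanol = spec$v_octanol, v_water = spec$v_water,
      truth = list(c_octanol = c_o, c_water = c_w,
                   logp_true = spec$logp_true)),
      class = "partition_measurement")
  })
}

#' Specification of a synthetic fluorescence droplet image
#'
#' @param width,height image size in pixels.
#' @param centers n x 2 matrix of droplet centre coordinates `(x, y)` in
#'   pixel units; every disk must lie fully inside the frame.
#' @param radii droplet radii in pixels.
#' @param foreground_intensity,background_intensity grey levels (16-bit
#'   range, 0..65535).
#' @param noise_sd Gaussian noise, grey levels.
#' @param seed RNG seed.
#' @return A list of class `"image_spec"`.
#' @export
image_spec <- function(width, height, centers = NULL, radii = NULL,
                       foreground_intensity = 20000,
                       background_intensity = 2000,
                       noise_sd = 0, seed = 0L) {
  if (is.null(centers)) centers <- matrix(numeric(0), 0, 2)
  centers <- as.matrix(centers)
  if (length(radii) != nrow(centers))
    stop("invalid ImageSpec: need one radius per centre")
  if (nrow(centers) > 0) {
    inside <- centers[, 1] - radii >= 0.5 & centers[, 1] + radii <= width + 0.5 &
      centers[, 2] - radii >= 0.5 & centers[, 2] + radii <= height + 0.5
    if (!all(inside))
      stop("invalid ImageSpec: droplets must lie fully inside the frame")
  }
  ok_int <- function(x) x >= 0 && x <= 65535
  if (!ok_int(foreground_intensity) || !ok_int(background_intensity))
    stop("invalid ImageSpec: intensities must be within 16-bit depth")
  if (noise_sd < 0) stop("invalid ImageSpec: noise_sd must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 centers = centers, radii = radii,
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_spec")
}

#' Generate a synthetic droplet image with known ground truth
#'
#' Renders bright disks on a darker background (a pixel belongs to a disk
#' when its centre is within the disk radius), adds Gaussian noise, and
#' clamps to the 16-bit range. The truth records the exact bright-pixel
#' area fraction and the number of 8-connected bright components, so
#' overlapping disks count as one merged droplet.
#'
#' @param spec an [image_spec()].
#' @return A list with `image` (height x width integer matrix), `mask`
#'   (logical ground-truth matrix) and `truth`
#'   (`area_fraction` in percent, `count`).
#' @export
gen_droplet_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  w <- spec$width; h <- spec$height
  px <- matrix(rep(seq_len(w), each = h), h, w)   # x coordinate per pixel
  py <- matrix(rep(seq_len(h), times = w), h, w)  # y coordinate per pixel
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(spec$centers))) {
    mask <- mask | ((px - spec$centers[i, 1])^2 +
                      (py - spec$centers[i, 2])^2 <= spec$radii[i]^2)
  }
  img <- matrix(spec$background_intensity, h, w)
  img[mask] <- spec$foreground_intensity
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed, matrix(rnorm(h * w, 0, spec$noise_sd),
                                             h, w))
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 65535))), h, w)
  count <- if (any(mask)) max(label_components_cpp(mask)) else 0L
  list(image = img, mask = mask,
       truth = list(area_fraction = 100 * mean(mask), count = count))
}
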