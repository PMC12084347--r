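#' Protein concentration from dilute-phase absorbance
#'
#' Beer-Lambert conversion of an A280 reading to concentration,
#' `c = A280 * dilution / (epsilon * pathlength)`, reported in micromolar.
#' This is the supernatant saturation-concentration (Csat) readout: after
#' pelleting droplets, the dilute-phase absorbance measures how much
#' protein remains soluble.
#'
#' @param a280 absorbance at 280 nm (vectorised, >= 0).
#' @param epsilon molar extinction coefficient, 1/(M cm) (> 0).
#' @param pathlength optical path, cm.
#' @param dilution dilution factor applied before reading.
#' @return Concentration in micromolar.
#' @examples
#' concentration_from_a280(0.30, 15000)  # 20 uM
#' @export
concentration_from_a280 <- function(a280, epsilon, pathlength = 1,
                                    dilution = 1) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (pathlength <= 0) stop("pathlength must be > 0")
  if (any(a280 < 0)) stop("absorbance must be >= 0")
  a280 * dilution / (epsilon * pathlength) * 1e6
}

#' Extinction-coefficient matrix for protein/RNA deconvolution
#'
#' 2 x 2 matrix of extinction coefficients, rows = wavelengths (260, 280),
#' columns = species (protein, RNA), in per-concentration per-cm units.
#' Must be non-singular for the two-wavelength deconvolution to be
#' solvable.
#'
#' @param protein_260,protein_280,rna_260,rna_280 extinction coefficients.
#' @return A 2 x 2 numeric matrix with dimnames.
#' @export
extinction_matrix <- function(protein_260, protein_280, rna_260, rna_280) {
  em <- matrix(c(protein_260, protein_280, rna_260, rna_280), 2, 2,
               dimnames = list(c("A260", "A280"), c("protein", "rna")))
  if (abs(det(em)) < .Machine$double.eps * max(abs(em))^2 * 4)
    stop("extinction matrix is singular; cannot deconvolve")
  em
}

#' Two-wavelength protein/RNA deconvolution
#'
#' Solves the 2 x 2 Beer-Lambert system
#' `A_lambda = eps_protein(lambda) c_p + eps_rna(lambda) c_r` at 260 and
#' 280 nm, separating the protein and RNA contributions to the dilute
#' phase of a protein/RNA coacervate. Negative solutions are reported with
#' a flag (a blank or coefficient mismatch diagnostic), never clipped.
#'
#' @param a260,a280 measured absorbances.
#' @param em an [extinction_matrix()].
#' @param pathlength optical path, cm.
#' @param dilution dilution factor.
#' @return A list with `protein`, `rna` (same concentration units as the
#'   extinction coefficients' inverse) and `negative_flag`.
#' @export
deconvolve_protein_rna <- function(a260, a280, em, pathlength = 1,
                                   dilution = 1) {
  if (!is.matrix(em) || any(dim(em) != 2))
    stop("em must be a 2 x 2 extinction matrix")
  if (abs(det(em)) == 0) stop("extinction matrix is singular")
  conc <- solve(em, c(a260, a280) * dilution / pathlength)
  list(protein = unname(conc[1]), rna = unname(conc[2]),
       negative_flag = any(conc < 0))
}

#' Background-corrected turbidity
#'
#' Subtracts a matched no-trigger control series (e.g. the no-TEV-protease
#' storage-buffer control) from sample turbidity readings, elementwise by
#' condition and replicate, and aggregates replicates as n, mean, sd.
#' Negative corrected values are preserved, not floored.
#'
#' @param sample,control data frames with columns `condition`, `a600` and
#'   optionally `replicate`; conditions must match between the two.
#' @return A list with `per_replicate` (condition, replicate, corrected)
#'   and `summary` (condition, n, mean, sd).
#' @export
turbidity_corrected <- function(sample, control) {
  need <- c("condition", "a600")
  if (!all(need %in% names(sample)) || !all(need %in% names(control)))
    stop("sample and control need columns condition and a600")
  miss <- union(setdiff(sample$condition, control$condition),
                setdiff(control$condition, sample$condition))
  if (length(miss) > 0)
    stop("unmatched conditions: ", paste(sort(unique(miss)), collapse = ", "))
  if (is.null(sample$replicate))
    sample$replicate <- stats::ave(seq_len(nrow(sample)), sample$condition,
                                   FUN = seq_along)
  if (is.null(control$replicate))
    control$replicate <- stats::ave(seq_len(nrow(control)), control$condition,
                                    FUN = seq_along)
  merged <- merge(sample, control, by = c("condition", "replicate"),
                  suffixes = c("_sample", "_control"))
  if (nrow(merged) == 0) stop("no matching condition/replicate pairs")
  merged$corrected <- merged$a600_sample - merged$a600_control
  per <- merged[, c("condition", "replicate", "corrected")]
  groups <- split(per$corrected, per$condition)
  summ <- data.frame(
    condition = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) sd(x) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_replicate = per, summary = summ)
}

# Threshold selection shared by the droplet quantifiers. Returns the grey
# level above which a pixel counts as droplet.
droplet_threshold <- function(image, method, threshold) {
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    return(threshold)
  }
  rng <- range(image)
  if (diff(rng) == 0)
    stop("constant image: Otsu thresholding is undefined; ",
         "use method = 'fixed' with an explicit threshold")
  # Otsu on the normalised histogram, mapped back to grey levels
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

#' Droplet area fraction of a fluorescence image
#'
#' Percentage of pixels brighter than a threshold, the standard droplet
#' area readout for phase-separation micrographs. The threshold comes from
#' Otsu's criterion by default; a fixed threshold gives exact control.
#'
#' @param image single-channel numeric matrix (grey levels).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold grey level for `method = "fixed"`.
#' @return A list of class `"droplet_quant"` with `area_fraction`
#'   (percent), `threshold`, `method`.
#' @export
droplet_area_fraction <- function(image, method = c("otsu", "fixed"),
                                  threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  th <- droplet_threshold(image, method, threshold)
  structure(list(area_fraction = 100 * mean(image > th),
                 threshold = th, method = method),
            class = "droplet_quant")
}

#' Count droplets in a fluorescence image
#'
#' Connected-component count (8-connectivity) of above-threshold regions
#' with at least `min_area` pixels, matching common ImageJ-style particle
#' analysis. Overlapping droplets merge into one component.
#'
#' @param image single-channel numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold grey level for `method = "fixed"`.
#' @param min_area minimum component area in pixels (default 5).
#' @return A list with `count`, `component_areas`, `threshold`, `min_area`.
#' @export
count_droplets <- function(image, method = c("otsu", "fixed"),
                           threshold = NULL, min_area = 5L) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  th <- droplet_threshold(image, method, threshold)
  labels <- label_components_cpp(image > th)
  areas <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  list(count = sum(areas >= min_area), component_areas = areas,
       threshold = th, min_area = min_area)
}

#' Linear trend of saturation concentration with diol concentration
#'
#' Ordinary least squares of Csat (or droplet area) against percent diol,
#' on replicate means; a weighted fit (1 / sd^2) is available when
#' replicate scatter varies between concentrations.
#'
#' @param points data frame with columns `percent_diol` and `csat`
#'   (replicate rows allowed).
#' @param weighted weight the fit by inverse replicate variance.
#' @return A list with `slope`, `intercept`, `r_squared`, `means` (the
#'   aggregated table) and the `lm` fit.
#' @export
fit_concentration_trend <- function(points, weighted = FALSE) {
  need <- c("percent_diol", "csat")
  if (!all(need %in% names(points)))
    stop("points needs columns percent_diol and csat")
  if (length(unique(points$percent_diol)) < 2L)
    stop("need at least 2 distinct diol concentrations")
  groups <- split(points$csat, points$percent_diol)
  means <- data.frame(
    percent_diol = as.numeric(names(groups)),
    csat = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) sd(x) else NA_real_,
                numeric(1)),
    n = vapply(groups, length, integer(1)),
    row.names = NULL)
  if (weighted) {
    if (any(is.na(means$sd) | means$sd == 0))
      stop("weighted fit needs positive replicate sd at every concentration")
    mod <- lm(csat ~ percent_diol, data = means, weights = 1 / means$sd^2)
  } else {
    mod <- lm(csat ~ percent_diol, data = means)
  }
  list(slope = unname(coef(mod)[["percent_diol"]]),
       intercept = unname(coef(mod)[["(Intercept)"]]),
       r_squared = suppressWarnings(summary(mod)$r.squared),
       means = means, fit = mod)
}
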