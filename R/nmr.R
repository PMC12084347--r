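# Frequency ratios (Xi, percent of the 1H reference frequency) for indirect
# referencing of heteronuclei to a 1H DSS reference.
XI_RATIOS <- c("15N" = 10.132912, "13C" = 25.144953)

#' Indirect referencing frequency for a heteronucleus
#'
#' Given the 1H spectrometer frequency referenced to DSS, the zero-ppm
#' frequency of a heteronucleus is `V_X = V_1H * Xi / 100` with
#' Xi(15N) = 10.132912 and Xi(13C) = 25.144953.
#'
#' @param v_1h 1H frequency in MHz (> 0).
#' @param nucleus `"15N"` or `"13C"`.
#' @return Frequency in MHz.
#' @examples
#' indirect_reference_frequency(850, "15N")  # 86.1297520
#' @export
indirect_reference_frequency <- function(v_1h, nucleus) {
  if (!is.numeric(v_1h) || any(v_1h <= 0))
    stop("v_1h must be a positive frequency in MHz")
  if (!nucleus %in% names(XI_RATIOS))
    stop("unknown nucleus '", nucleus, "'; expected one of ",
         paste(names(XI_RATIOS), collapse = ", "))
  v_1h * XI_RATIOS[[nucleus]] / 100
}

filter_nucleus <- function(peaks, nucleus) {
  need <- c("residue_index", "nucleus", "shift_ppm", "intensity")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols) > 0)
    stop("peak list is missing columns: ",
         paste(missing_cols, collapse = ", "))
  peaks[peaks$nucleus == nucleus, , drop = FALSE]
}

#' Chemical shift perturbations between two conditions
#'
#' Per-residue signed shift difference `delta_shift = shift_condition -
#' shift_reference` for one nucleus, together with the intensity ratio
#' `I_condition / I_reference`. Residues present in only one list are kept
#' with `NA` (missing, not zero); an empty intersection is an error.
#'
#' @param reference,condition peak-list data frames (columns
#'   `residue_index`, `residue_type`, `nucleus`, `shift_ppm`, `intensity`).
#' @param nucleus nucleus to compare (default `"15N"`).
#' @return A data frame of class `"csp_table"` with columns
#'   `residue_index`, `residue_type`, `delta_shift` (ppm, signed),
#'   `intensity_ratio`.
#' @export
compute_csp <- function(reference, condition, nucleus = "15N") {
  ref <- filter_nucleus(reference, nucleus)
  cond <- filter_nucleus(condition, nucleus)
  if (length(intersect(ref$residue_index, cond$residue_index)) == 0L)
    stop("no residues shared between the two peak lists")
  resids <- sort(union(ref$residue_index, cond$residue_index))
  ir <- match(resids, ref$residue_index)
  ic <- match(resids, cond$residue_index)
  rtype <- ifelse(is.na(ir), cond$residue_type[ic], ref$residue_type[ir])
  out <- data.frame(
    residue_index = resids,
    residue_type = rtype,
    delta_shift = cond$shift_ppm[ic] - ref$shift_ppm[ir],
    intensity_ratio = cond$intensity[ic] / ref$intensity[ir],
    stringsAsFactors = FALSE)
  attr(out, "nucleus") <- nucleus
  attr(out, "conditions") <- c(reference = ref$condition[1] %||% NA,
                               condition = cond$condition[1] %||% NA)
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Combined 1H/15N chemical shift perturbation
#'
#' Euclidean composite `sqrt(ddH^2 + (alpha * ddN)^2)` with the customary
#' nitrogen scaling `alpha = 0.2`. Provided as an option; per-nucleus
#' signed perturbations from [compute_csp()] are the primary
#' representation.
#'
#' @param reference,condition peak-list data frames.
#' @param alpha 15N scaling factor.
#' @return A data frame with `residue_index`, `residue_type`, `csp`.
#' @export
csp_combined <- function(reference, condition, alpha = 0.2) {
  n15 <- compute_csp(reference, condition, "15N")
  h1 <- compute_csp(reference, condition, "1H")
  merged <- merge(n15[, c("residue_index", "residue_type", "delta_shift")],
                  h1[, c("residue_index", "delta_shift")],
                  by = "residue_index", suffixes = c("_n", "_h"))
  data.frame(residue_index = merged$residue_index,
             residue_type = merged$residue_type,
             csp = sqrt(merged$delta_shift_h^2 +
                          (alpha * merged$delta_shift_n)^2),
             stringsAsFactors = FALSE)
}

#' Bin chemical shift perturbations by residue type
#'
#' Aggregates per-residue perturbations into residue-type bins (mean, sd,
#' n), using magnitudes by default since the binned representation asks how
#' strongly each residue chemistry is perturbed regardless of direction.
#' Missing residues are dropped from their bin, never imputed.
#'
#' @param table a [compute_csp()] result.
#' @param sequence optional residue-type vector (or single string) covering
#'   the residues in the table; conflicts with the table's own types are an
#'   error naming the residue.
#' @param signed use signed values instead of magnitudes.
#' @return A data frame `residue_type`, `mean`, `sd`, `n`, with the
#'   individual values as the `"values"` attribute.
#' @export
bin_csp_by_residue_type <- function(table, sequence = NULL, signed = FALSE) {
  stopifnot(inherits(table, "csp_table") || is.data.frame(table))
  tab <- table
  if (!is.null(sequence)) {
    if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
      sequence <- strsplit(sequence, "")[[1]]
    if (max(tab$residue_index) > length(sequence))
      stop("sequence shorter than the highest residue index in the table")
    seq_type <- sequence[tab$residue_index]
    bad <- which(!is.na(tab$residue_type) & tab$residue_type != seq_type)
    if (length(bad) > 0)
      stop("residue type conflict at residue ", tab$residue_index[bad[1]],
           ": table says '", tab$residue_type[bad[1]], "', sequence says '",
           seq_type[bad[1]], "'")
    tab$residue_type <- seq_type
  }
  tab <- tab[!is.na(tab$delta_shift), , drop = FALSE]
  v <- if (signed) tab$delta_shift else abs(tab$delta_shift)
  groups <- split(v, tab$residue_type)
  out <- data.frame(
    residue_type = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) sd(x) else NA_real_,
                numeric(1)),
    n = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "values") <- groups
  out
}

#' Cross-condition perturbation slope and correlation
#'
#' Least-squares fit of one condition's per-residue shift perturbations
#' against a reference condition's over the residues present in both, with
#' the Pearson correlation coefficient. When perturbation patterns are
#' shared and merely scaled between compounds, the slope measures relative
#' potency.
#'
#' @param table_x,table_ref [compute_csp()] results for the two conditions
#'   (both against the same cosolvent-free reference).
#' @param fit `"intercept"` (ordinary least squares with intercept, the
#'   default) or `"origin"` (through the origin).
#' @return A list with `slope`, `intercept` (0 for through-origin), `pcc`,
#'   `n` and the `lm` fit.
#' @export
cross_condition_slope <- function(table_x, table_ref,
                                  fit = c("intercept", "origin")) {
  fit <- match.arg(fit)
  merged <- merge(data.frame(residue_index = table_x$residue_index,
                             x = table_x$delta_shift),
                  data.frame(residue_index = table_ref$residue_index,
                             ref = table_ref$delta_shift),
                  by = "residue_index")
  merged <- merged[complete.cases(merged), , drop = FALSE]
  if (nrow(merged) < 3L) stop("need at least 3 common residues")
  if (sd(merged$ref) == 0) stop("zero variance in the reference table")
  mod <- if (fit == "intercept") lm(x ~ ref, data = merged)
         else lm(x ~ 0 + ref, data = merged)
  cf <- coef(mod)
  list(slope = unname(cf[["ref"]]),
       intercept = if (fit == "intercept") unname(cf[["(Intercept)"]]) else 0,
       pcc = cor(merged$x, merged$ref),
       n = nrow(merged), fit = mod)
}

#' Fit a single-exponential relaxation rate
#'
#' Nonlinear least-squares fit of `I(t) = I0 * exp(-R * t)` to a
#' relaxation-delay intensity series (15N R1 or R2 style), initialised from
#' the log-linear fit. Non-decaying data are fitted anyway and flagged,
#' never silently clamped.
#'
#' @param series data frame with columns `delay_s` and `intensity`
#'   (>= 3 distinct delays).
#' @return A list with `rate` (1/s), `rate_se` (from the fit covariance),
#'   `i0`, `converged`, `non_decaying` flag.
#' @export
fit_relaxation_rate <- function(series) {
  need <- c("delay_s", "intensity")
  if (!all(need %in% names(series)))
    stop("series needs columns delay_s and intensity")
  t <- series$delay_s; y <- series$intensity
  if (length(unique(t)) < 3L) stop("need at least 3 distinct delays")
  if (sd(y) == 0) {
    # constant intensities: the least-squares optimum is exactly R = 0
    return(list(rate = 0, rate_se = NA_real_, i0 = y[1],
                converged = TRUE, non_decaying = TRUE))
  }
  pos <- y > 0
  start_r <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(y[pos]) ~ t[pos]))[2]
    -unname(sl)
  } else 1 / max(t)
  non_decaying <- is.finite(start_r) && start_r <= 0
  if (!is.finite(start_r) || start_r == 0) start_r <- 1 / max(t)
  mod <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-r * t),
                      start = list(i0 = max(abs(y)), r = start_r),
                      control = nls.control(maxiter = 200, tol = 1e-10)),
    error = function(e) NULL)
  if (is.null(mod)) {
    return(list(rate = NA_real_, rate_se = NA_real_, i0 = NA_real_,
                converged = FALSE, non_decaying = non_decaying))
  }
  s <- summary(mod)$coefficients
  list(rate = unname(coef(mod)[["r"]]),
       rate_se = unname(s["r", "Std. Error"]),
       i0 = unname(coef(mod)[["i0"]]),
       converged = TRUE,
       non_decaying = non_decaying || coef(mod)[["r"]] <= 0)
}

#' Heteronuclear NOE ratio
#'
#' Ratio of the saturated to the reference peak intensity; values below
#' about 0.5 report fast backbone motions typical of disordered regions.
#'
#' @param i_saturated,i_reference peak intensities (reference non-zero).
#' @return `i_saturated / i_reference`, vectorised.
#' @export
het_noe <- function(i_saturated, i_reference) {
  if (any(i_reference == 0)) stop("reference intensity must be non-zero")
  i_saturated / i_reference
}
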