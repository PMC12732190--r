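#' Describe a two-fold (or other) serial-dilution series
#'
#' Bookkeeping for a microplate serial dilution: the first well holds the
#' undiluted sample, and each transfer carries half (for `dilution_factor`
#' 2) of the material one well to the right, leaving `retained_volume_ul`
#' in every occupied well. For a powder extract prepared weight-per-volume,
#' the concentration is expressed as ng powder per microliter (10% w/v =
#' 100 mg/mL = 100,000 ng/uL).
#'
#' @param start_conc_ng_per_ul Starting concentration in ng/uL (> 0).
#' @param retained_volume_ul Volume left in each well after the serial
#'   transfer, in uL (default 100).
#' @param dilution_factor Per-step dilution factor (default 2, > 1).
#' @param n_wells Series length: 12 for one plate, 24 when the series
#'   extends into a second plate (default 12).
#' @param first_well_undiluted Whether well 1 holds undiluted sample
#'   (default TRUE).
#' @return An object of class `dilution_series`.
#' @examples
#' dilution_series(1040)              # 1.04 mg/mL stock
#' dilution_series(100000, n_wells = 24) # 10% w/v powder extract
#' @export
dilution_series <- function(start_conc_ng_per_ul, retained_volume_ul = 100,
                            dilution_factor = 2, n_wells = 12L,
                            first_well_undiluted = TRUE) {
  if (!is.numeric(start_conc_ng_per_ul) || start_conc_ng_per_ul <= 0)
    stop("`start_conc_ng_per_ul` must be > 0", call. = FALSE)
  if (!is.numeric(retained_volume_ul) || retained_volume_ul <= 0)
    stop("`retained_volume_ul` must be > 0", call. = FALSE)
  if (!is.numeric(dilution_factor) || dilution_factor <= 1)
    stop("`dilution_factor` must be > 1", call. = FALSE)
  n_wells <- as.integer(n_wells)
  if (is.na(n_wells) || n_wells < 2L)
    stop("`n_wells` must be an integer >= 2", call. = FALSE)
  structure(
    list(start_conc_ng_per_ul = start_conc_ng_per_ul,
         retained_volume_ul = retained_volume_ul,
         dilution_factor = dilution_factor,
         n_wells = n_wells,
         first_well_undiluted = isTRUE(first_well_undiluted)),
    class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("dilution_series: start %.6g ng/uL, %.6g uL retained, 1:%g per step, %d wells\n",
              x$start_conc_ng_per_ul, x$retained_volume_ul,
              x$dilution_factor, x$n_wells))
  invisible(x)
}

#' Analyte (or powder) mass present in a given well
#'
#' For an undiluted first well, well n holds
#' `start_conc * retained_volume / dilution_factor^(n - 1)` nanograms.
#'
#' @param series A [dilution_series()].
#' @param well_index 1-based well index (vectorized), within the series.
#' @return Mass in ng per requested well.
#' @examples
#' amount_in_well(dilution_series(1040), 10) # 203.125 ng
#' @export
amount_in_well <- function(series, well_index) {
  stopifnot(inherits(series, "dilution_series"))
  if (any(well_index < 1 | well_index > series$n_wells) ||
      any(well_index != round(well_index)))
    stop(sprintf("`well_index` must be an integer in 1..%d", series$n_wells),
         call. = FALSE)
  expo <- if (series$first_well_undiluted) well_index - 1 else well_index
  series$start_conc_ng_per_ul * series$retained_volume_ul /
    series$dilution_factor^expo
}

#' Titer in hemagglutination units from the last positive well
#'
#' HAU is the reciprocal of the highest dilution still showing
#' agglutination: `dilution_factor^(last_positive - 1)`, so an endpoint at
#' well 10 of a two-fold series is a 1:512 dilution and reports HAU 512.
#'
#' @param last_positive 1-based index of the last positive well (>= 1).
#' @param dilution_factor Per-step dilution factor (default 2).
#' @return Numeric titer.
#' @examples
#' hau_from_well(10) # 512
#' hau_from_well(14) # 8192
#' @export
hau_from_well <- function(last_positive, dilution_factor = 2) {
  if (any(last_positive < 1) || any(last_positive != round(last_positive)))
    stop("`last_positive` must be a well index >= 1", call. = FALSE)
  dilution_factor^(last_positive - 1)
}

#' Estimate active lectin concentration from a hemagglutination endpoint
#'
#' The minimum analyte amount that still agglutinates (`theta_ng`, default
#' 200 ng) lies between the last positive and first negative wells. Taking
#' the powder mass in the first negative well as the denominator gives the
#' estimate `theta_ng / powder_ng * 1000` mg active lectin per g dry
#' powder. When the series never goes negative the estimate is
#' right-censored: the value returned is the lower bound from the deepest
#' well, marked `censored = "ge"`.
#'
#' @param series A [dilution_series()] describing the *powder* mass
#'   concentration of the extract (w/v basis).
#' @param first_negative 1-based index of the first negative well, or `NA`
#'   when the series is positive throughout.
#' @param theta_ng Minimal detectable analyte amount in ng (default 200).
#' @return An object of class `pha_quant`: `conc_mg_per_g`,
#'   `powder_ng_first_negative`, `theta_ng`, `censored` (`"none"` or
#'   `"ge"`).
#' @examples
#' s <- dilution_series(100000, n_wells = 24) # 10% w/v
#' pha_conc_hemagglutination(s, first_negative = 15) # ~327.7 mg/g
#' @export
pha_conc_hemagglutination <- function(series, first_negative, theta_ng = 200) {
  stopifnot(inherits(series, "dilution_series"))
  if (!is.numeric(theta_ng) || theta_ng <= 0)
    stop("`theta_ng` must be > 0", call. = FALSE)
  if (length(first_negative) != 1L)
    stop("`first_negative` must be a single well index or NA", call. = FALSE)
  if (is.na(first_negative)) {
    powder <- amount_in_well(series, series$n_wells)
    conc <- theta_ng / powder * 1000
    censored <- "ge"
  } else {
    powder <- amount_in_well(series, first_negative)
    conc <- theta_ng / powder * 1000
    censored <- "none"
  }
  structure(list(conc_mg_per_g = conc, powder_ng_first_negative = powder,
                 theta_ng = theta_ng, censored = censored),
            class = "pha_quant")
}

#' @export
print.pha_quant <- function(x, ...) {
  cat(sprintf("active lectin: %s%.4g mg/g dry powder (theta %g ng over %.4g ng powder)\n",
              if (x$censored == "ge") ">= " else "",
              x$conc_mg_per_g, x$theta_ng, x$powder_ng_first_negative))
  invisible(x)
}

#' Fit a linear ELISA standard curve
#'
#' Ordinary least squares of absorbance on standard amount (ng); the model
#' is linear, with an estimated intercept (a 0-ng standard implies a
#' measurable blank). Replicates enter the fit individually -- they are not
#' averaged per amount -- so the confidence interval reflects the full
#' replicate degrees of freedom. Quantitation downstream is restricted to
#' the interval between the lower limit of quantification and the highest
#' standard.
#'
#' @param amounts_ng Standard amounts in ng (>= 3 distinct values).
#' @param absorbances Matching absorbance readings (finite).
#' @param lloq_ng Lower limit of quantification in ng (default 15).
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `standard_curve`: `slope_au_per_ng`,
#'   `intercept_au`, `slope_ci` (2-vector), `r2`, `lloq_ng`,
#'   `max_standard_ng`, `n`, and the underlying `fit`.
#' @examples
#' a <- c(0, 12.5, 25, 50, 100, 200, 300)
#' fit_standard_curve(a, 0.0039 * a)
#' @export
fit_standard_curve <- function(amounts_ng, absorbances, lloq_ng = 15,
                               conf_level = 0.95) {
  if (length(amounts_ng) != length(absorbances))
    stop("`amounts_ng` and `absorbances` must have equal length", call. = FALSE)
  if (length(unique(amounts_ng)) < 3L)
    stop("degenerate standard design: at least 3 distinct amounts are required",
         call. = FALSE)
  if (any(!is.finite(absorbances)) || any(!is.finite(amounts_ng)))
    stop("standard amounts and absorbances must be finite", call. = FALSE)
  fit <- stats::lm(absorbances ~ amounts_ng)
  co <- stats::coef(fit)
  # suppressed: summary.lm warns on noise-free (exact) calibration data,
  # where the CI legitimately collapses to the point estimate
  ci <- suppressWarnings(
    tryCatch(stats::confint(fit, "amounts_ng", level = conf_level),
             error = function(e) matrix(c(NA_real_, NA_real_), 1)))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(
    list(slope_au_per_ng = unname(co[2]), intercept_au = unname(co[1]),
         slope_ci = c(ci[1], ci[2]), conf_level = conf_level,
         r2 = r2, lloq_ng = lloq_ng, max_standard_ng = max(amounts_ng),
         n = length(amounts_ng), fit = fit),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: A = %.5g + %.5g * ng (%.0f%% CI on slope %.5g-%.5g), r^2 = %.4f\n",
              x$intercept_au, x$slope_au_per_ng, 100 * x$conf_level,
              x$slope_ci[1], x$slope_ci[2], x$r2))
  cat(sprintf("  quantitation range: %g-%g ng (n = %d standards)\n",
              x$lloq_ng, x$max_standard_ng, x$n))
  invisible(x)
}

#' Back-calculate lectin concentration from an ELISA absorbance
#'
#' Inverts the standard curve to nanograms in the assay well, then converts
#' to mg active lectin per g dry powder through the well volume, the
#' dilution applied to the extract before the assay, and the powder mass
#' concentration of the undiluted extract:
#' `conc = ng / well_volume_ul * dilution_factor / extract_mg_powder_per_ul
#' / 1000`. Readings that invert below the lower limit of quantification
#' are censored: the concentration is reported as below the LLOQ-equivalent
#' bound (`flag = "below_lloq"`, `conc_mg_per_g = NA`), never as a number.
#' Readings above the highest standard are flagged `above_range` because the
#' linear fit is not trusted beyond the calibrated interval.
#'
#' @param absorbance Absorbance reading(s), AU (vectorized).
#' @param curve A [fit_standard_curve()] result with positive slope.
#' @param dilution_factor Fold-dilution of the extract assayed (default 1).
#' @param well_volume_ul Assay well volume in uL (default 100).
#' @param extract_mg_powder_per_ul Powder mass concentration of the
#'   undiluted extract in mg/uL (default 0.1, i.e. 10% w/v).
#' @return A data frame: `absorbance`, `ng_in_well`, `conc_mg_per_g`,
#'   `conc_bound_mg_per_g` (the LLOQ-equivalent bound, for censored rows),
#'   `flag` (`"ok"`, `"below_lloq"`, `"above_range"`).
#' @examples
#' cv <- fit_standard_curve(c(0, 12.5, 25, 50, 100, 200, 300),
#'                          0.0039 * c(0, 12.5, 25, 50, 100, 200, 300))
#' elisa_conc(0.78, cv) # 200 ng in well -> 0.02 mg/g
#' @export
elisa_conc <- function(absorbance, curve, dilution_factor = 1,
                       well_volume_ul = 100, extract_mg_powder_per_ul = 0.1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope_au_per_ng) || curve$slope_au_per_ng <= 0)
    stop("quantitation impossible: standard-curve slope is not positive",
         call. = FALSE)
  if (any(dilution_factor <= 0) || well_volume_ul <= 0 ||
      extract_mg_powder_per_ul <= 0)
    stop("dilution factor, well volume and extract concentration must be > 0",
         call. = FALSE)
  ng <- (absorbance - curve$intercept_au) / curve$slope_au_per_ng
  to_conc <- function(ng_in_well)
    ng_in_well / well_volume_ul * dilution_factor /
      extract_mg_powder_per_ul / 1000
  flag <- ifelse(ng < curve$lloq_ng, "below_lloq",
                 ifelse(ng > curve$max_standard_ng, "above_range", "ok"))
  conc <- ifelse(flag == "below_lloq", NA_real_, to_conc(ng))
  bound <- ifelse(flag == "below_lloq", to_conc(curve$lloq_ng), NA_real_)
  data.frame(absorbance = absorbance, ng_in_well = ng,
             conc_mg_per_g = conc, conc_bound_mg_per_g = bound,
             flag = flag, stringsAsFactors = FALSE)
}

#' Exposure dose from concentration and consumed dry mass
#'
#' The exposure dose is the active lectin concentration of the food (mg per
#' g dry weight) multiplied by the dry matter consumed (g). When a
#' reference dose is supplied (e.g. the amount associated with acute food
#' poisoning), the fold-margin `reference / dose` is reported alongside.
#'
#' @param conc_mg_per_g Active lectin concentration, mg/g dry weight (>= 0).
#' @param dry_mass_g Dry matter consumed, g (>= 0).
#' @param reference_dose_mg Optional reference dose in mg for the margin.
#' @return An object of class `exposure_dose`: `conc_mg_per_g`,
#'   `dry_mass_g`, `dose_mg`, and `margin_vs_reference` (`NA` without a
#'   reference or when the dose is 0).
#' @examples
#' exposure_dose(223.06, 2.44)              # ~544 mg
#' exposure_dose(0.0049, 94, reference_dose_mg = 544)
#' @export
exposure_dose <- function(conc_mg_per_g, dry_mass_g, reference_dose_mg = NULL) {
  if (conc_mg_per_g < 0 || dry_mass_g < 0)
    stop("concentration and mass must be >= 0", call. = FALSE)
  dose <- conc_mg_per_g * dry_mass_g
  margin <- if (is.null(reference_dose_mg) || dose == 0) NA_real_
            else reference_dose_mg / dose
  structure(list(conc_mg_per_g = conc_mg_per_g, dry_mass_g = dry_mass_g,
                 dose_mg = dose, reference_dose_mg = reference_dose_mg,
                 margin_vs_reference = margin),
            class = "exposure_dose")
}

#' @export
print.exposure_dose <- function(x, ...) {
  cat(sprintf("exposure dose: %.4g mg/g x %.4g g = %.4g mg active lectin\n",
              x$conc_mg_per_g, x$dry_mass_g, x$dose_mg))
  if (!is.na(x$margin_vs_reference))
    cat(sprintf("  %.4g-fold below the %.4g mg reference dose\n",
                x$margin_vs_reference, x$reference_dose_mg))
  invisible(x)
}

#' Percent of activity remaining after processing
#'
#' @param conc_processed Concentration in the processed food (mg/g, >= 0).
#' @param conc_raw Concentration in the raw food (mg/g, > 0).
#' @return Percent remaining, `100 * conc_processed / conc_raw`.
#' @examples
#' reduction_ratio(0.0049, 223.06) # ~0.0022%
#' @export
reduction_ratio <- function(conc_processed, conc_raw) {
  if (!is.numeric(conc_raw) || conc_raw <= 0)
    stop("`conc_raw` must be > 0", call. = FALSE)
  if (conc_processed < 0)
    stop("`conc_processed` must be >= 0", call. = FALSE)
  100 * conc_processed / conc_raw
}
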